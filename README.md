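# tvatoj

Hierarchical Bayesian estimation of visual salience and processing
capacity from temporal-order judgments (TOJ), based on Bundesen's Theory
of Visual Attention (TVA).

## The problem

How strongly a salient stimulus attracts attention depends not only on its
physical contrast but on *when* it is probed after onset. A TOJ experiment
measures this: a salient **probe** and a non-salient **reference** flicker
with a stimulus onset asynchrony (SOA, negative = probe first), and the
observer reports which came first. Varying the delay between the onset of
the salience display and the TOJ events (the display onset asynchrony,
DOA) traces the time course of salience. The package is for researchers in
visual psychophysics who want to analyse such designs in theoretically
interpretable parameters rather than descriptive PSS/JND summaries.

## The model

TVA treats the judgment as a capacity-limited independent race between two
exponentially distributed encoding processes. The overall processing
capacity *C* (Hz) is split according to attentional weights, with salience
κ multiplying the probe's weight (κ = 1 for a non-salient stimulus):

    v_p = κ/(1+κ) · C,    v_r = 1/(1+κ) · C

and the probability of judging the probe first at SOA Δt is

    P_p(Δt) = 1 − e^{−v_p|Δt|} (1 − v_p/C)   for Δt < 0
    P_p(Δt) = e^{−v_r|Δt|} · v_p/C           for Δt ≥ 0.

*C* controls the slope (temporal discrimination performance), κ the bias
toward the probe. Per DOA condition, a hierarchical binomial model
estimates population medians and between-participant spreads of both
parameters (JAGS; log-normal participant heterogeneity, κ ≥ 1 support).
Model variants (fixed-κ, fixed-C, logistic) are compared by PSIS-LOO
(looIC), and consecutive DOA conditions by posterior Cohen's *d* against a
ROPE of [−0.3, 0.3].

## Worked example

Simulate a cohort on the five-DOA design (the default generating scenario:
capacity rising 30 → 60 Hz over the first 200 ms, salience ~2–2.5) and fit
the free TVA model. A reduced MCMC budget is used here for speed; the fit
warns that it misses the convergence gates at this budget — use the default
4 × 1000/1000 for real analyses.

```r
library(tvatoj)
design <- make_design(1)
pop    <- population_spec(n_participants = 10, seed = 1)
trials <- simulate_trials(design, sample_participants(pop), seed = 2)
fit    <- fit_toj(trials, chains = 2, warmup = 500, iter = 500, seed = 3)
summary(fit)
#>    parameter condition  mean median hdi_lower hdi_upper
#> 1          C     doa50 35.79  35.19     26.49     44.29
#> 2          C    doa100 44.97  44.55     37.26     52.91
#> 3          C    doa200 52.45  52.31     43.21     61.87
#> 4          C    doa400 59.19  58.98     49.72     69.31
#> 5          C    doa800 65.58  65.34     50.39     80.18
#> 6      kappa     doa50  2.78   2.78      2.20      3.48
#> 7      kappa    doa100  2.81   2.78      2.32      3.32
#> 8      kappa    doa200  2.14   2.13      1.85      2.45
#> 9      kappa    doa400  2.40   2.41      1.82      2.81
#> 10     kappa    doa800  2.20   2.17      1.87      2.68
```

The population capacity medians (`C`, Hz) recover the generating rise from
~30 Hz at DOA 50 ms toward the normative ~60 Hz from 200 ms on, while
salience (`kappa`) stays in the 2–2.8 band; each row gives the posterior
mean/median with the 95% highest-density interval. Effect sizes between
consecutive conditions:

```r
condition_effects(fit, "C")
#>      comparison parameter  map hdi_lower hdi_upper   verdict
#> 1  DOA100-DOA50         C 0.93     -0.53       3.2 undecided
#> 2 DOA200-DOA100         C 0.73     -0.74       2.6 undecided
#> 3 DOA400-DOA200         C 0.68     -0.75       2.4 undecided
#> 4 DOA800-DOA400         C 0.53     -0.70       1.7 undecided
```

`map` is the most likely standardized effect (Cohen's *d* on the latent
log scale), bracketed by its 95% HDI; the verdict compares that HDI with
the ROPE. At 10 participants the intervals are wide, so the early capacity
steps show positive tendencies (`map` ≈ 0.9 and 0.7) but remain
`undecided`; larger cohorts sharpen the verdicts.

The whole chain — simulate, fit all variants, looIC comparison, ROPE
effects, figures — runs from one configuration:

```r
run_pipeline(pipeline_config(seed = 7, outdir = "run1"))
```

or from the shell via `inst/scripts/tvatoj_pipeline.R`.

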