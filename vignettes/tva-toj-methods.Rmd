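---
title: "Measuring the time course of visual salience from temporal-order judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the time course of visual salience from temporal-order judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvatoj)
```

## The model

In a temporal-order judgment (TOJ), two brief visual events — a salient
*probe* and a non-salient *reference* — occur separated by a stimulus onset
asynchrony (SOA, written $\Delta t$; in this package negative $\Delta t$
means the probe came first). The observer reports which event occurred
first. The Theory of Visual Attention (TVA) treats the judgment as the
outcome of a capacity-limited independent race: each stimulus is encoded
after an exponentially distributed latency, and whichever finishes first is
perceived as first.

Attentional weights distribute the overall processing capacity $C$ (Hz)
over the two stimuli. Salience multiplies the weight of the probe by a
factor $\kappa$, while the reference weight is fixed at 1 (a non-salient
stimulus has $\kappa = 1$ by definition; goal-driven weight components are
equal for the two stimuli by design and cancel under normalization). The
rates are therefore

$$v_p = \frac{\kappa}{1+\kappa}\,C, \qquad v_r = \frac{1}{1+\kappa}\,C,
\qquad v_p + v_r = C.$$

The probability of judging the probe first follows from the race between
two exponentials whose onsets are offset by $\Delta t$:

$$P_p(\Delta t) =
\begin{cases}
1 - e^{-v_p\lvert\Delta t\rvert}
  + e^{-v_p\lvert\Delta t\rvert}\dfrac{v_p}{v_p+v_r}, & \Delta t < 0,\\[1ex]
e^{-v_r\lvert\Delta t\rvert}\dfrac{v_p}{v_p+v_r}, & \Delta t \ge 0.
\end{cases}$$

The exponents are decaying: a growing exponential would leave the unit
interval and cannot be a probability. With decay the function is continuous
at $\Delta t = 0$ (both branches give $v_p/(v_p+v_r)$), strictly decreasing
in $\Delta t$, and point-symmetric through $(0, 0.5)$ exactly when
$\kappa = 1$. `race_oracle_prob()` simulates the race directly and is used
throughout the tests as an independent check of the closed form. Capacity
$C$ controls the slope of the curve (temporal discrimination performance);
$\kappa$ shifts its balance toward the probe.

The minimum effective exposure duration that appears in other TVA designs
cancels out of the TOJ race and is deliberately absent from the model.

Two conventions are fixed once: SOAs are handled internally in seconds and
rates in Hz, while all I/O tables use milliseconds; and negative SOA means
probe first, with `flip_soa_convention()` as the single conversion point
for data recorded the other way around.

As a descriptive benchmark, the package also implements the conventional
two-parameter logistic TOJ model with the point of subjective simultaneity
(PSS) and a scale parameter. The JND is defined operationally as the SOA
distance between the 50% and 75% points, $s\,\log 3$, the most common
reading of that convention.

## The experimental design and the synthetic-data generator

The designs built by `make_design()` cross five display onset asynchronies
(DOA: how long the salience display is visible before the TOJ events) of
50, 100, 200, 400 and 800 ms with SOAs of −80, −40, 0, 40 and 80 ms. Every
SOA contributes 34 trials except SOA 0 with 68; the (DOA 50, +80 ms) cell
cannot be presented (the reference would have to precede the salience
display) and is excluded, giving 986 trials per participant. Experiment 1
randomizes fully; experiment 2 blocks by DOA. Only the counts enter the
analysis, so presentation order is carried as metadata and trial order is
not modelled.

`population_spec()` + `sample_participants()` + `simulate_trials()` form
the generative chain: participant-level $(C, \kappa)$ pairs are drawn
log-normally around per-DOA population medians (log-normal because both
parameters are positive and their empirical distributions are
right-skewed), and each participant-by-cell count is binomial with the
closed-form $P_p$. The default scenario uses C medians of 30, 45, 58, 60,
60 Hz across the five DOAs and kappa medians of 2.5, 2.5, 2.3, 2.5, 2.0
with a between-participant log-SD of 0.2. These values emulate the
qualitative pattern this paradigm produces — capacity strongly reduced
below 200 ms and flat thereafter around the normative 60 Hz of healthy
adults, salience in the 2–2.5 range typical of a 90° orientation contrast,
varying only mildly — and are scenario inputs for testing recovery and
ranking, not empirical claims. The generator reproduces the *structure* of
such experiments (hierarchy, binomial noise, design imbalance); it does not
emulate lapses, response bias, learning or serial dependence, so passing
tests demonstrate that the estimation machinery works where the model is
true, not that the model is true of any given dataset.

All randomness is seed-controlled. The pipeline derives per-stage seeds
from one global seed by fixed offsets, and JAGS chain RNGs are seeded from
the fit seed, so identical configurations reproduce results exactly.

## Hierarchical estimation

`fit_toj()` estimates, per DOA condition, population medians and
between-participant spreads of $C$ and $\kappa$ (or PSS and scale), with
participant-level parameters partially pooled within a condition.
Population parameters are independent across conditions — no smoothing is
imposed on the time course, because condition differences are exactly what
the downstream tests assess. Sampling uses JAGS with non-centered
participant effects (latent = $\mu + \sigma z$, $z \sim \mathrm{N}(0,1)$):
the between-participant spreads are only weakly identified when per-cell
trial counts are modest, and the centered form then mixes badly in the
resulting funnel geometry.

Priors (recorded verbatim in every fit object so prior sensitivity is
auditable): population $\log C \sim \mathrm{N}(\log 60, 0.5)$, population
$\log\kappa \sim \mathrm{N}(\log 2, 0.5)$ truncated to $\kappa \ge 1$ —
values of $\kappa$ below 1 would mean the salient stimulus receives *less*
attention than the non-salient one, which this paradigm treats as
implausible — and half-normal(0.5) spreads. The logistic model uses
PSS $\sim \mathrm{N}(0, 0.05\,\mathrm{s})$ and
$\log s \sim \mathrm{N}(\log 0.02, 0.5)$. The default budget is 4 chains
of 1000 warmup + 1000 retained iterations. Convergence is gated at
$\hat R < 1.01$ and ESS > 400 for every population parameter; a fit that
fails the gate is returned with `converged = FALSE` and a warning rather
than failing silently. Predicted cell probabilities are clipped at
$10^{-12}$ for numerical safety only.

Four variants serve the scientific questions: the *free* model (both
parameters per condition), *fixed-κ* (one $\kappa$ across conditions — "no
time course of salience"), *fixed-C* (one $C$ — "no time course of
capacity"), and the *logistic* alternative with the same hierarchy.

## Model comparison and effect sizes

`pointwise_loglik()` + `psis_loo()` implement Pareto-smoothed
importance-sampling leave-one-out cross-validation, reported as
looIC $= -2\,\widehat{\mathrm{elpd}}$ (smaller is better). The observation
unit is one participant × DOA × SOA binomial cell: cells are the natural
exchangeable block of the cell-level likelihood and keep importance
weights stable. A consequence is that absolute looIC values depend on this
unit choice (and on priors), so only looIC *orderings* — not absolute
values — are comparable across analyses that made different choices.
Units with Pareto tail shape $k > 0.7$ are flagged. `loo_compare()` reports
pairwise elpd differences with standard errors computed from the paired
pointwise contributions.

`condition_effects()` computes, per posterior draw, Cohen's
$d = (\mu_A - \mu_B)\big/\sqrt{(\sigma_A^2+\sigma_B^2)/2}$ between
consecutive DOA conditions, using the population location and spread draws
on the latent (log) scale — the scale on which the hierarchy is normal, so
the standardizer is well defined. The verdict compares the 95%
highest-density interval of $d$ against a region of practical equivalence
(ROPE) of $[-0.3, 0.3]$, i.e. effects up to "small" are treated as
practically null: disjoint = `outside_rope` (medium-or-larger effect highly
likely), contained = `inside_rope`, otherwise `undecided` with the MAP
(kernel-density mode, reference-rule bandwidth) reported as the tendency.

## Numerical and design choices

- HDI: narrowest contiguous window over the sorted draws; for multimodal
  posteriors a contiguous interval is an approximation, which is acceptable
  for the unimodal effect-size posteriors this package produces.
- Degenerate inputs: zero population spread is a valid generator setting
  (all participants identical) but spread draws of exactly zero are
  rejected in `cohens_d_draws()` since $d$ is then undefined.
- Ties in the race ($t_p = t_r$) occur with probability zero and are
  resolved in favour of the reference in the oracle (strict inequality),
  which is immaterial at any finite precision.
- The participant screening described for real cohorts (excluding an
  observer who answers "probe first" regardless of SOA) is a data-quality
  issue of real experiments; synthetic cohorts cannot produce it and the
  package deliberately does not fabricate an exclusion statistic.

## Problem sizes used in the validation suite

The test suite validates the chain at sizes chosen to be informative per
unit of computation: identity properties over 1000 random parameter draws;
oracle agreement on a 27-point $(C, \kappa, \Delta t)$ grid at $10^6$
races per point; recovery on one 20-participant cohort at 2 × 600/600
MCMC budget plus twenty 8-participant repetitions at 2 × 300/300 for
interval calibration; model-comparison and ROPE checks on 20-participant
cohorts at 2 × 500/500, the ROPE pattern over five seeds with a majority
criterion. The acceptance script runs the full default budget
(4 × 1000/1000) on a 20-participant cohort. Stochastic checks state
tolerances in Monte-Carlo standard errors or as majority criteria over
seeds; none of these scales is a claim about real-data requirements.

## Limitations

Estimates are conditional on accepting the capacity-limited
independent-race account of the TOJ. Standardized effect sizes between
conditions are noisy at cohort sizes around 20: the population-location
difference carries noise of order $\sqrt{2(\sigma^2+\sigma_m^2)/n}$ (with
$\sigma_m \approx 0.2$ the per-participant log-C measurement uncertainty
from ~200 trials per condition), and the spread draws in the standardizer
add heavy right tails, so the 95% HDI of $d$ clears a $\pm 0.3$ ROPE only
for condition gaps well above $d \approx 1$; smaller gaps land in
`undecided` even when the generating effect is real. This is the
information limit of the design at that cohort size, not a defect of the
decision rule. The looIC comparison covers the four
implemented variants only; it is not a systematic benchmark of all
psychometric functions. Absolute looIC values are not comparable across
different observation-unit or prior choices. The generator's log-normal
heterogeneity is an assumption — convenient, positive-support,
right-skewed — not an estimated fact; and the package makes no attempt to
model the perceptual mechanics of the salience display itself (flicker,
offsets, temporal expectations).
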