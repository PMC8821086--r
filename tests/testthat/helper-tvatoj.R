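# Shared fixtures: synthetic cohorts and cached fits (several tests reuse the
# same MCMC fit; caching keeps the suite fast without coupling the tests).

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache, inherits = FALSE))
    assign(key, expr, envir = .fit_cache)
  get(key, envir = .fit_cache, inherits = FALSE)
}

# Reduced MCMC budget for test-scale fits.
quick <- list(chains = 2, warmup = 400, iter = 400)

sim_cohort <- function(C, kappa, n = 20, sigma_C = 0.2, sigma_K = sigma_C,
                       seed = 1, experiment = 1) {
  pop <- population_spec(C_median = C, kappa_median = kappa,
                         sigma_logC = sigma_C, sigma_logK = sigma_K,
                         n_participants = n, seed = seed)
  simulate_trials(make_design(experiment), sample_participants(pop),
                  seed = seed + 1000L)
}

fit_quiet <- function(data, ..., sampler = quick) {
  suppressWarnings(fit_toj(data, ...,
                           chains = sampler$chains, warmup = sampler$warmup,
                           iter = sampler$iter))
}

# A small TVA cohort + free fit reused across fit/loo/effects tests.
small_fit <- function() {
  cached("small_fit", fit_quiet(small_trials(), seed = 7))
}

small_trials <- function() {
  cached("small_trials", sim_cohort(C = 60, kappa = 2.5, n = 8,
                                    sigma_C = 0.15, seed = 21))
}
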