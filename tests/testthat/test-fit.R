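test_that("free fit exposes per-condition population parameters with diagnostics", {
  fit <- small_fit()
  expect_s3_class(fit, "tvatoj_fit")
  expect_equal(ncol(fit$population$mu_logC), 5)
  expect_equal(ncol(fit$population$mu_logK), 5)
  expect_equal(colnames(fit$population$mu_logC),
               paste0("doa", c(50, 100, 200, 400, 800)))
  S <- quick$chains * quick$iter
  expect_equal(dim(fit$participant$C), c(S, 8, 5))
  expect_equal(dim(fit$participant$kappa), c(S, 8, 5))
  # kappa >= 1 holds strictly at the population level, softly below
  expect_true(all(exp(fit$population$mu_logK) >= 1))
  expect_gt(mean(fit$participant$kappa >= 1), 0.95)

  # an R-hat and ESS entry for every population parameter
  expect_equal(nrow(fit$diagnostics), 20)
  expect_true(all(is.finite(fit$diagnostics$ess)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(is.logical(fit$converged))

  # the prior specification travels with the fit (auditability)
  expect_s3_class(fit$priors, "prior_spec")

  s <- summary(fit)
  expect_equal(nrow(s), 10)
  expect_true(all(s$hdi_lower <= s$median & s$median <= s$hdi_upper))
})

test_that("constrained variants share a single population parameter", {
  trials <- sim_cohort(C = 60, kappa = 2.5, n = 4, seed = 31)
  tiny <- list(chains = 2, warmup = 200, iter = 200)
  fk <- fit_quiet(trials, constraint = "fixed_kappa", seed = 3, sampler = tiny)
  expect_equal(colnames(fk$population$mu_logK), "all")
  expect_equal(ncol(fk$population$mu_logC), 5)
  expect_error(condition_effects(fk, "kappa"), "shared across conditions")

  fc <- fit_quiet(trials, constraint = "fixed_C", seed = 3, sampler = tiny)
  expect_equal(colnames(fc$population$mu_logC), "all")
  expect_equal(ncol(fc$population$mu_logK), 5)
})

test_that("sampling is reproducible given identical seed and configuration", {
  trials <- sim_cohort(C = 60, kappa = 2, n = 3, seed = 41)
  tiny <- list(chains = 2, warmup = 150, iter = 100)
  f1 <- fit_quiet(trials, seed = 12, sampler = tiny)
  f2 <- fit_quiet(trials, seed = 12, sampler = tiny)
  expect_identical(f1$population$mu_logC, f2$population$mu_logC)
  expect_identical(f1$participant$kappa, f2$participant$kappa)
  f3 <- fit_quiet(trials, seed = 13, sampler = tiny)
  expect_false(identical(f1$population$mu_logC, f3$population$mu_logC))
})

test_that("zero-salience data drives kappa to its support boundary", {
  trials <- sim_cohort(C = 60, kappa = 1, n = 8, sigma_C = 0.15, sigma_K = 0,
                       seed = 51)
  fit <- fit_quiet(trials, seed = 5)
  k_draws <- population_draws(fit, "kappa")
  expect_lt(median(k_draws), 1.15)
  expect_lt(quantile(k_draws, 0.25), 1.1)
  expect_true(all(k_draws >= 1))
})

test_that("logistic family fits with the same hierarchical structure", {
  fit <- cached("logistic_fit",
                fit_quiet(small_trials(), family = "logistic", seed = 9))
  expect_equal(ncol(fit$population$mu_pss), 5)
  expect_equal(ncol(fit$population$mu_logscale), 5)
  expect_true(all(is.finite(population_draws(fit, "pss"))))
  expect_true(all(population_draws(fit, "scale") > 0))
  # salient probe is perceived earlier: PSS shifted to positive SOAs
  expect_gt(mean(population_draws(fit, "pss")), 0)
  expect_error(fit_toj(small_trials(), family = "logistic",
                       constraint = "fixed_C"), "TVA family")
  expect_error(population_draws(fit, "kappa"), "not part of a logistic fit")
})

test_that("malformed or empty data is rejected", {
  expect_error(fit_toj(data.frame()), "columns")
  bad <- data.frame(participant_id = 1, doa_ms = 50, soa_ms = 0,
                    n_trials = 2L, n_probe_first = 5L)
  expect_error(fit_toj(bad), "counts")
})

test_that("posterior predictive reproduces the design grid deterministically", {
  fit <- small_fit()
  preds <- posterior_predictive(fit, ndraws = 3, seed = 2)
  expect_length(preds, 3)
  for (pr in preds) {
    expect_equal(as.data.frame(pr[, c("participant_id", "doa_ms", "soa_ms", "n_trials")]),
                 as.data.frame(fit$data[order(fit$data$participant_id,
                                              fit$data$doa_ms, fit$data$soa_ms),
                                        c("participant_id", "doa_ms", "soa_ms", "n_trials")]),
                 ignore_attr = TRUE)
    expect_true(all(pr$n_probe_first <= pr$n_trials))
  }
  expect_identical(posterior_predictive(fit, ndraws = 2, seed = 6),
                   posterior_predictive(fit, ndraws = 2, seed = 6))

  bad_design <- toj_design(doa_ms = c(50, 300))
  expect_error(posterior_predictive(fit, bad_design), "DOA levels")
})

test_that("a degenerate posterior predicts the closed-form proportions", {
  fit <- small_fit()
  degen <- fit
  degen$participant$C[] <- 60
  degen$participant$kappa[] <- 2.5
  preds <- posterior_predictive(degen, ndraws = 150, seed = 3)
  pooled <- Reduce(`+`, lapply(preds, function(p) p$n_probe_first))
  n_tot <- preds[[1]]$n_trials * 150
  p_true <- prob_probe_first(rates_from_params(tva_params(60, 2.5)),
                             preds[[1]]$soa_ms / 1000)
  se <- sqrt(p_true * (1 - p_true) / n_tot)
  expect_true(all(abs(pooled / n_tot - p_true) < 4 * se))
})
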