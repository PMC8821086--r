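test_that("capacity partitions into rates by normalized salience weights", {
  r <- rates_from_params(tva_params(60, 1))
  expect_equal(r$v_probe, 30)
  expect_equal(r$v_reference, 30)

  r <- rates_from_params(tva_params(60, 2.5))
  expect_equal(r$v_probe, 60 * 2.5 / 3.5, tolerance = 1e-10)
  expect_equal(r$v_reference, 60 / 3.5, tolerance = 1e-10)
  expect_equal(r$v_probe + r$v_reference, 60)

  # extreme salience: probe absorbs virtually all capacity
  r <- rates_from_params(tva_params(60, 1e6))
  expect_equal(r$v_probe, 60, tolerance = 1e-4)
  expect_lt(r$v_reference, 1e-3)

  # sum rule over random parameters
  set.seed(1)
  for (i in 1:25) {
    C <- runif(1, 5, 120); k <- runif(1, 0.2, 8)
    r <- rates_from_params(tva_params(C, k))
    expect_equal(r$v_probe + r$v_reference, C, tolerance = 1e-10)
  }

  expect_error(tva_params(0, 1), "positive")
  expect_error(tva_params(60, -1), "positive")
  expect_error(tva_params(Inf, 1), "positive")
  expect_error(rate_pair(0, 10), "positive")
})

test_that("goal-driven weight components cancel under normalization", {
  # normalized weights sum to 1 and are invariant to the shared eta*pi factor
  for (k in c(1, 2.5, 0.7)) {
    w1 <- normalized_weights(weight_model(k, eta_pi = 1))
    w2 <- normalized_weights(weight_model(k, eta_pi = 37.5))
    expect_equal(sum(w1), 1)
    expect_equal(w1, w2)
    expect_equal(unname(w1["probe"]), k / (1 + k))
  }
  # the reference weight carries no salience factor
  wm <- weight_model(2.5, eta_pi = 3)
  expect_equal(wm$w_reference, 3)
  expect_equal(wm$w_probe, 2.5 * 3)
  # rate partition is capacity times the normalized weights
  r <- rates_from_params(tva_params(60, 2.5))
  expect_equal(r$v_probe,
               60 * unname(normalized_weights(weight_model(2.5))["probe"]))
  expect_error(weight_model(0), "positive")
  expect_error(weight_model(2, eta_pi = -1), "positive")
})

test_that("psychometric function: anchors, continuity at SOA 0, saturation", {
  r_eq <- rates_from_params(tva_params(60, 1))
  expect_equal(prob_probe_first(r_eq, 0), 0.5)

  # huge probe head start: certainty
  r <- rates_from_params(tva_params(60, 2.5))
  expect_gt(prob_probe_first(r, -10), 1 - 1e-12)
  expect_lt(prob_probe_first(r, 10), 1e-12)

  # both branch formulas evaluate to v_p/(v_p+v_r) at SOA 0
  share <- r$v_probe / (r$v_probe + r$v_reference)
  left_at_zero <- 1 - exp(-r$v_probe * 0) * (1 - share)
  right_at_zero <- exp(-r$v_reference * 0) * share
  expect_equal(left_at_zero, share)
  expect_equal(right_at_zero, share)
  expect_equal(prob_probe_first(r, 0), share)
  expect_equal(prob_probe_first(r, -1e-9), share, tolerance = 1e-6)
  expect_equal(prob_probe_first(r, 1e-9), share, tolerance = 1e-6)

  expect_error(prob_probe_first(r, NA), "finite")
})

test_that("closed form matches the race oracle at the worked example point", {
  r <- rates_from_params(tva_params(60, 2.5))  # v_p ~ 42.857, v_r ~ 17.143
  p_closed <- prob_probe_first(r, -0.040)
  # frozen from direct evaluation of the corrected decaying-exponential form
  expect_equal(p_closed, 0.94854513, tolerance = 1e-7)
  oracle <- race_oracle_prob(r, -0.040, n_draws = 1e6, seed = 99)
  expect_lt(abs(p_closed - as.numeric(oracle)), 3 * attr(oracle, "mc_se"))
})

test_that("logistic descriptive model: PSS anchor, shift, saturation, JND", {
  expect_equal(logistic_prob(logistic_params(0, 0.02), 0), 0.5)
  expect_equal(logistic_prob(logistic_params(-0.020, 0.017), -0.020), 0.5)
  expect_gt(logistic_prob(logistic_params(0, 0.017), -1), 1 - 1e-9)

  # decreasing in SOA, same orientation as the TVA curve
  p <- logistic_prob(logistic_params(0, 0.02), seq(-0.08, 0.08, by = 0.02))
  expect_true(all(diff(p) < 0))

  # JND: SOA distance between the 50% and 75% points
  lp <- logistic_params(0.01, 0.02)
  expect_equal(jnd(lp), 0.02 * log(3))
  expect_equal(logistic_prob(lp, lp$pss - jnd(lp)), 0.75, tolerance = 1e-10)

  expect_error(logistic_params(0, 0), "positive")
  expect_error(logistic_params(0, -0.1), "positive")
})

test_that("binomial log-likelihood: single-trial anchor, enumeration oracle, ML bound", {
  # predicted p = 0.5 (kappa = 1 at SOA 0), one trial: log(0.5) either way
  cell1 <- data.frame(soa_ms = 0, n_trials = 1L, n_probe_first = 1L)
  cell0 <- data.frame(soa_ms = 0, n_trials = 1L, n_probe_first = 0L)
  expect_equal(binomial_loglik(tva_params(60, 1), cell1), log(0.5))
  expect_equal(binomial_loglik(tva_params(60, 1), cell0), log(0.5))

  # brute-force oracle: per-trial Bernoulli terms plus binomial coefficients
  params <- tva_params(55, 2.2)
  cells <- data.frame(soa_ms = c(-40, 40), n_trials = c(3L, 3L),
                      n_probe_first = c(3L, 1L))
  p <- prob_probe_first(rates_from_params(params), cells$soa_ms / 1000)
  manual <- sum(log(choose(cells$n_trials, cells$n_probe_first)) +
                  cells$n_probe_first * log(p) +
                  (cells$n_trials - cells$n_probe_first) * log(1 - p))
  expect_equal(binomial_loglik(params, cells), manual, tolerance = 1e-12)

  # saturated-model bound: empirical proportions maximize the likelihood
  set.seed(4)
  data <- data.frame(soa_ms = c(-80, -40, 0, 40, 80),
                     n_trials = rep(34L, 5),
                     n_probe_first = c(33L, 30L, 24L, 12L, 4L))
  phat <- data$n_probe_first / data$n_trials
  bound <- sum(dbinom(data$n_probe_first, data$n_trials, phat, log = TRUE))
  for (i in 1:20) {
    ll <- binomial_loglik(tva_params(runif(1, 10, 120), runif(1, 1, 6)), data)
    expect_lte(ll, bound)
  }

  bad <- data.frame(soa_ms = 0, n_trials = 2L, n_probe_first = 3L)
  expect_error(binomial_loglik(tva_params(60, 2), bad), "counts")
})

test_that("race oracle: symmetry, dominance, determinism", {
  r_eq <- rate_pair(30, 30)
  o <- race_oracle_prob(r_eq, 0, n_draws = 1e5, seed = 5)
  expect_lt(abs(as.numeric(o) - 0.5), 3 * attr(o, "mc_se"))

  o_dom <- race_oracle_prob(rate_pair(1000, 1), 0, n_draws = 1e5, seed = 5)
  expect_gt(as.numeric(o_dom), 0.99)

  a <- race_oracle_prob(r_eq, -0.02, n_draws = 1e4, seed = 11)
  b <- race_oracle_prob(r_eq, -0.02, n_draws = 1e4, seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("probability bounds, monotonicity, salience ordering and kappa-1 symmetry", {
  set.seed(2)
  soa_grid <- seq(-0.12, 0.12, by = 0.02)
  for (i in 1:300) {
    C <- runif(1, 5, 150); k <- runif(1, 0.2, 8)
    r <- rates_from_params(tva_params(C, k))
    p <- prob_probe_first(r, soa_grid)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) < 0))  # strictly decreasing in SOA
  }
  # strictly increasing in kappa at fixed C and negative SOA
  kappas <- c(0.5, 1, 1.5, 2.5, 4)
  p_k <- vapply(kappas, function(k)
    prob_probe_first(rates_from_params(tva_params(60, k)), -0.04), 0)
  expect_true(all(diff(p_k) > 0))
  # kappa = 1: point symmetry through (0, 0.5)
  r1 <- rates_from_params(tva_params(47, 1))
  expect_equal(prob_probe_first(r1, soa_grid) + prob_probe_first(r1, -soa_grid),
               rep(1, length(soa_grid)), tolerance = 1e-12)
})

test_that("SOA convention flip negates soa_ms once", {
  tr <- data.frame(soa_ms = c(-40, 0, 80))
  expect_equal(flip_soa_convention(tr)$soa_ms, c(40, 0, -80))
})
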