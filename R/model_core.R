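#' TVA parameters for one observer in one condition
#'
#' The two free parameters of the TVA temporal-order-judgment (TOJ) model:
#' the overall visual processing capacity `C` (sum of the two stimulus
#' processing rates, in Hz) and the salience factor `kappa` (dimensionless
#' attentional-weight ratio of the salient probe relative to the non-salient
#' reference, whose own kappa is fixed at 1). `kappa = 1` means no
#' salience-driven bias; healthy adults typically show `C` around 60 Hz and
#' orientation pop-out contrasts a kappa of roughly 2 to 2.5.
#'
#' @param C Overall processing capacity in Hz; strictly positive and finite.
#' @param kappa Salience ratio; strictly positive and finite.
#' @return An object of class `tva_params`.
#' @seealso [rates_from_params()], [prob_probe_first()]
#' @export
#' @examples
#' tva_params(C = 60, kappa = 2.5)
tva_params <- function(C, kappa) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("`C` must be a single finite positive number (Hz)", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single finite positive number", call. = FALSE)
  structure(list(C = C, kappa = kappa), class = "tva_params")
}

#' Attentional weights under the multiplicative weight equation
#'
#' Salience and goal-driven influences combine multiplicatively into
#' attentional weights: `w_x = kappa_x * eta_pi`, where `eta_pi` collapses
#' the goal-driven sum (pertinence-weighted sensory evidence) into one
#' non-negative constant. In a TOJ both stimuli are equally task-relevant,
#' so `eta_pi` is shared — and cancels once weights are normalized. The
#' reference stimulus has no specific bottom-up salience, so its kappa is
#' fixed at 1.
#'
#' @param kappa_probe Salience factor of the probe (> 0).
#' @param eta_pi Shared goal-driven weight component (> 0). Default 1.
#' @return An object of class `weight_model` with raw weights `w_probe`,
#'   `w_reference` and the salience factor.
#' @seealso [normalized_weights()], [rates_from_params()]
#' @export
weight_model <- function(kappa_probe, eta_pi = 1) {
  if (!is.numeric(kappa_probe) || length(kappa_probe) != 1L ||
      !is.finite(kappa_probe) || kappa_probe <= 0)
    stop("`kappa_probe` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(eta_pi) || length(eta_pi) != 1L || !is.finite(eta_pi) ||
      eta_pi <= 0)
    stop("`eta_pi` must be a single finite positive number", call. = FALSE)
  structure(list(kappa_probe = kappa_probe, eta_pi = eta_pi,
                 w_probe = kappa_probe * eta_pi,
                 w_reference = 1 * eta_pi),
            class = "weight_model")
}

#' Normalized attentional weights
#'
#' Dividing by the weight sum removes the shared goal-driven factor: the
#' normalized weights depend on kappa only and sum to 1. These are the
#' fractions of the capacity C allotted to each stimulus.
#'
#' @param wm A [weight_model()] object.
#' @return Named numeric vector `c(probe = , reference = )` summing to 1.
#' @export
normalized_weights <- function(wm) {
  stopifnot(inherits(wm, "weight_model"))
  s <- wm$w_probe + wm$w_reference
  c(probe = wm$w_probe / s, reference = wm$w_reference / s)
}

#' Partition processing capacity into probe and reference rates
#'
#' Attentional weights are proportional to salience (probe: kappa,
#' reference: 1); normalising them distributes the capacity `C` over the two
#' stimuli:
#' \deqn{v_p = \frac{\kappa}{1+\kappa} C, \qquad v_r = \frac{1}{1+\kappa} C.}
#'
#' @param params A [tva_params()] object.
#' @return An object of class `rate_pair` with fields `v_probe` and
#'   `v_reference` (Hz). The rates always sum to `C`.
#' @export
#' @examples
#' rates_from_params(tva_params(60, 2.5))
rates_from_params <- function(params) {
  stopifnot(inherits(params, "tva_params"))
  v_p <- params$kappa / (1 + params$kappa) * params$C
  rate_pair(v_probe = v_p, v_reference = params$C - v_p)
}

#' @rdname rates_from_params
#' @param v_probe,v_reference Processing rates in Hz; strictly positive.
#' @export
rate_pair <- function(v_probe, v_reference) {
  if (!is.finite(v_probe) || v_probe <= 0 || !is.finite(v_reference) || v_reference <= 0)
    stop("processing rates must be finite and strictly positive", call. = FALSE)
  structure(list(v_probe = v_probe, v_reference = v_reference), class = "rate_pair")
}

# Vectorised core of the race-model psychometric function.
# vp, vr in Hz; dt in seconds (negative = probe onset first).
# Left branch (dt < 0): 1 - e^{-v_p|dt|} + e^{-v_p|dt|} v_p/(v_p+v_r)
# Right branch (dt >= 0): e^{-v_r|dt|} v_p/(v_p+v_r)
p_probe_first <- function(vp, vr, dt) {
  k <- max(length(vp), length(vr), length(dt))
  vp <- rep_len(vp, k); vr <- rep_len(vr, k); dt <- rep_len(dt, k)
  share <- vp / (vp + vr)
  out <- numeric(k)
  neg <- dt < 0
  out[neg] <- 1 - exp(vp[neg] * dt[neg]) * (1 - share[neg])
  out[!neg] <- exp(-vr[!neg] * dt[!neg]) * share[!neg]
  out
}

#' TVA-TOJ psychometric function: probability of judging the probe first
#'
#' Probability that the salient probe wins the encoding race and is hence
#' reported as appearing first, as a function of the stimulus onset
#' asynchrony. Negative SOA means the probe event physically preceded the
#' reference event. The function is continuous at SOA 0 (both branches give
#' \eqn{v_p/(v_p+v_r)}), strictly decreasing in SOA, and point-symmetric
#' about (0, 0.5) when the rates are equal (kappa = 1).
#'
#' @param rates A [rate_pair()] object.
#' @param soa_s Signed SOA in seconds (vectorised); negative = probe first.
#' @return Probabilities in \eqn{[0, 1]}, one per SOA.
#' @export
#' @examples
#' r <- rates_from_params(tva_params(60, 2.5))
#' prob_probe_first(r, soa_s = c(-0.08, -0.04, 0, 0.04, 0.08))
prob_probe_first <- function(rates, soa_s) {
  stopifnot(inherits(rates, "rate_pair"))
  if (!is.numeric(soa_s) || any(!is.finite(soa_s)))
    stop("`soa_s` must be finite numeric (seconds)", call. = FALSE)
  p_probe_first(rates$v_probe, rates$v_reference, soa_s)
}

#' Logistic (PSS/JND) parameters for the descriptive TOJ model
#'
#' The conventional descriptive model of TOJ data: a two-parameter logistic
#' in SOA, located by the point of subjective simultaneity (PSS, where the
#' probe-first probability crosses 0.5) and scaled by a slope parameter from
#' which the just-noticeable difference (JND) derives. Both are in seconds
#' to match the internal SOA unit.
#'
#' @param pss Point of subjective simultaneity in seconds.
#' @param scale Logistic scale parameter in seconds; strictly positive.
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(pss, scale) {
  if (!is.numeric(pss) || length(pss) != 1L || !is.finite(pss))
    stop("`pss` must be a single finite number (seconds)", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single finite positive number (seconds)", call. = FALSE)
  structure(list(pss = pss, scale = scale), class = "logistic_params")
}

#' @rdname logistic_params
#' @param params A `logistic_params` object.
#' @param soa_s Signed SOA in seconds; negative = probe first.
#' @details `logistic_prob()` is oriented like the TVA function: it decreases
#'   in SOA and equals 0.5 at `soa_s = pss`.
#' @export
logistic_prob <- function(params, soa_s) {
  stopifnot(inherits(params, "logistic_params"))
  if (!is.numeric(soa_s) || any(!is.finite(soa_s)))
    stop("`soa_s` must be finite numeric (seconds)", call. = FALSE)
  plogis((params$pss - soa_s) / params$scale)
}

#' @rdname logistic_params
#' @details `jnd()` returns the SOA distance between the 50% and 75% points
#'   of the logistic curve, `scale * log(3)`, in seconds.
#' @export
jnd <- function(params) {
  stopifnot(inherits(params, "logistic_params"))
  params$scale * log(3)
}

# Dispatch: predicted probe-first probability for either model family.
toj_probability <- function(params, soa_s) {
  if (inherits(params, "tva_params")) {
    prob_probe_first(rates_from_params(params), soa_s)
  } else if (inherits(params, "logistic_params")) {
    logistic_prob(params, soa_s)
  } else {
    stop("`params` must be tva_params or logistic_params", call. = FALSE)
  }
}

#' Binomial log-likelihood of aggregated TOJ counts under a psychometric model
#'
#' Sums, over the cells of a trial table, the binomial log-probability of the
#' observed probe-first counts given the model's predicted probability at
#' each cell's SOA. Predicted probabilities are clipped to
#' \eqn{[\epsilon, 1-\epsilon]} for numerical safety.
#'
#' @param params A [tva_params()] or [logistic_params()] object (one
#'   observer/condition).
#' @param data A data frame with columns `soa_ms`, `n_trials`,
#'   `n_probe_first` (e.g. a subset of a [simulate_trials()] table).
#' @param eps Clipping bound for predicted probabilities. Default `1e-12`.
#' @return A single finite log-likelihood value.
#' @export
binomial_loglik <- function(params, data, eps = 1e-12) {
  check_trial_cells(data)
  p <- toj_probability(params, data$soa_ms / 1000)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(dbinom(data$n_probe_first, data$n_trials, p, log = TRUE))
}

# Validate the count columns of a trial-table-like data frame.
check_trial_cells <- function(data) {
  need <- c("soa_ms", "n_trials", "n_probe_first")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must contain columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L) stop("`data` has no cells", call. = FALSE)
  bad <- !is.finite(data$n_trials) | !is.finite(data$n_probe_first) |
    data$n_trials < data$n_probe_first | data$n_probe_first < 0 |
    data$n_trials %% 1 != 0 | data$n_probe_first %% 1 != 0
  if (any(bad))
    stop("malformed counts: need integer 0 <= n_probe_first <= n_trials", call. = FALSE)
  invisible(data)
}

#' Monte-Carlo race oracle for the TOJ probability
#'
#' Simulates the independent exponential race directly: the probe's encoding
#' time is Exp(v_p) from probe onset, the reference's Exp(v_r) from reference
#' onset, and the onsets are offset by the SOA (negative = probe onset
#' earlier). Returns the fraction of races the probe wins — an estimate of
#' [prob_probe_first()] that is independent of the closed form and serves as
#' its oracle.
#'
#' @param rates A [rate_pair()] object.
#' @param soa_s Signed SOA in seconds (scalar).
#' @param n_draws Number of simulated races (>= 1).
#' @param seed Integer seed; same seed, same estimate.
#' @return The win fraction, with attributes `mc_se` (binomial Monte-Carlo
#'   standard error) and `n_draws`.
#' @export
race_oracle_prob <- function(rates, soa_s, n_draws = 1e6, seed = 1) {
  stopifnot(inherits(rates, "rate_pair"), length(soa_s) == 1L, is.finite(soa_s))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("`n_draws` must be >= 1", call. = FALSE)
  with_seed(seed, {
    onset_p <- max(soa_s, 0)
    onset_r <- max(-soa_s, 0)
    t_p <- onset_p + rexp(n_draws, rates$v_probe)
    t_r <- onset_r + rexp(n_draws, rates$v_reference)
    p_hat <- mean(t_p < t_r)
    structure(p_hat,
              mc_se = sqrt(p_hat * (1 - p_hat) / n_draws),
              n_draws = n_draws)
  })
}

#' Flip the SOA sign convention of a trial table
#'
#' The package convention is negative SOA = probe event first. Data recorded
#' with the opposite convention (positive = probe first) can be converted
#' here, at a single point, by negating `soa_ms`.
#'
#' @param trials A trial table with column `soa_ms`.
#' @return The table with `soa_ms` negated.
#' @export
flip_soa_convention <- function(trials) {
  stopifnot(is.data.frame(trials), "soa_ms" %in% names(trials))
  trials$soa_ms <- -trials$soa_ms
  trials
}
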