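#' Pointwise log-likelihood matrix for a fitted model
#'
#' Evaluates the binomial log-likelihood of every observation unit at every
#' posterior draw. The observation unit is one participant x DOA x SOA
#' binomial cell — the exchangeable block of the cell-level likelihood.
#' Summing a row over units recovers the total data log-likelihood at that
#' draw's parameters.
#'
#' @param fit A [fit_toj()] result.
#' @param data A trial table; defaults to the data the model was fitted to.
#'   Cells must be covered by the fit's participants and DOA levels.
#' @param eps Probability clipping bound (as in [binomial_loglik()]).
#' @return A draws x units matrix with unit labels as column names, class
#'   `pointwise_loglik`.
#' @export
pointwise_loglik <- function(fit, data = fit$data, eps = 1e-12) {
  stopifnot(inherits(fit, "tvatoj_fit"))
  check_trial_cells(data)
  if (!all(data$participant_id %in% fit$participant_ids) ||
      !all(data$doa_ms %in% fit$doa_ms))
    stop("data cells are not covered by the fit's participants/DOA levels",
         call. = FALSE)
  i_idx <- match(data$participant_id, fit$participant_ids)
  d_idx <- match(data$doa_ms, fit$doa_ms)
  dt <- data$soa_ms / 1000
  S <- dim(fit$participant[[1]])[1]
  out <- matrix(NA_real_, S, nrow(data))
  for (n in seq_len(nrow(data))) {
    if (fit$family == "tva") {
      Cv <- fit$participant$C[, i_idx[n], d_idx[n]]
      Kv <- fit$participant$kappa[, i_idx[n], d_idx[n]]
      vp <- Kv / (1 + Kv) * Cv
      p <- p_probe_first(vp, Cv - vp, dt[n])
    } else {
      p <- plogis((fit$participant$pss[, i_idx[n], d_idx[n]] - dt[n]) /
                    fit$participant$scale[, i_idx[n], d_idx[n]])
    }
    p <- pmin(pmax(p, eps), 1 - eps)
    out[, n] <- dbinom(data$n_probe_first[n], data$n_trials[n], p, log = TRUE)
  }
  colnames(out) <- sprintf("p%02d:doa%03d:soa%+04d", data$participant_id,
                           data$doa_ms, data$soa_ms)
  structure(out, unit = "participant x DOA x SOA cell",
            class = c("pointwise_loglik", "matrix", "array"))
}

# Maximum-likelihood fit of a generalized Pareto distribution to tail
# exceedances, by the profile-posterior quadrature of Zhang & Stephens
# (2009), with the weak shape prior used in PSIS. Parameterization:
# F(x) = 1 - (1 + k x / sigma)^(-1/k).
gpd_fit <- function(x, wip = TRUE, min_grid = 30L) {
  n <- length(x)
  x <- sort.int(x)
  m <- min_grid + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  prof <- function(t) {
    k <- mean(log1p(-t * x))  # = -k in the Zhang-Stephens convention
    n * (log(-t / k) - k - 1)
  }
  l_theta <- vapply(theta, prof, 0)
  w <- 1 / vapply(jj, function(j) sum(exp(l_theta - l_theta[j])), 0)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- (k * n + 5) / (n + 10)  # regularize towards 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios (PSIS). Returns the
# smoothed, max-truncated log weights (unnormalized) and the tail shape k.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lr <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || S < 25) return(list(log_w = lr, k = NA_real_))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- exp(lr[ord[S - M]])
  exceed <- exp(lr[tail_ids]) - cutoff
  if (all(exceed <= 0) || length(unique(exceed)) < 2)
    return(list(log_w = lr, k = NA_real_))
  fit <- gpd_fit(exceed)
  q <- vapply((seq_len(M) - 0.5) / M, gpd_quantile, 0, k = fit$k, sigma = fit$sigma)
  smoothed <- log(cutoff + q)
  lr[tail_ids[order(lr[tail_ids])]] <- pmin(smoothed, 0)  # truncate at raw max
  list(log_w = lr, k = fit$k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' PSIS leave-one-out cross-validation from a pointwise log-likelihood matrix
#'
#' Pareto-smoothed importance-sampling estimate of the expected log pointwise
#' predictive density under leave-one-unit-out cross-validation, and the
#' corresponding information criterion looIC = -2 elpd (smaller = better
#' out-of-sample prediction). Units whose importance-weight tail shape
#' exceeds 0.7 are flagged as unstable.
#'
#' @param loglik A [pointwise_loglik()] matrix (draws x units).
#' @return An object of class `tvatoj_loo` with `elpd`, `elpd_se`, `looic`,
#'   `looic_se`, a pointwise data frame (`elpd_i`, `pareto_k`), and
#'   `n_unstable`.
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 25)
  n <- ncol(loglik)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[, i])
    elpd_i[i] <- log_sum_exp(sm$log_w + loglik[, i]) - log_sum_exp(sm$log_w)
    k_i[i] <- sm$k
  }
  elpd <- sum(elpd_i)
  se <- sqrt(n * var(elpd_i))
  structure(list(elpd = elpd, elpd_se = se,
                 looic = -2 * elpd, looic_se = 2 * se,
                 pointwise = data.frame(unit = colnames(loglik) %||%
                                          as.character(seq_len(n)),
                                        elpd_i = elpd_i, pareto_k = k_i),
                 n_unstable = sum(k_i > 0.7, na.rm = TRUE),
                 n_units = n),
            class = "tvatoj_loo")
}

#' @export
print.tvatoj_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d units: elpd = %.2f (SE %.2f), looIC = %.2f\n",
              x$n_units, x$elpd, x$elpd_se, x$looic))
  if (x$n_unstable > 0)
    cat(sprintf("  warning: %d unit(s) with Pareto k > 0.7 (unstable weights)\n",
                x$n_unstable))
  invisible(x)
}

#' Compare models by looIC
#'
#' Ranks models by looIC (ascending: the best predicting model first) and
#' reports, for each model, the elpd difference to the best model with the
#' standard error of that difference (computed from the paired pointwise
#' elpd contributions). All models must be evaluated on the identical unit
#' set.
#'
#' @param ... Named [psis_loo()] results, or a single named list of them.
#' @return A data frame with one row per model: `model`, `looic`,
#'   `looic_se`, `elpd_diff` (vs. best; 0 for the best), `diff_se`,
#'   `n_unstable`.
#' @export
#' @examples
#' \donttest{
#' # loo_compare(free = psis_loo(ll1), fixed_kappa = psis_loo(ll2))
#' }
loo_compare <- function(...) {
  models <- list(...)
  if (length(models) == 1L && !inherits(models[[1]], "tvatoj_loo"))
    models <- models[[1]]
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be named", call. = FALSE)
  stopifnot(all(vapply(models, inherits, TRUE, "tvatoj_loo")))
  units <- lapply(models, function(m) sort(m$pointwise$unit))
  if (!all(vapply(units, identical, TRUE, units[[1]])))
    stop("models were evaluated on different unit sets", call. = FALSE)
  looic <- vapply(models, `[[`, 0, "looic")
  best <- which.min(looic)
  # align pointwise contributions by unit label before pairing
  pw <- lapply(models, function(m)
    m$pointwise$elpd_i[order(m$pointwise$unit)])
  out <- data.frame(
    model = names(models),
    looic = looic,
    looic_se = vapply(models, `[[`, 0, "looic_se"),
    elpd_diff = vapply(models, `[[`, 0, "elpd") - models[[best]]$elpd,
    diff_se = vapply(seq_along(models), function(j) {
      if (j == best) return(0)
      d <- pw[[j]] - pw[[best]]
      sqrt(length(d) * var(d))
    }, 0),
    n_unstable = vapply(models, `[[`, 0, "n_unstable"),
    row.names = NULL
  )
  out[order(out$looic), ]
}
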