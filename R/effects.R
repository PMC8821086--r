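#' Posterior draws of Cohen's d between two conditions
#'
#' Per posterior draw, the standardized difference of two population
#' locations, pooled over the two conditions' population spreads:
#' \deqn{d = (\mu_A - \mu_B) / \sqrt{(\sigma_A^2 + \sigma_B^2)/2}.}
#' For the hierarchical TOJ models the locations and spreads live on the
#' latent (log) scale of the parameter, so d is the standardized log-scale
#' difference.
#'
#' @param mu_a,mu_b Draws of the two population locations (equal length).
#' @param sigma_a,sigma_b Draws of the two population spreads (equal length,
#'   strictly positive).
#' @return A vector of d draws.
#' @export
cohens_d_draws <- function(mu_a, mu_b, sigma_a, sigma_b) {
  n <- length(mu_a)
  if (length(mu_b) != n || length(sigma_a) != n || length(sigma_b) != n)
    stop("all draw vectors must have equal length", call. = FALSE)
  if (any(sigma_a <= 0) || any(sigma_b <= 0))
    stop("spread draws must be strictly positive", call. = FALSE)
  (mu_a - mu_b) / sqrt((sigma_a^2 + sigma_b^2) / 2)
}

#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing the requested posterior
#' mass, found by scanning all windows of `floor(mass * n)` sorted draws.
#'
#' @param draws Numeric draws (at least 100).
#' @param mass Probability mass, strictly between 0 and 1. Default 0.95.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 100) stop("need at least 100 draws", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop("`mass` must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, floor(mass * n))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Maximum a posteriori (MAP) estimate from draws
#'
#' Mode of a Gaussian kernel-density estimate over the draws (bandwidth by
#' the standard reference rule). Degenerate (zero-variance) draws return
#' their common value.
#'
#' @param draws Numeric draws.
#' @return The estimated posterior mode.
#' @export
map_estimate <- function(draws) {
  if (length(unique(draws)) == 1L) return(draws[1])
  dens <- density(draws)
  dens$x[which.max(dens$y)]
}

#' ROPE decision on a posterior effect-size sample
#'
#' Compares the 95% highest-density interval of the effect-size draws with a
#' region of practical equivalence (ROPE). Verdicts: `outside_rope` if the
#' HDI and the ROPE are disjoint (a medium-or-larger effect is highly
#' likely), `inside_rope` if the HDI lies entirely within the ROPE (no or a
#' small effect is highly likely), `undecided` if they partially overlap.
#' The default ROPE of \eqn{[-0.3, 0.3]} treats effects up to "small" as
#' practically equivalent to zero.
#'
#' @param d_draws Draws of the standardized effect size.
#' @param rope Length-2 ROPE bounds. Default `c(-0.3, 0.3)`.
#' @param mass HDI mass. Default 0.95.
#' @return A list with `verdict`, `map`, `hdi` and `rope`.
#' @export
rope_decision <- function(d_draws, rope = c(-0.3, 0.3), mass = 0.95) {
  stopifnot(length(rope) == 2L, rope[1] <= rope[2])
  h <- hdi(d_draws, mass)
  verdict <- if (h[2] < rope[1] || h[1] > rope[2]) "outside_rope"
  else if (h[1] >= rope[1] && h[2] <= rope[2]) "inside_rope"
  else "undecided"
  list(verdict = verdict, map = map_estimate(d_draws), hdi = h, rope = rope)
}

#' Effect sizes and ROPE verdicts for consecutive DOA conditions
#'
#' For each pair of consecutive DOA conditions (shorter subtracted from
#' longer, e.g. "DOA100-DOA50"), computes the posterior Cohen's d of the
#' chosen population parameter via [cohens_d_draws()] and the ROPE verdict
#' via [rope_decision()]. Mirrors the "MAP [HDI]" reporting style used for
#' this paradigm.
#'
#' @param fit A [fit_toj()] result with per-condition parameters.
#' @param parameter `"C"`, `"kappa"`, `"pss"` or `"scale"`.
#' @param rope ROPE bounds. Default `c(-0.3, 0.3)`.
#' @param mass HDI mass. Default 0.95.
#' @return A data frame with one row per consecutive comparison:
#'   `comparison`, `parameter`, `map`, `hdi_lower`, `hdi_upper`, `verdict`.
#' @export
condition_effects <- function(fit, parameter = c("C", "kappa", "pss", "scale"),
                              rope = c(-0.3, 0.3), mass = 0.95) {
  stopifnot(inherits(fit, "tvatoj_fit"))
  parameter <- match.arg(parameter)
  keys <- switch(parameter,
                 C = c("mu_logC", "sigma_logC"),
                 kappa = c("mu_logK", "sigma_logK"),
                 pss = c("mu_pss", "sigma_pss"),
                 scale = c("mu_logscale", "sigma_logscale"))
  mu <- fit$population[[keys[1]]]
  sg <- fit$population[[keys[2]]]
  if (is.null(mu))
    stop("parameter `", parameter, "` is not part of a ", fit$family,
         " fit", call. = FALSE)
  if (ncol(mu) < 2L)
    stop("parameter `", parameter, "` is shared across conditions in the ",
         fit$constraint, " variant; no condition effects exist", call. = FALSE)
  D <- length(fit$doa_ms)
  out <- lapply(seq_len(D - 1), function(j) {
    d <- cohens_d_draws(mu[, j + 1], mu[, j], sg[, j + 1], sg[, j])
    dec <- rope_decision(d, rope, mass)
    data.frame(comparison = sprintf("DOA%d-DOA%d", fit$doa_ms[j + 1], fit$doa_ms[j]),
               parameter = parameter,
               map = dec$map, hdi_lower = dec$hdi[1], hdi_upper = dec$hdi[2],
               verdict = dec$verdict)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
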