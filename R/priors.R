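#' Prior specification for the hierarchical TOJ models
#'
#' All hierarchical variants share this prior structure. Population locations
#' are normal on the latent scale; population spreads are half-normal. For
#' the TVA family the latent scales are log C and log kappa, with the log
#' kappa location truncated at 0 so that a population in which the salient
#' stimulus is *less* attended than the non-salient reference (kappa < 1)
#' receives no prior mass; at the participant level the bound is soft,
#' through the smallness of the spread. Defaults centre C on the normative
#' 60 Hz and kappa on 2, with wide (0.5) log-scale dispersion. For the
#' logistic family the latent scales are the PSS (seconds) and log of the
#' logistic scale parameter.
#'
#' @param C_location,C_scale Normal prior on population log C. Defaults
#'   `log(60)`, `0.5`.
#' @param kappa_location,kappa_scale Truncated-normal prior on population
#'   log kappa (support log kappa >= 0). Defaults `log(2)`, `0.5`.
#' @param spread_scale Half-normal scale for all log-scale population
#'   spreads. Default `0.5`.
#' @param pss_location,pss_scale Normal prior on population PSS in seconds.
#'   Defaults `0`, `0.05`.
#' @param pss_spread_scale Half-normal scale for the PSS population spread
#'   (seconds). Default `0.05`.
#' @param logscale_location,logscale_scale Normal prior on the population
#'   log logistic scale (seconds). Defaults `log(0.02)`, `0.5`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(C_location = log(60), C_scale = 0.5,
                       kappa_location = log(2), kappa_scale = 0.5,
                       spread_scale = 0.5,
                       pss_location = 0, pss_scale = 0.05,
                       pss_spread_scale = 0.05,
                       logscale_location = log(0.02), logscale_scale = 0.5) {
  scales <- c(C_scale, kappa_scale, spread_scale, pss_scale,
              pss_spread_scale, logscale_scale)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all prior scales must be finite and positive (proper priors)", call. = FALSE)
  structure(list(C_location = C_location, C_scale = C_scale,
                 kappa_location = kappa_location, kappa_scale = kappa_scale,
                 spread_scale = spread_scale,
                 pss_location = pss_location, pss_scale = pss_scale,
                 pss_spread_scale = pss_spread_scale,
                 logscale_location = logscale_location,
                 logscale_scale = logscale_scale),
            class = "prior_spec")
}
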