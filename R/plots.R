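utils::globalVariables(c("soa_ms", "prop", "doa", "value", "p"))

#' Psychometric curves at the posterior median, with observed proportions
#'
#' One curve per DOA condition, drawn from the posterior median population
#' parameters, overlaid on the pooled observed probe-first proportions.
#'
#' @param fit A [fit_toj()] result.
#' @param soa_range SOA range for the curves in ms.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fit, soa_range = c(-100, 100)) {
  stopifnot(inherits(fit, "tvatoj_fit"))
  grid_soa <- seq(soa_range[1], soa_range[2], length.out = 201)
  curves <- do.call(rbind, lapply(seq_along(fit$doa_ms), function(d) {
    params <- if (fit$family == "tva") {
      tva_params(median(population_draws(fit, "C")[, min(d, ncol(population_draws(fit, "C")))]),
                 median(population_draws(fit, "kappa")[, min(d, ncol(population_draws(fit, "kappa")))]))
    } else {
      logistic_params(median(population_draws(fit, "pss")[, d]),
                      median(population_draws(fit, "scale")[, d]))
    }
    data.frame(doa = factor(fit$doa_ms[d]), soa_ms = grid_soa,
               p = toj_probability(params, grid_soa / 1000))
  }))
  obs <- aggregate(cbind(n_trials, n_probe_first) ~ doa_ms + soa_ms,
                   data = fit$data, FUN = sum)
  obs$prop <- obs$n_probe_first / obs$n_trials
  obs$doa <- factor(obs$doa_ms)
  ggplot2::ggplot(curves, ggplot2::aes(soa_ms, p, colour = doa)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs, ggplot2::aes(soa_ms, prop, colour = doa)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "SOA (ms, negative = probe first)",
                  y = "P(probe judged first)", colour = "DOA (ms)") +
    ggplot2::theme_minimal()
}

#' Posterior densities of a population parameter across DOA conditions
#'
#' @param fit A [fit_toj()] result.
#' @param parameter `"C"`, `"kappa"`, `"pss"` or `"scale"`.
#' @return A ggplot object.
#' @export
plot_posterior <- function(fit, parameter = "C") {
  draws <- population_draws(fit, parameter)
  df <- data.frame(
    doa = factor(rep(colnames(draws), each = nrow(draws))),
    value = as.vector(draws)
  )
  xlab <- switch(parameter, C = "population C (Hz)",
                 kappa = "population kappa",
                 pss = "population PSS (s)", scale = "population scale (s)")
  ggplot2::ggplot(df, ggplot2::aes(value, colour = doa, fill = doa)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::labs(x = xlab, y = "posterior density", colour = "condition",
                  fill = "condition") +
    ggplot2::theme_minimal()
}
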