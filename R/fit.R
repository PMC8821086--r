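#' Fit a hierarchical Bayesian TOJ model
#'
#' Estimates population- and participant-level parameters per DOA condition
#' from an aggregated trial table by MCMC (JAGS). Four variants are
#' available: the TVA race model with both C and kappa free per condition,
#' the `fixed_kappa` variant (one kappa shared across conditions), the
#' `fixed_C` variant (one C shared), and the descriptive logistic model
#' (PSS and scale per condition, same hierarchical structure).
#'
#' Participant parameters are partially pooled within each DOA condition;
#' population parameters are independent across conditions. The full prior
#' specification is recorded in the returned object so prior sensitivity is
#' auditable. Convergence is gated on split-chain R-hat < `rhat_threshold`
#' and effective sample size > `ess_threshold` for every population
#' parameter; a failing fit is returned flagged (`converged = FALSE`, with a
#' warning), never silently.
#'
#' @param data A trial table (see [simulate_trials()] / [read_trial_table()]).
#' @param family `"tva"` or `"logistic"`.
#' @param constraint `"free"`, `"fixed_kappa"`, or `"fixed_C"` (TVA only).
#' @param priors A [prior_spec()].
#' @param chains,warmup,iter MCMC budget: number of chains, warmup
#'   iterations per chain (half adaptation, half burn-in), and retained
#'   iterations per chain. Defaults 4 / 1000 / 1000.
#' @param seed Integer seed; chain RNGs are derived from it, so identical
#'   settings reproduce the draws exactly.
#' @param quiet Suppress JAGS progress output.
#' @param rhat_threshold,ess_threshold Convergence gates (defaults 1.01, 400).
#' @return An object of class `tvatoj_fit`.
#' @export
#' @examples
#' \donttest{
#' pop <- population_spec(n_participants = 4)
#' trials <- simulate_trials(make_design(1), sample_participants(pop), seed = 2)
#' fit <- fit_toj(trials, chains = 2, warmup = 200, iter = 200)
#' summary(fit)
#' }
fit_toj <- function(data,
                    family = c("tva", "logistic"),
                    constraint = c("free", "fixed_kappa", "fixed_C"),
                    priors = prior_spec(),
                    chains = 4, warmup = 1000, iter = 1000,
                    seed = 1,
                    quiet = TRUE,
                    rhat_threshold = 1.01, ess_threshold = 400) {
  family <- match.arg(family)
  constraint <- match.arg(constraint)
  if (family == "logistic" && constraint != "free")
    stop("constraints apply to the TVA family only", call. = FALSE)
  stopifnot(inherits(priors, "prior_spec"))
  check_trial_cells(data)
  if (!all(c("participant_id", "doa_ms") %in% names(data)))
    stop("`data` needs columns participant_id and doa_ms", call. = FALSE)

  pids <- sort(unique(data$participant_id))
  doas <- sort(unique(data$doa_ms))
  P <- length(pids); D <- length(doas)

  jd <- c(list(D = D, P = P, Ncell = nrow(data),
               pid = match(data$participant_id, pids),
               doa = match(data$doa_ms, doas),
               soa = data$soa_ms / 1000,
               N = as.integer(data$n_trials),
               y = as.integer(data$n_probe_first),
               eps = 1e-12),
          jags_prior_data(priors, family))

  monitors <- if (family == "tva") c("muC", "sdC", "muK", "sdK", "C", "K")
              else c("muPSS", "sdPSS", "muLS", "sdLS", "pss", "S")

  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(as.integer(seed)) %% 1000000L) * 1000L + ch)
  })

  adapt <- max(100L, floor(warmup / 2))
  burn <- max(0L, warmup - adapt)
  jm <- rjags::jags.model(textConnection(jags_model_string(family, constraint)),
                          data = jd, inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = quiet)
  if (burn > 0) update(jm, burn, progress.bar = if (quiet) "none" else "text")
  samples <- rjags::coda.samples(jm, monitors, n.iter = iter,
                                 progress.bar = if (quiet) "none" else "text")

  m <- as.matrix(samples)
  pop <- extract_population(m, family, constraint, D, doas)
  part <- extract_participants(m, family, P, D)
  diag <- population_diagnostics(samples, family)
  converged <- all(is.na(diag$rhat) | diag$rhat < rhat_threshold) &&
    all(diag$ess > ess_threshold)
  if (!converged)
    warning("fit did not pass convergence gates (max R-hat = ",
            round(max(diag$rhat, na.rm = TRUE), 3), ", min ESS = ",
            round(min(diag$ess)), "); results are flagged", call. = FALSE)

  structure(list(family = family, constraint = constraint,
                 doa_ms = doas, participant_ids = pids,
                 population = pop, participant = part,
                 diagnostics = diag, converged = converged,
                 priors = priors,
                 sampler = list(chains = chains, warmup = warmup,
                                iter = iter, seed = seed),
                 data = data),
            class = "tvatoj_fit")
}

# Pull a population-level parameter into an S x D (or S x 1 when shared)
# matrix from the stacked draw matrix.
pop_matrix <- function(m, base, D, doas) {
  vec_cols <- paste0(base, "[", seq_len(D), "]")
  if (all(vec_cols %in% colnames(m))) {
    out <- m[, vec_cols, drop = FALSE]
    colnames(out) <- paste0("doa", doas)
  } else {
    out <- m[, base, drop = FALSE]
    colnames(out) <- "all"
  }
  out
}

extract_population <- function(m, family, constraint, D, doas) {
  if (family == "tva") {
    list(mu_logC = pop_matrix(m, "muC", D, doas),
         sigma_logC = pop_matrix(m, "sdC", D, doas),
         mu_logK = pop_matrix(m, "muK", D, doas),
         sigma_logK = pop_matrix(m, "sdK", D, doas))
  } else {
    list(mu_pss = pop_matrix(m, "muPSS", D, doas),
         sigma_pss = pop_matrix(m, "sdPSS", D, doas),
         mu_logscale = pop_matrix(m, "muLS", D, doas),
         sigma_logscale = pop_matrix(m, "sdLS", D, doas))
  }
}

extract_participants <- function(m, family, P, D) {
  grab <- function(base) {
    arr <- array(NA_real_, c(nrow(m), P, D))
    for (i in seq_len(P)) for (d in seq_len(D))
      arr[, i, d] <- m[, sprintf("%s[%d,%d]", base, i, d)]
    arr
  }
  if (family == "tva") list(C = grab("C"), kappa = grab("K"))
  else list(pss = grab("pss"), scale = grab("S"))
}

population_diagnostics <- function(samples, family) {
  pat <- if (family == "tva") "^(muC|sdC|muK|sdK)(\\[|$)"
         else "^(muPSS|sdPSS|muLS|sdLS)(\\[|$)"
  nm <- grep(pat, coda::varnames(samples), value = TRUE)
  sub <- samples[, nm, drop = FALSE]
  rhat <- if (coda::nchain(samples) >= 2)
    coda::gelman.diag(sub, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  else rep(NA_real_, length(nm))
  ess <- coda::effectiveSize(sub)
  data.frame(parameter = nm, rhat = unname(rhat[nm]), ess = unname(ess[nm]),
             row.names = NULL)
}

#' Posterior draws of a population-level location parameter
#'
#' @param fit A [fit_toj()] result.
#' @param parameter `"C"`, `"kappa"` (TVA) or `"pss"`, `"scale"` (logistic).
#' @param scale `"natural"` maps latent locations to the parameter's own
#'   scale (exp for C, kappa and the logistic scale — the population
#'   *median* under the log-normal hierarchy); `"latent"` returns the raw
#'   location draws.
#' @return A draws x conditions matrix (one column per DOA, or `"all"` for a
#'   shared parameter).
#' @export
population_draws <- function(fit, parameter = c("C", "kappa", "pss", "scale"),
                             scale = c("natural", "latent")) {
  stopifnot(inherits(fit, "tvatoj_fit"))
  parameter <- match.arg(parameter)
  scale <- match.arg(scale)
  key <- switch(parameter, C = "mu_logC", kappa = "mu_logK",
                pss = "mu_pss", scale = "mu_logscale")
  if (is.null(fit$population[[key]]))
    stop("parameter `", parameter, "` is not part of a ", fit$family,
         " fit", call. = FALSE)
  x <- fit$population[[key]]
  if (scale == "natural" && parameter != "pss") x <- exp(x)
  x
}

#' @export
print.tvatoj_fit <- function(x, ...) {
  cat("Hierarchical TOJ fit —", x$family,
      if (x$family == "tva") paste0("(", x$constraint, ")"), "\n")
  cat(sprintf("  %d participants, DOA conditions: %s ms\n",
              length(x$participant_ids), paste(x$doa_ms, collapse = ", ")))
  cat(sprintf("  %d chains x %d draws; converged: %s (max R-hat %.3f, min ESS %.0f)\n",
              x$sampler$chains, x$sampler$iter, x$converged,
              max(x$diagnostics$rhat, na.rm = TRUE), min(x$diagnostics$ess)))
  print(summary(x), digits = 3)
  invisible(x)
}

#' @export
summary.tvatoj_fit <- function(object, mass = 0.95, ...) {
  pars <- if (object$family == "tva") c("C", "kappa") else c("pss", "scale")
  out <- do.call(rbind, lapply(pars, function(p) {
    dr <- population_draws(object, p)
    do.call(rbind, lapply(colnames(dr), function(cn) {
      h <- hdi(dr[, cn], mass)
      data.frame(parameter = p, condition = cn,
                 mean = mean(dr[, cn]), median = median(dr[, cn]),
                 hdi_lower = h[1], hdi_upper = h[2])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate datasets from the posterior (posterior predictive)
#'
#' Draws `ndraws` posterior parameter states and simulates one trial table
#' from each over the given design, using the fitted participant-level
#' parameters. Used for model checking.
#'
#' @param fit A [fit_toj()] result.
#' @param design A [toj_design()]; defaults to the cell structure of the
#'   fitted data. Its DOA levels must all be present in the fit.
#' @param ndraws Number of predictive datasets.
#' @param seed Integer seed (reproducible).
#' @return A list of `ndraws` trial tables.
#' @export
posterior_predictive <- function(fit, design = NULL, ndraws = 20, seed = 1) {
  stopifnot(inherits(fit, "tvatoj_fit"))
  if (is.null(design)) {
    cells <- unique(fit$data[, c("doa_ms", "soa_ms", "n_trials")])
  } else {
    stopifnot(inherits(design, "toj_design"))
    if (!all(design$doa_ms %in% fit$doa_ms))
      stop("design has DOA levels the fit does not cover", call. = FALSE)
    cells <- as.data.frame(design)
  }
  P <- length(fit$participant_ids)
  grid <- merge(data.frame(participant_id = fit$participant_ids), cells)
  grid <- grid[order(grid$participant_id, grid$doa_ms, grid$soa_ms), ]
  i_idx <- match(grid$participant_id, fit$participant_ids)
  d_idx <- match(grid$doa_ms, fit$doa_ms)
  dt <- grid$soa_ms / 1000
  S <- dim(fit$participant[[1]])[1]
  with_seed(seed, {
    picks <- sample.int(S, ndraws, replace = ndraws > S)
    lapply(picks, function(s) {
      p <- predictive_prob(fit, s, i_idx, d_idx, dt)
      out <- grid
      out$n_probe_first <- rbinom(nrow(grid), grid$n_trials, p)
      out <- out[, c("participant_id", "doa_ms", "soa_ms", "n_trials", "n_probe_first")]
      rownames(out) <- NULL
      class(out) <- c("toj_trials", "data.frame")
      out
    })
  })
}

# Model probability at one posterior draw for a vector of cells.
predictive_prob <- function(fit, s, i_idx, d_idx, dt) {
  if (fit$family == "tva") {
    Cv <- fit$participant$C[cbind(s, i_idx, d_idx)]
    Kv <- fit$participant$kappa[cbind(s, i_idx, d_idx)]
    vp <- Kv / (1 + Kv) * Cv
    p_probe_first(vp, Cv - vp, dt)
  } else {
    pssv <- fit$participant$pss[cbind(s, i_idx, d_idx)]
    sv <- fit$participant$scale[cbind(s, i_idx, d_idx)]
    plogis((pssv - dt) / sv)
  }
}
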