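#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything a run needs: the experimental design, the generating
#' population (for synthetic cohorts), priors, MCMC budget, model variants,
#' ROPE bounds, the global seed (per-stage seeds are derived from it by
#' fixed offsets: +0 participants, +1 trial simulation, +2... one per fitted
#' variant), and the output directory. Round-trips losslessly through YAML
#' via [write_config()] / [read_config()].
#'
#' @param experiment 1 (randomized) or 2 (blocked).
#' @param population A [population_spec()].
#' @param priors A [prior_spec()].
#' @param sampler List with `chains`, `warmup`, `iter`.
#' @param variants Model variants to fit: subset of `"free"`,
#'   `"fixed_kappa"`, `"fixed_C"`, `"logistic"`.
#' @param rope ROPE bounds for the effect stage.
#' @param seed Global integer seed.
#' @param outdir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1,
                            population = population_spec(),
                            priors = prior_spec(),
                            sampler = list(chains = 4, warmup = 1000, iter = 1000),
                            variants = c("free", "fixed_kappa", "fixed_C", "logistic"),
                            rope = c(-0.3, 0.3),
                            seed = 1L,
                            outdir = "tvatoj-run") {
  variants <- match.arg(variants, several.ok = TRUE)
  structure(list(experiment = experiment, population = population,
                 priors = priors, sampler = sampler, variants = variants,
                 rope = rope, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(experiment = raw$experiment,
                  population = do.call(population_spec, raw$population[
                    setdiff(names(raw$population), character())]),
                  priors = do.call(prior_spec, raw$priors),
                  sampler = raw$sampler,
                  variants = unlist(raw$variants),
                  rope = unlist(raw$rope),
                  seed = raw$seed,
                  outdir = raw$outdir)
}

pipeline_log <- function(outdir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  cat(line, "\n", file = file.path(outdir, "pipeline.log"), append = TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (draw a synthetic cohort and its trial
#' table), `fit` (fit the configured model variants), `compare` (PSIS-LOO
#' ranking of the fitted variants), `effects` (consecutive-DOA ROPE
#' decisions for C and kappa from the free TVA fit), and `report` (JSON
#' summary plus posterior-density and psychometric figures). Every run
#' archives its exact config (with an md5 provenance hash) and seed in the
#' output directory, so any artifact can be regenerated.
#'
#' Later stages need the in-memory products of earlier ones: `fit` loads
#' `trials.csv` from the output directory if `simulate` is not part of the
#' same call; `compare`, `effects` and `report` require `fit` in the same
#' call and raise a dependency error otherwise.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("simulate", "fit", "compare", "effects",
#'   "report")`, or `"all"`.
#' @return Invisibly, a list with the trial table, fits, loo table, effects
#'   and artifact paths.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "fit", "compare", "effects", "report")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")
  write_config(config, cfg_path)
  pipeline_log(out, "run start | stages=", paste(stages, collapse = ","),
               " | seed=", config$seed, " | config md5=",
               unname(tools::md5sum(cfg_path)))

  trials <- NULL
  fits <- list()
  loo_tab <- NULL
  effects <- NULL

  if ("simulate" %in% stages) {
    pop <- config$population
    pop$seed <- config$seed
    participants <- sample_participants(pop)
    design <- make_design(config$experiment)
    trials <- simulate_trials(design, participants, seed = config$seed + 1L)
    write_trial_table(trials, file.path(out, "trials.csv"))
    write.csv(participants, file.path(out, "participants_true.csv"),
              row.names = FALSE, quote = FALSE)
    pipeline_log(out, "simulate | ", nrow(trials), " cells, ",
                 pop$n_participants, " participants, experiment ",
                 config$experiment)
  }

  if ("fit" %in% stages) {
    if (is.null(trials)) {
      tp <- file.path(out, "trials.csv")
      if (!file.exists(tp))
        stop("fit stage needs trials: run `simulate` first or place trials.csv in the output directory",
             call. = FALSE)
      trials <- read_trial_table(tp)
    }
    for (k in seq_along(config$variants)) {
      v <- config$variants[k]
      fam <- if (v == "logistic") "logistic" else "tva"
      cons <- if (v == "logistic") "free" else v
      fit <- fit_toj(trials, family = fam, constraint = cons,
                     priors = config$priors,
                     chains = config$sampler$chains,
                     warmup = config$sampler$warmup,
                     iter = config$sampler$iter,
                     seed = config$seed + 1L + k)
      fits[[v]] <- fit
      write.csv(summary(fit), file.path(out, paste0("summary_", v, ".csv")),
                row.names = FALSE, quote = FALSE)
      n_iter <- config$sampler$iter
      draws_long <- do.call(rbind, lapply(names(fit$population), function(nm) {
        x <- fit$population[[nm]]  # chains stacked in order
        data.frame(parameter = nm,
                   condition = rep(colnames(x), each = nrow(x)),
                   chain = rep(rep(seq_len(config$sampler$chains),
                                   each = n_iter), ncol(x)),
                   iteration = rep(rep(seq_len(n_iter),
                                       config$sampler$chains), ncol(x)),
                   value = as.vector(x))
      }))
      write.csv(draws_long, file.path(out, paste0("posterior_", v, ".csv")),
                row.names = FALSE, quote = FALSE)
      pipeline_log(out, "fit | variant=", v, " | converged=", fit$converged,
                   " | seed=", config$seed + 1L + k)
    }
  }

  if ("compare" %in% stages) {
    if (length(fits) < 2)
      stop("compare stage needs at least two fitted variants in this call",
           call. = FALSE)
    loos <- lapply(fits, function(f) psis_loo(pointwise_loglik(f, trials)))
    loo_tab <- loo_compare(loos)
    jsonlite::write_json(loo_tab, file.path(out, "loo_compare.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    writeLines(c("Model comparison by looIC (smaller = better):",
                 utils::capture.output(print(loo_tab, row.names = FALSE))),
               file.path(out, "loo_compare.txt"))
    pipeline_log(out, "compare | best=", loo_tab$model[1])
  }

  if ("effects" %in% stages) {
    base_fit <- fits[["free"]] %||% Filter(function(f)
      f$family == "tva" && f$constraint == "free", fits)[1][[1]]
    if (is.null(base_fit))
      stop("effects stage needs a free TVA fit in this call", call. = FALSE)
    effects <- rbind(condition_effects(base_fit, "C", rope = config$rope),
                     condition_effects(base_fit, "kappa", rope = config$rope))
    jsonlite::write_json(effects, file.path(out, "effects.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    pipeline_log(out, "effects | ", sum(effects$verdict == "outside_rope"),
                 " comparison(s) outside ROPE")
  }

  if ("report" %in% stages) {
    if (length(fits) == 0)
      stop("report stage needs fits in this call", call. = FALSE)
    base_fit <- fits[["free"]] %||% fits[[1]]
    report <- list(
      seed = config$seed,
      convergence = lapply(fits, function(f)
        list(converged = f$converged,
             max_rhat = max(f$diagnostics$rhat, na.rm = TRUE),
             min_ess = min(f$diagnostics$ess))),
      population_summary = summary(base_fit),
      loo = loo_tab,
      effects = effects
    )
    jsonlite::write_json(report, file.path(out, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    for (parameter in if (base_fit$family == "tva") c("C", "kappa") else c("pss", "scale")) {
      fp <- file.path(out, paste0("fig_", parameter, ".pdf"))
      ggplot2::ggsave(fp, plot_posterior(base_fit, parameter),
                      width = 7, height = 4)
    }
    ggplot2::ggsave(file.path(out, "fig_psychometric.pdf"),
                    plot_psychometric(base_fit), width = 7, height = 4)
    pipeline_log(out, "report | written")
  }

  pipeline_log(out, "run end")
  invisible(list(trials = trials, fits = fits, loo = loo_tab,
                 effects = effects, outdir = out))
}
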