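#' Construct a DOA-by-SOA temporal-order-judgment design
#'
#' A design is the grid of display-onset-asynchrony (DOA) conditions crossed
#' with stimulus-onset-asynchronies (SOA), with per-cell trial counts and
#' optional excluded cells. [make_design()] returns the two canonical
#' designs: five DOA levels (50, 100, 200, 400, 800 ms) crossed with SOAs
#' \{-80, -40, 0, 40, 80\} ms, 34 trials per SOA except 68 at SOA 0, and the
#' (DOA 50, +80 ms) cell excluded because the reference event would have to
#' precede the salience display. The two experiments differ only in
#' presentation order: fully randomized (experiment 1) versus DOA-blocked
#' (experiment 2); the analysis consumes counts, so presentation is carried
#' as metadata only.
#'
#' @param doa_ms DOA levels in ms.
#' @param soa_ms SOA levels in ms (negative = probe first).
#' @param reps_per_soa Trials per non-zero SOA cell.
#' @param reps_at_zero_soa Trials at SOA 0.
#' @param exclusions Data frame with columns `doa_ms`, `soa_ms` of cells to
#'   drop, or NULL.
#' @param presentation `"randomized"` or `"blocked"`.
#' @return A data frame of class `toj_design` with columns `doa_ms`,
#'   `soa_ms`, `n_trials` and a `presentation` attribute.
#' @export
#' @examples
#' d <- make_design(1)
#' subset(d, doa_ms == 50)
toj_design <- function(doa_ms = c(50, 100, 200, 400, 800),
                       soa_ms = c(-80, -40, 0, 40, 80),
                       reps_per_soa = 34L,
                       reps_at_zero_soa = 68L,
                       exclusions = data.frame(doa_ms = 50, soa_ms = 80),
                       presentation = c("randomized", "blocked")) {
  presentation <- match.arg(presentation)
  if (reps_per_soa < 1L || reps_at_zero_soa < 1L)
    stop("trial counts must be positive integers", call. = FALSE)
  g <- expand.grid(soa_ms = soa_ms, doa_ms = doa_ms,
                   KEEP.OUT.ATTRS = FALSE)[, c("doa_ms", "soa_ms")]
  if (!is.null(exclusions) && nrow(exclusions)) {
    drop <- paste(g$doa_ms, g$soa_ms) %in% paste(exclusions$doa_ms, exclusions$soa_ms)
    g <- g[!drop, , drop = FALSE]
  }
  g$n_trials <- ifelse(g$soa_ms == 0, as.integer(reps_at_zero_soa),
                       as.integer(reps_per_soa))
  rownames(g) <- NULL
  structure(g, presentation = presentation, class = c("toj_design", "data.frame"))
}

#' @rdname toj_design
#' @param experiment `1` (fully randomized presentation) or `2` (blocked).
#' @export
make_design <- function(experiment = 1) {
  if (!experiment %in% c(1, 2))
    stop("unknown experiment id: ", experiment, call. = FALSE)
  toj_design(presentation = if (experiment == 2) "blocked" else "randomized")
}

#' Population-level generating distributions for a synthetic cohort
#'
#' Ground truth for the synthetic-data generator: per-DOA population medians
#' of capacity C and salience kappa, with log-normal between-participant
#' variation. The default scenario mirrors the qualitative pattern reported
#' for this paradigm — capacity strongly reduced at short DOAs, rising
#' steeply to 200 ms and flat thereafter, with salience in the 2–2.5 range
#' varying only mildly — around the normative values C ~ 60 Hz and
#' kappa ~ 2–2.5 for a 90 degree orientation contrast.
#'
#' @param doa_ms DOA levels in ms.
#' @param C_median Per-DOA population median of C (Hz); recycled if scalar.
#' @param kappa_median Per-DOA population median of kappa; recycled if scalar.
#' @param sigma_logC,sigma_logK Between-participant SDs on the log scale
#'   (non-negative).
#' @param n_participants Cohort size.
#' @param seed Integer seed used by [sample_participants()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(doa_ms = c(50, 100, 200, 400, 800),
                            C_median = c(30, 45, 58, 60, 60),
                            kappa_median = c(2.5, 2.5, 2.3, 2.5, 2.0),
                            sigma_logC = 0.2,
                            sigma_logK = 0.2,
                            n_participants = 30L,
                            seed = 1L) {
  C_median <- rep_len(C_median, length(doa_ms))
  kappa_median <- rep_len(kappa_median, length(doa_ms))
  if (any(C_median <= 0) || any(kappa_median < 1))
    stop("C medians must be positive and kappa medians >= 1", call. = FALSE)
  if (sigma_logC < 0 || sigma_logK < 0)
    stop("log-scale spreads must be non-negative", call. = FALSE)
  if (n_participants < 1L) stop("`n_participants` must be >= 1", call. = FALSE)
  structure(list(doa_ms = doa_ms, C_median = C_median,
                 kappa_median = kappa_median,
                 sigma_logC = sigma_logC, sigma_logK = sigma_logK,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw participant-level true parameters from a population spec
#'
#' Each participant gets one (C, kappa) pair per DOA condition, drawn
#' log-normally around the population medians. Reproducible given the seed
#' stored in the spec.
#'
#' @param pop A [population_spec()] object.
#' @return A data frame with columns `participant_id`, `doa_ms`, `C`,
#'   `kappa` (one row per participant x DOA).
#' @export
sample_participants <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  P <- pop$n_participants
  D <- length(pop$doa_ms)
  with_seed(pop$seed, {
    logC <- rnorm(P * D, rep(log(pop$C_median), each = P), pop$sigma_logC)
    logK <- rnorm(P * D, rep(log(pop$kappa_median), each = P), pop$sigma_logK)
    data.frame(
      participant_id = rep(seq_len(P), times = D),
      doa_ms = rep(pop$doa_ms, each = P),
      C = exp(logC),
      kappa = exp(logK)
    )
  })
}

#' Simulate binomial TOJ counts for a cohort on a design
#'
#' The forward model: for every participant and design cell, the probe-first
#' count is binomial with the participant's closed-form probe-first
#' probability at that cell's SOA (the participant's C and kappa for that
#' DOA condition partition into rates, which enter the race-model
#' psychometric function).
#'
#' @param design A [toj_design()].
#' @param participants Output of [sample_participants()] (or any data frame
#'   with `participant_id`, `doa_ms`, `C`, `kappa` covering all design DOAs).
#' @param seed Integer seed for the binomial draws.
#' @return A data frame of class `toj_trials` with columns `participant_id`,
#'   `doa_ms`, `soa_ms`, `n_trials`, `n_probe_first`.
#' @export
#' @examples
#' pop <- population_spec(n_participants = 3)
#' trials <- simulate_trials(make_design(1), sample_participants(pop), seed = 7)
#' head(trials)
simulate_trials <- function(design, participants, seed = 1L) {
  stopifnot(inherits(design, "toj_design"))
  need <- c("participant_id", "doa_ms", "C", "kappa")
  if (!all(need %in% names(participants)))
    stop("`participants` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  missing_doa <- setdiff(design$doa_ms, participants$doa_ms)
  if (length(missing_doa))
    stop("participants lack parameters for DOA level(s): ",
         paste(missing_doa, collapse = ", "), call. = FALSE)
  cells <- merge(participants, as.data.frame(design), by = "doa_ms")
  cells <- cells[order(cells$participant_id, cells$doa_ms, cells$soa_ms), ]
  vp <- cells$kappa / (1 + cells$kappa) * cells$C
  p <- p_probe_first(vp, cells$C - vp, cells$soa_ms / 1000)
  cells$n_probe_first <- with_seed(seed, rbinom(nrow(cells), cells$n_trials, p))
  out <- cells[, c("participant_id", "doa_ms", "soa_ms", "n_trials", "n_probe_first")]
  rownames(out) <- NULL
  class(out) <- c("toj_trials", "data.frame")
  out
}

#' Convert between aggregated and long (one row per trial) representations
#'
#' The aggregated table (one row per participant x DOA x SOA cell with
#' binomial counts) and the long table (one row per trial with a binary
#' `probe_first` response) are lossless inverses up to trial order.
#'
#' @param trials An aggregated trial table.
#' @return `trials_to_long()`: data frame with `participant_id`, `doa_ms`,
#'   `soa_ms`, `probe_first` (0/1). `long_to_trials()`: the aggregated table.
#' @export
trials_to_long <- function(trials) {
  check_trial_cells(trials)
  idx <- rep(seq_len(nrow(trials)), trials$n_trials)
  long <- trials[idx, c("participant_id", "doa_ms", "soa_ms")]
  long$probe_first <- unlist(lapply(seq_len(nrow(trials)), function(i) {
    c(rep(1L, trials$n_probe_first[i]),
      rep(0L, trials$n_trials[i] - trials$n_probe_first[i]))
  }))
  rownames(long) <- NULL
  long
}

#' @rdname trials_to_long
#' @param long A long-format table with column `probe_first`.
#' @export
long_to_trials <- function(long) {
  need <- c("participant_id", "doa_ms", "soa_ms", "probe_first")
  stopifnot(all(need %in% names(long)))
  agg <- aggregate(cbind(n_trials = rep(1L, nrow(long)),
                         n_probe_first = long$probe_first)
                   ~ participant_id + doa_ms + soa_ms,
                   data = long, FUN = sum)
  agg <- agg[order(agg$participant_id, agg$doa_ms, agg$soa_ms), ]
  rownames(agg) <- NULL
  class(agg) <- c("toj_trials", "data.frame")
  agg
}

#' Read or write a trial table as delimited text
#'
#' CSV schema: header `participant_id,doa_ms,soa_ms,n_trials,n_probe_first`,
#' one row per cell.
#'
#' @param trials A trial table.
#' @param path File path.
#' @export
write_trial_table <- function(trials, path) {
  check_trial_cells(trials)
  write.csv(as.data.frame(trials), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trials <- read.csv(path)
  check_trial_cells(trials)
  class(trials) <- c("toj_trials", "data.frame")
  trials
}
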