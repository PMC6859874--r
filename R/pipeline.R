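#' Run the full DQ + HMM analysis on a simulated cohort
#'
#' Convenience driver for end-to-end evaluation: builds the panel-wide and
#' per-pool baselines from the cohort's reference samples, fits all three
#' DQ modes and the copy-number HMM (on DQ values normalized against the
#' dedicated HMM baseline) to the test samples, and scores the results
#' against the cohort's truth table.
#'
#' Two positivity notions are reported, matching how validation studies are
#' scored:
#' \itemize{
#'   \item sample-level positivity — a test sample is DQ-positive when any
#'     of the three DQ evaluations yields at least one (hard or soft) call;
#'     this drives the confusion counts and specificity;
#'   \item event detection — a true event counts as detected by a caller
#'     only when that caller produced a call of the matching type
#'     overlapping the event by at least one amplicon (DQ detection is
#'     scored on the per-pool mode, the cleanest of the three).
#' }
#'
#' @param cohort A `sim_cohort` carrying `reference_ids`,
#'   `hmm_reference_ids` and `test_ids` (see [validation_scenario()]).
#' @param hmm_min_amplicons Minimum segment length for the HMM caller.
#' @param soft_sd_multiplier,soft_min_run Soft-rule settings for the DQ
#'   caller.
#' @return A list of class `lgr_analysis` with the three `dq_fit`s, the
#'   `hmm_fit`, the pooled DQ call table, per-sample `positivity`,
#'   `concordance` ([match_calls()]), `triage` decisions, `detection` (one
#'   row per true event with `dq_detected`/`hmm_detected`), `confusion` and
#'   `metrics` for the DQ caller.
#' @export
analyze_cohort <- function(cohort, hmm_min_amplicons = 2L,
                           soft_sd_multiplier = 1, soft_min_run = 3L) {
  stopifnot(inherits(cohort, "sim_cohort"),
            !is.null(cohort$reference_ids), !is.null(cohort$test_ids))
  panel <- cohort$panel
  counts <- cohort$counts
  tests <- cohort$test_ids
  test_counts <- counts[tests, , drop = FALSE]
  base1 <- build_baseline(counts, panel, cohort$reference_ids,
                          "B1_panel_wide")
  base2 <- build_baseline(counts, panel, cohort$reference_ids,
                          "B2_per_pool")
  fits <- list(
    dqa = dq_fit(test_counts, panel, "dqa",
                 soft_sd_multiplier = soft_sd_multiplier,
                 soft_min_run = soft_min_run),
    dqb1 = dq_fit(test_counts, panel, "dqb1", baseline = base1,
                  soft_sd_multiplier = soft_sd_multiplier,
                  soft_min_run = soft_min_run),
    dqb2 = dq_fit(test_counts, panel, "dqb2", baseline = base2,
                  soft_sd_multiplier = soft_sd_multiplier,
                  soft_min_run = soft_min_run))
  dq_calls <- do.call(rbind, lapply(names(fits), function(m) {
    calls <- fits[[m]]$calls
    if (nrow(calls) > 0L) calls$mode <- m else calls$mode <- character()
    calls
  }))
  hmm_base_ids <- cohort$hmm_reference_ids
  if (is.null(hmm_base_ids)) hmm_base_ids <- cohort$reference_ids
  # per-pool normalization for the HMM input: pool batch effects otherwise
  # masquerade as shallow multi-amplicon dosage shifts along the path
  hmm_base <- build_baseline(counts, panel, hmm_base_ids, "B2_per_pool")
  hmm_input <- dq_fit(test_counts, panel, "dqb2", baseline = hmm_base)
  hmm <- hmm_fit(hmm_input, min_amplicons = hmm_min_amplicons)
  positivity <- sample_positivity(dq_calls, sample_ids = tests)
  truth <- cohort$truth[match(tests, cohort$truth$sample_id), ,
                        drop = FALSE]
  truth_pos <- stats::setNames(truth$lgr_status, tests)
  conf <- confusion(positivity, truth_pos)
  concord <- match_calls(dq_calls, hmm$calls, panel, sample_ids = tests)
  detection <- NULL
  if (!is.null(cohort$events)) {
    detection <- cohort$events
    detection$dq_detected <- vapply(seq_len(nrow(detection)), function(i)
      event_detected(fits$dqb2$calls, panel, detection[i, ]), logical(1L))
    detection$hmm_detected <- vapply(seq_len(nrow(detection)), function(i)
      event_detected(hmm$calls, panel, detection[i, ]), logical(1L))
  }
  structure(list(fits = fits, hmm = hmm, dq_calls = dq_calls,
                 positivity = positivity, concordance = concord,
                 triage = triage(concord), detection = detection,
                 confusion = conf, metrics = compute_metrics(conf)),
            class = "lgr_analysis")
}

# does any matching-type call overlap the event? (internal)
event_detected <- function(calls, panel, event) {
  calls <- calls[calls$sample_id == event$sample_id &
                   calls$type == event$type, , drop = FALSE]
  if (nrow(calls) == 0L) return(FALSE)
  f <- match(calls$first_amplicon, panel$amplicon_id)
  l <- match(calls$last_amplicon, panel$amplicon_id)
  any(pmax(f, event$first) <= pmin(l, event$last))
}

#' @export
print.lgr_analysis <- function(x, ...) {
  cat("LGR cohort analysis: ", length(x$positivity), " test samples, ",
      sum(x$positivity), " DQ-positive\n", sep = "")
  if (!is.null(x$detection)) {
    cat("  event detection (DQ per-pool / HMM): ",
        sum(x$detection$dq_detected), "/", nrow(x$detection), " vs ",
        sum(x$detection$hmm_detected), "/", nrow(x$detection), "\n",
        sep = "")
  }
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}
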