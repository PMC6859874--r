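#' Maximal-run CNV segmentation of a single DQ profile
#'
#' Vector-level core of the DQ caller.  Two tiers of evidence are produced:
#' \describe{
#'   \item{hard}{Maximal runs (length >= 1) of amplicons beyond the
#'     mean +/- 2 SD thresholds `lo`/`hi`, all in the same direction.}
#'   \item{soft}{Maximal runs of at least `soft_min_run` consecutive
#'     amplicons that all sit beyond the softer `center +/-
#'     soft_sd_multiplier * sd` band in the same direction.  A soft run that
#'     consists entirely of hard-flagged amplicons is already reported as a
#'     hard call and is not duplicated; a run mixing hard and sub-threshold
#'     amplicons is reported with evidence `"soft"` over its full extent.}
#' }
#' The soft tier rescues consistent multi-amplicon dosage drops in noisy
#' (e.g. degraded-DNA) profiles that never cross the hard threshold.
#'
#' @param dq Numeric DQ vector in panel order.
#' @param center,sd Per-amplicon center and SD of the reference DQ
#'   distribution (recycled if scalar).
#' @param soft_sd_multiplier Soft band half-width in SD units (default 1).
#' @param soft_min_run Minimum length of a soft run (default 3).
#' @return Data frame with columns `first`, `last` (panel indices), `type`
#'   (`"del"`/`"dup"`), `evidence` (`"hard"`/`"soft"`), `n_amplicons`,
#'   `score` (mean |log2 dq| over the run), ordered by `first`.
#' @export
cnv_runs <- function(dq, center, sd, soft_sd_multiplier = 1,
                     soft_min_run = 3L) {
  n <- length(dq)
  center <- rep_len(center, n)
  sd <- rep_len(sd, n)
  lo <- center - 2 * sd
  hi <- center + 2 * sd
  soft_lo <- center - soft_sd_multiplier * sd
  soft_hi <- center + soft_sd_multiplier * sd
  hard <- ifelse(dq < lo, "del", ifelse(dq > hi, "dup", "n"))
  soft <- ifelse(dq < soft_lo, "del", ifelse(dq > soft_hi, "dup", "n"))
  score <- function(i, j) mean(abs(log2(pmax(dq[i:j], 1e-3))))
  out <- list()
  r <- rle(hard)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "n") next
    out[[length(out) + 1L]] <- data.frame(
      first = starts[k], last = ends[k], type = r$values[k],
      evidence = "hard", n_amplicons = r$lengths[k],
      score = score(starts[k], ends[k]))
  }
  r <- rle(soft)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "n" || r$lengths[k] < soft_min_run) next
    if (all(hard[starts[k]:ends[k]] == r$values[k])) next  # pure hard run
    out[[length(out) + 1L]] <- data.frame(
      first = starts[k], last = ends[k], type = r$values[k],
      evidence = "soft", n_amplicons = r$lengths[k],
      score = score(starts[k], ends[k]))
  }
  if (length(out) == 0L) {
    return(data.frame(first = integer(), last = integer(),
                      type = character(), evidence = character(),
                      n_amplicons = integer(), score = numeric()))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$first, out$evidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge flagged amplicons of a DQ fit into CNV calls
#'
#' Applies [cnv_runs()] to every sample of a [dq_fit()] and annotates the
#' runs with amplicon ids, exon and genomic spans from the panel.
#'
#' @param fit A `dq_fit`.
#' @param soft_sd_multiplier,soft_min_run Override the soft-rule settings
#'   stored in the fit.
#' @return Data frame with one row per call: `sample_id`, `caller` (`"DQ"`),
#'   `type`, `first_amplicon`, `last_amplicon`, `exon_span`, `genomic_span`,
#'   `n_amplicons`, `evidence`, `score`; sorted by sample then panel
#'   position.
#' @export
call_cnvs <- function(fit, soft_sd_multiplier = fit$soft_sd_multiplier,
                      soft_min_run = fit$soft_min_run) {
  stopifnot(inherits(fit, "dq_fit"))
  panel <- fit$panel
  res <- lapply(rownames(fit$dq), function(s) {
    runs <- cnv_runs(fit$dq[s, ], fit$center, fit$sd,
                     soft_sd_multiplier, soft_min_run)
    if (nrow(runs) == 0L) return(NULL)
    annotate_calls(runs, panel, sample_id = s, caller = "DQ")
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- annotate_calls(NULL, panel)
  res
}

# turn index runs into the standard call table (internal)
annotate_calls <- function(runs, panel, sample_id = character(),
                           caller = character()) {
  if (is.null(runs) || nrow(runs) == 0L) {
    return(data.frame(sample_id = character(), caller = character(),
                      type = character(), first_amplicon = character(),
                      last_amplicon = character(), exon_span = character(),
                      genomic_span = character(), n_amplicons = integer(),
                      evidence = character(), score = numeric()))
  }
  exon_span <- mapply(function(i, j) {
    a <- panel$exon_label[i]
    b <- panel$exon_label[j]
    if (a == b) a else paste0(a, "-", b)
  }, runs$first, runs$last)
  genomic_span <- mapply(function(i, j) {
    # display 1-based inclusive from 0-based half-open storage
    paste0(panel$chrom[i], ":", panel$start[i] + 1L, "-", panel$end[j])
  }, runs$first, runs$last)
  data.frame(sample_id = sample_id, caller = caller, type = runs$type,
             first_amplicon = panel$amplicon_id[runs$first],
             last_amplicon = panel$amplicon_id[runs$last],
             exon_span = exon_span, genomic_span = genomic_span,
             n_amplicons = runs$n_amplicons, evidence = runs$evidence,
             score = runs$score)
}

#' Per-sample quality control on a DQ fit
#'
#' Counts the amplicons outside the hard threshold band for each sample;
#' a sample whose outlier fraction exceeds `degraded_threshold` is flagged
#' degraded (the many-peaks-out-of-threshold profile of low-quality DNA),
#' meaning its hard calls deserve scrutiny and the soft consecutive-run
#' evidence becomes the more reliable signal.
#'
#' @param fit A `dq_fit`.
#' @param degraded_threshold Outlier-fraction cutoff (default from the fit).
#' @return Data frame with `sample_id`, `n_outliers`, `outlier_fraction`,
#'   `degraded`.
#' @export
sample_qc <- function(fit, degraded_threshold = fit$degraded_threshold) {
  stopifnot(inherits(fit, "dq_fit"))
  n_out <- rowSums(fit$flags != "normal")
  frac <- n_out / ncol(fit$flags)
  data.frame(sample_id = rownames(fit$dq), n_outliers = unname(n_out),
             outlier_fraction = unname(frac),
             degraded = unname(frac > degraded_threshold))
}
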