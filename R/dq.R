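#' Fit per-amplicon dosage quotients for a cohort
#'
#' The dosage quotient (DQ) of a sample at an amplicon is the sample's
#' normalized coverage fraction divided by a reference average of the same
#' fraction; it is ~1 for two copies, ~0.5 for a heterozygous deletion and
#' ~1.5 for a heterozygous duplication.  Three modes are available:
#'
#' \describe{
#'   \item{`"dqa"`}{Intra-chip: the reference average for each amplicon is
#'     the mean normalized fraction over all samples in `counts` (the
#'     co-sequenced chip, including the sample under test).  Per-amplicon
#'     thresholds come from the cross-sample DQ distribution.  Requires at
#'     least `min_chip_samples` samples.}
#'   \item{`"dqb1"`}{External baseline, panel-wide normalization.}
#'   \item{`"dqb2"`}{External baseline, per-primer-pool normalization, which
#'     absorbs per-pool batch effects.}
#' }
#'
#' Thresholds follow the mean +/- 2 SD rule, expressed on the DQ scale: an
#' amplicon is flagged as deleted when `dq < lo` and duplicated when
#' `dq > hi`, with `lo = center - 2*sd`, `hi = center + 2*sd` where `center`
#' and `sd` describe the per-amplicon reference DQ distribution (for the
#' baseline modes `center = 1`, `sd = baseline sd/mean`).  Ties sit inside
#' the normal band.  Contiguous flagged runs become calls via [call_cnvs()],
#' which also applies the consecutive-amplicon soft rule; [sample_qc()]
#' screens for degraded-DNA profiles.
#'
#' @param counts Samples x amplicons count matrix (see [read_coverage()]).
#' @param panel The matching `amplicon_panel`.
#' @param mode `"dqb2"`, `"dqb1"` or `"dqa"`.
#' @param baseline A `dq_baseline` (required for the dqb modes unless
#'   `reference_ids` is given, in which case it is built from those rows of
#'   `counts` and the remaining samples are fitted).
#' @param reference_ids Optional reference sample ids used to build the
#'   baseline in situ.
#' @param soft_sd_multiplier,soft_min_run Defaults for the soft run rule,
#'   stored in the fit and used by [call_cnvs()].
#' @param degraded_threshold Outlier fraction above which [sample_qc()]
#'   declares a sample degraded.
#' @param min_chip_samples Minimum cohort size for `"dqa"`.
#' @param sd_floor_frac SD floor (fraction of the center) for `"dqa"`
#'   thresholds; baseline modes inherit the floor from [build_baseline()].
#' @return An object of class `dq_fit`: list with `dq` (samples x amplicons
#'   matrix), `center`, `sd`, `lo`, `hi` (per-amplicon), `flags` (character
#'   matrix), `calls` (data frame, see [call_cnvs()]), `qc` (data frame, see
#'   [sample_qc()]), plus `mode`, `scope`, `panel` and the soft-rule
#'   settings.
#' @seealso [call_cnvs()], [sample_qc()], [hmm_fit()]
#' @examples
#' panel <- simulate_panel(30)
#' sim <- simulate_cohort(panel, n_samples = 12, seed = 1)
#' base <- build_baseline(sim$counts, panel, rownames(sim$counts)[1:8])
#' fit <- dq_fit(sim$counts[9:12, ], panel, mode = "dqb2", baseline = base)
#' summary(fit)
#' @export
dq_fit <- function(counts, panel, mode = c("dqb2", "dqb1", "dqa"),
                   baseline = NULL, reference_ids = NULL,
                   soft_sd_multiplier = 1, soft_min_run = 3L,
                   degraded_threshold = 0.10, min_chip_samples = 8L,
                   sd_floor_frac = 0.01) {
  mode <- match.arg(mode)
  counts <- validate_coverage(counts, panel)
  if (mode == "dqa") {
    if (nrow(counts) < min_chip_samples) {
      stop("dqa mode needs at least ", min_chip_samples,
           " co-sequenced samples (got ", nrow(counts),
           "); use a dqb mode with an external baseline instead")
    }
    norm <- normalize_coverage(counts, panel, "panel_wide")
    ref_mean <- colMeans(norm)
    if (any(ref_mean <= 0)) {
      stop("amplicon(s) with zero mean coverage on the chip: ",
           paste(colnames(norm)[ref_mean <= 0], collapse = ", "))
    }
    dq <- sweep(norm, 2L, ref_mean, "/")
    center <- colMeans(dq)                  # identically 1 by construction
    sd_dq <- pmax(apply(dq, 2L, stats::sd), sd_floor_frac * center)
    scope <- "panel_wide"
    baseline_info <- list(mode = "intra_chip", n_reference = nrow(counts))
  } else {
    if (is.null(baseline)) {
      if (is.null(reference_ids)) {
        stop("mode '", mode, "' needs a baseline or reference_ids")
      }
      baseline <- build_baseline(counts, panel, reference_ids,
                                 mode = if (mode == "dqb2") "B2_per_pool"
                                        else "B1_panel_wide")
      counts <- counts[setdiff(rownames(counts), reference_ids), ,
                       drop = FALSE]
    }
    expected <- if (mode == "dqb2") "B2_per_pool" else "B1_panel_wide"
    if (!identical(baseline$mode, expected)) {
      stop("baseline mode ", baseline$mode, " does not match dq mode ", mode)
    }
    if (!identical(baseline$amplicon_id, panel$amplicon_id)) {
      stop("baseline amplicons do not match the panel")
    }
    scope <- baseline$scope
    norm <- normalize_coverage(counts, panel, scope)
    dq <- sweep(norm, 2L, baseline$mean, "/")
    center <- rep(1, ncol(dq))
    sd_dq <- baseline$sd / baseline$mean
    baseline_info <- baseline[c("mode", "n_reference", "reference_ids")]
  }
  names(center) <- names(sd_dq) <- colnames(dq)
  lo <- center - 2 * sd_dq
  hi <- center + 2 * sd_dq
  fit <- structure(list(dq = dq, center = center, sd = sd_dq,
                        lo = lo, hi = hi,
                        mode = mode, scope = scope, panel = panel,
                        baseline_info = baseline_info,
                        soft_sd_multiplier = soft_sd_multiplier,
                        soft_min_run = as.integer(soft_min_run),
                        degraded_threshold = degraded_threshold),
                   class = "dq_fit")
  fit$flags <- flag_amplicons(dq, lo, hi)
  fit$calls <- call_cnvs(fit)
  fit$qc <- sample_qc(fit)
  fit
}

#' Hard deletion/duplication flags from DQ values and thresholds
#'
#' Strict inequalities: a value exactly on a threshold is normal.
#'
#' @param dq Numeric vector or samples x amplicons matrix of DQ values.
#' @param lo,hi Per-amplicon thresholds (recycled across samples).
#' @return Character vector/matrix over `{"normal","del_hard","dup_hard"}`.
#' @export
flag_amplicons <- function(dq, lo, hi) {
  if (any(lo >= hi)) stop("thresholds must satisfy lo < hi")
  f <- function(x) ifelse(x < lo, "del_hard", ifelse(x > hi, "dup_hard",
                                                     "normal"))
  if (is.matrix(dq)) {
    out <- t(apply(dq, 1L, f))
    dimnames(out) <- dimnames(dq)
    out
  } else {
    f(dq)
  }
}

#' @export
print.dq_fit <- function(x, ...) {
  cat("DQ fit (mode ", x$mode, ", ", x$scope, " normalization): ",
      nrow(x$dq), " sample(s) x ", ncol(x$dq), " amplicons\n", sep = "")
  cat("  calls: ", nrow(x$calls), " (",
      sum(x$calls$evidence == "hard"), " hard, ",
      sum(x$calls$evidence == "soft"), " soft); degraded samples: ",
      sum(x$qc$degraded), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dq_fit <- function(object, ...) {
  qc <- object$qc
  qc$n_calls <- vapply(qc$sample_id, function(s)
    sum(object$calls$sample_id == s), integer(1L))
  structure(list(mode = object$mode, qc = qc, calls = object$calls),
            class = "summary.dq_fit")
}

#' @export
print.summary.dq_fit <- function(x, ...) {
  cat("DQ fit summary (mode ", x$mode, ")\n", sep = "")
  print(x$qc, row.names = FALSE)
  if (nrow(x$calls) > 0L) {
    cat("\nCalls:\n")
    print(x$calls[, c("sample_id", "type", "exon_span", "n_amplicons",
                      "evidence", "score")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dq_fit <- function(object, ...) object$dq

#' @export
residuals.dq_fit <- function(object, epsilon = 1e-3, ...) {
  log2(pmax(object$dq, epsilon))
}

#' Plot a sample's DQ profile with threshold bands
#'
#' @param x A `dq_fit`.
#' @param sample Sample id or row index (default: first sample).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dq_fit <- function(x, sample = 1L, ...) {
  dq <- x$dq[sample, ]
  idx <- seq_along(dq)
  graphics::plot(idx, dq, type = "h", xlab = "amplicon (panel order)",
                 ylab = "dosage quotient",
                 ylim = range(0, dq, x$hi, 1.6),
                 main = paste0(rownames(x$dq)[if (is.numeric(sample)) sample
                                              else match(sample,
                                                         rownames(x$dq))],
                               " (", x$mode, ")"), ...)
  graphics::lines(idx, x$lo, col = "red", lty = 2L)
  graphics::lines(idx, x$hi, col = "red", lty = 2L)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}
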