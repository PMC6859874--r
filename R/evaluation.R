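#' Per-sample concordance between DQ and HMM calls
#'
#' @param dq_calls,hmm_calls Call tables in the standard format (see
#'   [call_cnvs()]); `hmm_calls` may be empty.
#' @param panel The `amplicon_panel` the calls refer to.
#' @param sample_ids Sample universe; defaults to the union of samples seen
#'   in the two call sets.
#' @return Data frame with `sample_id`, `dq_positive`, `hmm_positive`,
#'   `shared_region` (TRUE iff some DQ call and some HMM call of the sample
#'   overlap in at least one amplicon).
#' @export
match_calls <- function(dq_calls, hmm_calls, panel, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(c(dq_calls$sample_id, hmm_calls$sample_id)))
  }
  idx <- function(calls) {
    calls$first <- match(calls$first_amplicon, panel$amplicon_id)
    calls$last <- match(calls$last_amplicon, panel$amplicon_id)
    if (anyNA(calls$first) || anyNA(calls$last)) {
      stop("call refers to amplicon(s) absent from the panel")
    }
    calls
  }
  dq_calls <- idx(dq_calls)
  hmm_calls <- idx(hmm_calls)
  out <- lapply(sample_ids, function(s) {
    d <- dq_calls[dq_calls$sample_id == s, , drop = FALSE]
    h <- hmm_calls[hmm_calls$sample_id == s, , drop = FALSE]
    shared <- FALSE
    if (nrow(d) > 0L && nrow(h) > 0L) {
      for (i in seq_len(nrow(d))) {
        if (any(pmax(d$first[i], h$first) <= pmin(d$last[i], h$last))) {
          shared <- TRUE
          break
        }
      }
    }
    data.frame(sample_id = s, dq_positive = nrow(d) > 0L,
               hmm_positive = nrow(h) > 0L, shared_region = shared)
  })
  do.call(rbind, out)
}

#' Triage samples for orthogonal MLPA confirmation
#'
#' Decision rule over the per-sample concordance of the two callers:
#' DQ-negative samples are reported negative (the DQ caller's negative
#' predictive value is what licenses skipping the wet-lab assay); samples
#' positive by both callers with overlapping regions can go straight to a
#' confirmation assay or breakpoint characterization; every other
#' DQ-positive sample needs MLPA.  HMM-positive/DQ-negative samples are
#' reported negative but carry a review flag.
#'
#' @param concordance Output of [match_calls()].
#' @return Data frame with `sample_id`, `decision` (one of
#'   `"REPORT_NEGATIVE"`, `"MLPA_REQUIRED"`, `"DIRECT_CONFIRMATION"`),
#'   `rationale`, `review_flag`.
#' @export
triage <- function(concordance) {
  decide <- function(dqp, hmmp, shared) {
    if (!dqp) {
      c("REPORT_NEGATIVE",
        if (hmmp) "DQ negative; HMM-only positive flagged for review"
        else "DQ negative")
    } else if (hmmp && shared) {
      c("DIRECT_CONFIRMATION",
        "DQ and HMM positive with overlapping region")
    } else if (hmmp) {
      c("MLPA_REQUIRED", "DQ and HMM positive but regions disjoint")
    } else {
      c("MLPA_REQUIRED", "DQ positive only")
    }
  }
  res <- t(mapply(decide, concordance$dq_positive, concordance$hmm_positive,
                  concordance$shared_region))
  data.frame(sample_id = concordance$sample_id, decision = res[, 1L],
             rationale = res[, 2L],
             review_flag = !concordance$dq_positive &
                           concordance$hmm_positive)
}

#' Sample-level confusion counts against a truth set
#'
#' @param predicted_positive,truth_positive Named logical vectors over the
#'   same sample set (order-insensitive).
#' @return Object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(predicted_positive, truth_positive) {
  if (is.null(names(predicted_positive)) || is.null(names(truth_positive))) {
    stop("predicted and truth vectors must be named by sample id")
  }
  if (!setequal(names(predicted_positive), names(truth_positive))) {
    stop("predicted and truth cover different sample sets")
  }
  truth_positive <- truth_positive[names(predicted_positive)]
  confusion_counts(tp = sum(predicted_positive & truth_positive),
                   fp = sum(predicted_positive & !truth_positive),
                   tn = sum(!predicted_positive & !truth_positive),
                   fn = sum(!predicted_positive & truth_positive))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative integer counts, e.g. transcribed from a
#'   published 2x2 table.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(x < 0) || any(x != floor(x))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(lapply(x, as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, " (n=", x$tp + x$fp + x$tn + x$fn, ")\n", sep = "")
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval; the boundary cases are exact
#' (`lower = 0` when `successes = 0`, `upper = 1` when `successes = n`).
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, conf_level = 0.95) {
  if (n < 1L || successes < 0L || successes > n) {
    stop("need 0 <= successes <= n and n >= 1")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lower <- if (successes == 0L) 0 else max(0, center - half)
  upper <- if (successes == n) 1 else min(1, center + half)
  c(lower = lower, upper = upper)
}

#' Diagnostic validation metrics with Wilson intervals
#'
#' Point estimates follow the standard definitions — accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, negative predictive value `TN/(TN+FN)` — each with a
#' Wilson score interval on its own numerator/denominator.  A metric whose
#' denominator is zero is undefined and omitted from the result rather than
#' reported as 0.
#'
#' @param x A `confusion_counts` object.
#' @param conf_level Confidence level for the Wilson intervals.
#' @param include_ppv Also report positive predictive value `TP/(TP+FP)`
#'   (not part of the core metric set).
#' @return Data frame of class `dq_metrics` with columns `metric`,
#'   `numerator`, `denominator`, `estimate`, `lower`, `upper`.
#' @export
compute_metrics <- function(x, conf_level = 0.95, include_ppv = FALSE) {
  stopifnot(inherits(x, "confusion_counts"))
  total <- x$tp + x$fp + x$tn + x$fn
  if (total == 0L) stop("all confusion counts are zero")
  defs <- list(accuracy = c(x$tp + x$tn, total),
               sensitivity = c(x$tp, x$tp + x$fn),
               specificity = c(x$tn, x$tn + x$fp),
               npv = c(x$tn, x$tn + x$fn))
  if (include_ppv) defs$ppv <- c(x$tp, x$tp + x$fp)
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1L]
    den <- defs[[m]][2L]
    if (den == 0L) return(NULL)
    ci <- wilson_ci(num, den, conf_level)
    data.frame(metric = m, numerator = num, denominator = den,
               estimate = num / den, lower = ci[[1L]], upper = ci[[2L]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dq_metrics", "data.frame")
  attr(out, "conf_level") <- conf_level
  out
}

#' @export
print.dq_metrics <- function(x, digits = 1L, ...) {
  cl <- attr(x, "conf_level")
  cat("Diagnostic metrics (", format(100 * cl), "% Wilson CIs):\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %5.1f%%  (%s/%s)  CI [%.1f-%.1f]\n",
                x$metric[i], round_half_up(100 * x$estimate[i], digits),
                x$numerator[i], x$denominator[i],
                round_half_up(100 * x$lower[i], digits),
                round_half_up(100 * x$upper[i], digits)))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Report-style rounding (0.05 -> 0.1) as opposed to [round()]'s
#' round-half-even; used when comparing computed percentages with printed
#' one-decimal values.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Sample-level positivity from one or more call tables
#'
#' A sample is positive when it carries at least one call (hard or soft) in
#' any of the supplied call sets — e.g. the union over the dqa/dqb1/dqb2
#' evaluations of one cohort.
#'
#' @param ... Call tables in the standard format.
#' @param sample_ids Sample universe for the result.
#' @return Named logical vector over `sample_ids`.
#' @export
sample_positivity <- function(..., sample_ids) {
  called <- unique(unlist(lapply(list(...), function(x) x$sample_id)))
  stats::setNames(sample_ids %in% called, sample_ids)
}
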