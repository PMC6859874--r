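#' Viterbi copy-number path for one DQ profile
#'
#' Copy-number segmentation by a homogeneous hidden Markov model over
#' amplicons in panel order.  Emissions are Gaussian on `log2(dq)` with mean
#' `log2(cn/2)` and standard deviation `emission_sigma`; the chain stays in
#' its state with probability `1 - switch_prob` and moves to each other
#' state with probability `switch_prob/(K-1)`.  The initial distribution
#' treats position 0 as diploid: state 2 has probability `1 - switch_prob`.
#' DQ values are floored at `epsilon` before the log transform.  Ties are
#' broken toward copy number 2, then toward the lower copy number, so the
#' path is deterministic.
#'
#' This is an open surrogate for the proprietary copy-number HMM shipped
#' with the sequencing vendor's analysis software: model family and its
#' documented more-than-one-amplicon reporting limit are reproduced, but
#' none of its (unpublished) parameter values or score definitions.
#'
#' @param dq Numeric DQ vector in panel order.
#' @param states Ordered integer copy numbers; must contain 2.
#' @param emission_sigma SD of log2(DQ) around log2(cn/2) (> 0).
#' @param switch_prob Per-step probability of leaving the current state,
#'   in (0, 0.5).
#' @param epsilon Floor applied to `dq` before `log2`.
#' @return Integer vector of copy numbers, one per amplicon.
#' @export
viterbi_copy_number <- function(dq, states = c(1L, 2L, 3L),
                                emission_sigma = 0.2, switch_prob = 1e-3,
                                epsilon = 1e-3) {
  if (length(dq) == 0L) stop("empty DQ profile")
  states <- as.integer(states)
  if (!2L %in% states) stop("states must contain copy number 2")
  if (emission_sigma <= 0) stop("emission_sigma must be > 0")
  if (switch_prob <= 0 || switch_prob >= 0.5) {
    stop("switch_prob must lie in (0, 0.5)")
  }
  K <- length(states)
  n <- length(dq)
  x <- log2(pmax(dq, epsilon))
  em <- vapply(seq_len(K), function(k)
    stats::dnorm(x, log2(states[k] / 2), emission_sigma, log = TRUE),
    numeric(n))
  em <- matrix(em, nrow = n)
  l_stay <- log(1 - switch_prob)
  l_switch <- log(switch_prob / max(1L, K - 1L))
  init <- rep(l_switch, K)
  init[states == 2L] <- l_stay
  # preference order for tie-breaking: 2 first, then ascending copy number
  pref <- order(states != 2L, states)
  delta <- init + em[1L, ]
  back <- matrix(0L, n, K)
  if (n > 1L) {
    for (i in 2:n) {
      nd <- numeric(K)
      for (j in seq_len(K)) {
        best <- -Inf
        arg <- pref[1L]
        for (p in pref) {
          cand <- delta[p] + if (p == j) l_stay else l_switch
          if (cand > best) {
            best <- cand
            arg <- p
          }
        }
        nd[j] <- best + em[i, j]
        back[i, j] <- arg
      }
      delta <- nd
    }
  }
  path <- integer(n)
  best <- -Inf
  for (p in pref) {
    if (delta[p] > best) {
      best <- delta[p]
      path[n] <- p
    }
  }
  if (n > 1L) {
    for (i in n:2) path[i - 1L] <- back[i, path[i]]
  }
  states[path]
}

#' Fit the copy-number HMM to a DQ profile matrix
#'
#' Runs [viterbi_copy_number()] on every sample and converts maximal
#' non-diploid runs of the path into calls.  Runs shorter than
#' `min_amplicons` are suppressed — with the default of 2 the caller is
#' structurally blind to copy-number changes covered by a single amplicon,
#' the documented limitation this comparator exists to reproduce.
#'
#' Segment scores: `confidence` is the log10 likelihood ratio of the
#' segment's emissions under its copy number versus copy number 2 (clamped
#' at 0); `precision` is the mean per-amplicon margin between the best and
#' second-best state emission log-likelihood.
#'
#' @param object A `dq_fit` (its DQ matrix is used) or a samples x amplicons
#'   DQ matrix.
#' @param panel The `amplicon_panel` (taken from a `dq_fit` automatically).
#' @param states,emission_sigma,switch_prob,epsilon See
#'   [viterbi_copy_number()].
#' @param min_amplicons Minimum run length for a reportable segment.
#' @return Object of class `hmm_fit`: list with `path` (samples x amplicons
#'   integer matrix of copy numbers), `calls` (standard call table with
#'   `caller = "HMM"` plus `copy_number`, `confidence`, `precision`) and
#'   `config`.
#' @export
hmm_fit <- function(object, panel = NULL, states = c(1L, 2L, 3L),
                    emission_sigma = 0.2, switch_prob = 1e-3,
                    min_amplicons = 2L, epsilon = 1e-3) {
  if (inherits(object, "dq_fit")) {
    if (is.null(panel)) panel <- object$panel
    dq <- object$dq
  } else {
    dq <- object
    if (is.null(panel)) stop("panel is required for a plain DQ matrix")
  }
  if (!identical(colnames(dq), panel$amplicon_id)) {
    stop("DQ matrix amplicons do not match the panel")
  }
  config <- list(states = as.integer(states),
                 emission_sigma = emission_sigma,
                 switch_prob = switch_prob,
                 min_amplicons = as.integer(min_amplicons),
                 epsilon = epsilon)
  path <- t(vapply(rownames(dq), function(s)
    viterbi_copy_number(dq[s, ], states, emission_sigma, switch_prob,
                        epsilon), integer(ncol(dq))))
  dimnames(path) <- dimnames(dq)
  calls <- do.call(rbind, lapply(rownames(dq), function(s)
    hmm_segment_calls(path[s, ], dq[s, ], panel, s, config)))
  if (is.null(calls)) {
    calls <- annotate_calls(NULL, panel)
    calls$copy_number <- integer()
    calls$confidence <- numeric()
    calls$precision <- numeric()
  }
  structure(list(path = path, calls = calls, config = config, panel = panel),
            class = "hmm_fit")
}

# calls for a single sample's path (internal)
hmm_segment_calls <- function(path, dq, panel, sample_id, config) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 2L & r$lengths >= config$min_amplicons)
  if (length(keep) == 0L) return(NULL)
  x <- log2(pmax(dq, config$epsilon))
  em <- vapply(config$states, function(cn)
    stats::dnorm(x, log2(cn / 2), config$emission_sigma, log = TRUE),
    numeric(length(x)))
  em <- matrix(em, nrow = length(x))
  i2 <- which(config$states == 2L)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    icn <- which(config$states == r$values[k])
    confidence <- max(0, sum(em[idx, icn] - em[idx, i2]) / log(10))
    ordered <- apply(em[idx, , drop = FALSE], 1L,
                     function(e) sort(e, decreasing = TRUE)[1:2])
    precision <- mean(ordered[1L, ] - ordered[2L, ])
    runs <- data.frame(first = starts[k], last = ends[k],
                       type = if (r$values[k] < 2L) "del" else "dup",
                       evidence = "hard",
                       n_amplicons = r$lengths[k], score = confidence)
    ann <- annotate_calls(runs, panel, sample_id = sample_id,
                          caller = "HMM")
    ann$copy_number <- r$values[k]
    ann$confidence <- confidence
    ann$precision <- precision
    ann
  })
  do.call(rbind, out)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Copy-number HMM fit: ", nrow(x$path), " sample(s) x ", ncol(x$path),
      " amplicons; states {", paste(x$config$states, collapse = ","),
      "}, sigma ", x$config$emission_sigma, ", switch_prob ",
      x$config$switch_prob, ", min_amplicons ", x$config$min_amplicons,
      "\n  calls: ", nrow(x$calls), "\n", sep = "")
  invisible(x)
}

#' @export
summary.hmm_fit <- function(object, ...) {
  cat("HMM calls:\n")
  if (nrow(object$calls) > 0L) {
    print(object$calls[, c("sample_id", "type", "copy_number", "exon_span",
                           "n_amplicons", "confidence", "precision")],
          row.names = FALSE)
  } else {
    cat("  (none)\n")
  }
  invisible(object$calls)
}
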