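#' Normalize amplicon read counts to coverage fractions
#'
#' Each amplicon count is divided by the sample's total read count over the
#' normalization scope, so copy-number signal becomes independent of library
#' size.  With `scope = "panel_wide"` the denominator is the sample's total
#' over all panel amplicons (the fractions of a sample sum to 1); with
#' `scope = "per_pool"` each primer pool is normalized on its own total
#' (fractions sum to 1 within every pool), which additionally absorbs
#' per-sample-per-pool amplification batch effects.
#'
#' @param counts Samples x amplicons count matrix (see [read_coverage()]).
#' @param panel The matching `amplicon_panel`.
#' @param scope `"panel_wide"` or `"per_pool"`.
#' @return Numeric matrix of fractions with attribute `scope`.
#' @export
normalize_coverage <- function(counts, panel,
                               scope = c("panel_wide", "per_pool")) {
  scope <- match.arg(scope)
  counts <- validate_coverage(counts, panel)
  m <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  if (scope == "panel_wide") {
    tot <- rowSums(m)
    if (any(tot <= 0)) {
      stop("sample '", rownames(m)[which(tot <= 0)[1L]],
           "' has zero total reads in panel_wide scope")
    }
    m <- m / tot
  } else {
    for (p in attr(panel, "pools")) {
      idx <- which(panel$pool == p)
      tot <- rowSums(m[, idx, drop = FALSE])
      if (any(tot <= 0)) {
        stop("sample '", rownames(m)[which(tot <= 0)[1L]],
             "' has zero total reads in pool ", p)
      }
      m[, idx] <- m[, idx, drop = FALSE] / tot
    }
  }
  attr(m, "scope") <- scope
  m
}
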