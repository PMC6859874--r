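#' Build a per-amplicon baseline from LGR-negative reference samples
#'
#' The baseline stores, for every amplicon, the mean and standard deviation
#' of normalized coverage across a set of rearrangement-negative reference
#' samples.  Two modes exist, differing only in normalization scope:
#' `"B1_panel_wide"` (all amplicons normalized together) and `"B2_per_pool"`
#' (each primer pool normalized separately).  Standard deviations use the
#' n-1 denominator and are floored at `sd_floor_frac * mean` so that
#' degenerate reference sets cannot produce zero-width threshold bands.
#'
#' @param counts Samples x amplicons count matrix containing at least the
#'   reference samples.
#' @param panel The matching `amplicon_panel`.
#' @param reference_ids Character vector of reference sample ids (>= 2).
#' @param mode `"B2_per_pool"` (default) or `"B1_panel_wide"`.
#' @param sd_floor_frac SD floor as a fraction of the amplicon mean.
#' @return A list of class `dq_baseline` with elements `mode`, `scope`,
#'   `amplicon_id`, `mean`, `sd`, `n_reference`, `reference_ids`.
#' @export
build_baseline <- function(counts, panel, reference_ids,
                           mode = c("B2_per_pool", "B1_panel_wide"),
                           sd_floor_frac = 0.01) {
  mode <- match.arg(mode)
  unknown <- setdiff(reference_ids, rownames(counts))
  if (length(unknown) > 0L) {
    stop("unknown reference sample id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(reference_ids) < 2L) {
    stop("at least 2 reference samples are required, got ",
         length(reference_ids))
  }
  scope <- if (mode == "B2_per_pool") "per_pool" else "panel_wide"
  norm <- normalize_coverage(counts[reference_ids, , drop = FALSE], panel,
                             scope)
  mu <- colMeans(norm)
  if (any(mu <= 0)) {
    stop("amplicon(s) with zero mean coverage across references: ",
         paste(colnames(norm)[mu <= 0], collapse = ", "))
  }
  sdev <- apply(norm, 2L, stats::sd)
  sdev <- pmax(sdev, sd_floor_frac * mu)
  structure(list(mode = mode, scope = scope,
                 amplicon_id = panel$amplicon_id,
                 mean = unname(mu), sd = unname(sdev),
                 n_reference = length(reference_ids),
                 reference_ids = as.character(reference_ids)),
            class = "dq_baseline")
}

#' @export
print.dq_baseline <- function(x, ...) {
  cat("DQ baseline (", x$mode, "): ", length(x$amplicon_id),
      " amplicons from ", x$n_reference, " reference samples\n", sep = "")
  cat("  relative SD (sd/mean): median ",
      signif(stats::median(x$sd / x$mean), 3L), ", max ",
      signif(max(x$sd / x$mean), 3L), "\n", sep = "")
  invisible(x)
}

#' Write / read a baseline as annotated TSV
#'
#' The file carries `# key: value` comment headers (mode, n_reference,
#' reference ids) followed by columns `amplicon_id`, `mean`, `sd`.
#'
#' @param baseline A `dq_baseline`.
#' @param path File path.
#' @return `write_baseline()`: invisibly `path`; `read_baseline()`: a
#'   `dq_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# mode: ", baseline$mode),
               paste0("# n_reference: ", baseline$n_reference),
               paste0("# reference_ids: ",
                      paste(baseline$reference_ids, collapse = ","))), con)
  utils::write.table(data.frame(amplicon_id = baseline$amplicon_id,
                                mean = baseline$mean, sd = baseline$sd),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  raw <- readLines(path)
  hdr <- raw[grepl("^# ", raw)]
  field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0L) stop("baseline file lacks '# ", key, ":' header")
    sub(paste0("^# ", key, ": "), "", ln[1L])
  }
  mode <- field("mode")
  if (!mode %in% c("B1_panel_wide", "B2_per_pool")) {
    stop("unknown baseline mode: ", mode)
  }
  refs <- strsplit(field("reference_ids"), ",", fixed = TRUE)[[1L]]
  df <- utils::read.delim(text = raw[!grepl("^#", raw)], header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(mode = mode,
                 scope = if (mode == "B2_per_pool") "per_pool"
                         else "panel_wide",
                 amplicon_id = df$amplicon_id,
                 mean = df$mean, sd = df$sd,
                 n_reference = as.integer(field("n_reference")),
                 reference_ids = refs),
            class = "dq_baseline")
}
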