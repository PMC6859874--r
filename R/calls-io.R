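#' Write / read CNV call tables
#'
#' TSV with the standard call columns (`sample_id`, `caller`, `type`,
#' `first_amplicon`, `last_amplicon`, `exon_span`, `genomic_span`,
#' `n_amplicons`, `evidence`, `score` and, when present, the HMM
#' `copy_number`/`confidence`/`precision` columns).  Output is byte-stable
#' for a fixed input ordering; an empty call set yields a header-only file.
#'
#' @param calls Call table (see [call_cnvs()], [hmm_fit()]).
#' @param path File path.
#' @param header Optional character vector of comment lines.
#' @return `write_calls()`: invisibly `path`; `read_calls()`: the call
#'   table.
#' @export
write_calls <- function(calls, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  needed <- c("sample_id", "caller", "type", "first_amplicon",
              "last_amplicon", "exon_span", "genomic_span", "n_amplicons",
              "evidence", "score")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("call file lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("sample_id", "caller", "type", "first_amplicon",
                "last_amplicon", "exon_span", "genomic_span", "evidence")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$n_amplicons <- as.integer(df$n_amplicons)
  df
}

#' Write / read a per-amplicon DQ profile table
#'
#' Long-format TSV with one row per (sample, amplicon):
#' `sample_id`, `amplicon_id`, `dq`, `center`, `lo`, `hi`.
#'
#' @param fit A `dq_fit`.
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_profile <- function(fit, path, header = NULL) {
  stopifnot(inherits(fit, "dq_fit"))
  df <- data.frame(sample_id = rep(rownames(fit$dq), each = ncol(fit$dq)),
                   amplicon_id = rep(colnames(fit$dq), nrow(fit$dq)),
                   dq = as.vector(t(fit$dq)),
                   center = rep(fit$center, nrow(fit$dq)),
                   lo = rep(fit$lo, nrow(fit$dq)),
                   hi = rep(fit$hi, nrow(fit$dq)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @return `read_profile()`: a list with `dq` (samples x amplicons matrix),
#'   `center`, `lo`, `hi` (per-amplicon vectors).
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  samples <- unique(df$sample_id)
  amplicons <- unique(df$amplicon_id)
  dq <- matrix(NA_real_, length(samples), length(amplicons),
               dimnames = list(samples, amplicons))
  dq[cbind(match(df$sample_id, samples),
           match(df$amplicon_id, amplicons))] <- df$dq
  first <- df[match(amplicons, df$amplicon_id), , drop = FALSE]
  list(dq = dq,
       center = stats::setNames(first$center, amplicons),
       lo = stats::setNames(first$lo, amplicons),
       hi = stats::setNames(first$hi, amplicons))
}
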