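#' Read a per-amplicon coverage matrix
#'
#' Returns a samples x amplicons matrix of non-negative integer read counts,
#' with amplicon columns in panel order.  Two dialects are supported:
#' \describe{
#'   \item{`"matrix_tsv"`}{A single TSV whose rows are amplicons and whose
#'     columns are samples; the first column must be `amplicon_id`.}
#'   \item{`"iontorrent_amplicon_summary"`}{One TSV per sample in the style
#'     of torrent-suite coverage-analysis amplicon summaries: one row per
#'     amplicon, columns including at least `region_id` (the amplicon id) and
#'     `total_reads`; any other annotation columns are ignored.  `path` is a
#'     vector of per-sample files; sample ids are taken from `names(path)`
#'     when set, else from the file base names.}
#' }
#'
#' @param path File path (matrix dialect) or vector of file paths
#'   (amplicon-summary dialect).
#' @param panel An `amplicon_panel`; every panel amplicon must be present.
#' @param dialect One of `"matrix_tsv"`, `"iontorrent_amplicon_summary"`.
#' @return Integer matrix, `rownames` = sample ids in file order,
#'   `colnames` = panel amplicon ids.
#' @export
read_coverage <- function(path, panel,
                          dialect = c("matrix_tsv",
                                      "iontorrent_amplicon_summary")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix_tsv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            comment.char = "#", check.names = FALSE)
    if (names(df)[1L] != "amplicon_id") {
      stop("matrix_tsv coverage must have 'amplicon_id' as first column")
    }
    missing <- setdiff(panel$amplicon_id, df$amplicon_id)
    if (length(missing) > 0L) {
      stop("coverage file is missing panel amplicon(s): ",
           paste(missing, collapse = ", "))
    }
    df <- df[match(panel$amplicon_id, df$amplicon_id), , drop = FALSE]
    m <- t(as.matrix(df[, -1L, drop = FALSE]))
    colnames(m) <- panel$amplicon_id
  } else {
    sample_ids <- names(path)
    if (is.null(sample_ids)) {
      sample_ids <- sub("\\.(tsv|txt)$", "", basename(path))
    }
    rows <- lapply(seq_along(path), function(i) {
      df <- utils::read.delim(path[i], header = TRUE,
                              stringsAsFactors = FALSE, comment.char = "#")
      if (!all(c("region_id", "total_reads") %in% names(df))) {
        stop("amplicon summary '", path[i],
             "' lacks region_id/total_reads columns")
      }
      missing <- setdiff(panel$amplicon_id, df$region_id)
      if (length(missing) > 0L) {
        stop("'", path[i], "' is missing panel amplicon(s): ",
             paste(missing, collapse = ", "))
      }
      df$total_reads[match(panel$amplicon_id, df$region_id)]
    })
    m <- do.call(rbind, rows)
    dimnames(m) <- list(sample_ids, panel$amplicon_id)
  }
  validate_coverage(m, panel)
}

# common checks; coerces to integer storage
validate_coverage <- function(m, panel = NULL) {
  if (!is.matrix(m)) stop("coverage must be a matrix")
  if (anyNA(m)) stop("coverage contains missing values")
  if (!is.numeric(m)) stop("coverage counts must be numeric")
  if (any(m < 0)) stop("negative read count in coverage")
  if (any(m != floor(m))) stop("non-integer read count in coverage")
  if (!is.null(panel) && !identical(colnames(m), panel$amplicon_id)) {
    stop("coverage amplicons do not match the panel")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a coverage matrix
#'
#' Inverse of [read_coverage()].  For the amplicon-summary dialect, `path`
#' is a directory and one `<sample>.amplicon_summary.tsv` is written per
#' sample (with panel annotation columns, mimicking a torrent-suite coverage
#' summary); the vector of written files is returned so it can be fed back
#' to [read_coverage()].
#'
#' @param counts Samples x amplicons integer matrix.
#' @param path Output file (matrix dialect) or directory (summary dialect).
#' @param panel The matching `amplicon_panel`.
#' @param dialect See [read_coverage()].
#' @param header Optional comment lines for the matrix dialect.
#' @return Invisibly, the written path(s); named by sample for the summary
#'   dialect.
#' @export
write_coverage <- function(counts, path, panel,
                           dialect = c("matrix_tsv",
                                       "iontorrent_amplicon_summary"),
                           header = NULL) {
  dialect <- match.arg(dialect)
  counts <- validate_coverage(counts, panel)
  if (dialect == "matrix_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    df <- data.frame(amplicon_id = colnames(counts), t(counts),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- vapply(rownames(counts), function(s) {
    f <- file.path(path, paste0(s, ".amplicon_summary.tsv"))
    df <- data.frame(contig_id = panel$chrom,
                     contig_srt = panel$start,
                     contig_end = panel$end,
                     region_id = panel$amplicon_id,
                     attributes = paste0("GENE_ID=", panel$gene,
                                         ";POOL=", panel$pool),
                     total_reads = counts[s, ],
                     fwd_reads = counts[s, ] %/% 2L,
                     rev_reads = counts[s, ] - counts[s, ] %/% 2L)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1L))
  invisible(out)
}
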