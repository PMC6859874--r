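#' Construct and validate an amplicon panel
#'
#' An amplicon panel is an ordered table of PCR amplicons with genomic
#' coordinates (0-based, half-open, BED convention), gene and exon labels and
#' a primer-pool assignment.  Rows are always stored sorted by
#' `(chrom, start)` so that "consecutive amplicons" has a single meaning
#' throughout the package.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `amplicon_id`,
#'   `gene`, `exon_label`, `pool`.
#' @param lines Optional integer vector of source line numbers, used to make
#'   parse errors point at the offending input line.
#' @return A data frame of class `amplicon_panel`, sorted by `(chrom, start)`,
#'   with an attribute `pools` holding the sorted set of pool indices.
#' @export
as_amplicon_panel <- function(x, lines = NULL) {
  needed <- c("chrom", "start", "end", "amplicon_id", "gene", "exon_label",
              "pool")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[needed]
  if (is.null(lines)) lines <- seq_len(nrow(x))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$pool <- as.integer(x$pool)
  x$chrom <- as.character(x$chrom)
  x$amplicon_id <- as.character(x$amplicon_id)
  x$gene <- as.character(x$gene)
  x$exon_label <- as.character(x$exon_label)
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$pool)) {
    bad <- which(is.na(x$start) | is.na(x$end) | is.na(x$pool))[1L]
    stop("malformed panel row at line ", lines[bad],
         ": non-numeric start/end/pool")
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0L) {
    stop("malformed panel row at line ", lines[bad[1L]],
         ": end <= start for amplicon '", x$amplicon_id[bad[1L]], "'")
  }
  dup <- x$amplicon_id[duplicated(x$amplicon_id)]
  if (length(dup) > 0L) {
    stop("duplicate amplicon_id in panel: ",
         paste(unique(dup), collapse = ", "))
  }
  ord <- order(x$chrom, x$start)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "pools") <- sort(unique(x$pool))
  class(x) <- c("amplicon_panel", "data.frame")
  x
}

#' Read an amplicon panel definition
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`"tsv"`}{Tab-separated with a header line naming the columns
#'     `chrom`, `start`, `end`, `amplicon_id`, `gene`, `exon_label`, `pool`.}
#'   \item{`"bed6+pool"`}{Headerless BED6 (`chrom start end name score
#'     strand`) with three extra columns `gene`, `exon_label`, `pool`; the
#'     BED `name` field is the amplicon id, `score` and `strand` are
#'     ignored.}
#' }
#' Lines starting with `#` are comments in both dialects.  Coordinates are
#' 0-based half-open in both.
#'
#' @param path Path to the panel file.
#' @param dialect One of `"tsv"`, `"bed6+pool"`.
#' @return An [as_amplicon_panel()] object.
#' @export
read_panel <- function(path, dialect = c("tsv", "bed6+pool")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (dialect == "tsv") {
    df <- utils::read.delim(text = raw[keep], header = TRUE,
                            stringsAsFactors = FALSE)
    lines <- which(keep)[-1L]
  } else {
    df <- utils::read.delim(text = raw[keep], header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 9L) {
      stop("bed6+pool panel needs 9 columns ",
           "(chrom start end name score strand gene exon_label pool), got ",
           ncol(df))
    }
    df <- df[, c(1L, 2L, 3L, 4L, 7L, 8L, 9L)]
    names(df) <- c("chrom", "start", "end", "amplicon_id", "gene",
                   "exon_label", "pool")
    lines <- which(keep)
  }
  as_amplicon_panel(df, lines = lines)
}

#' Write an amplicon panel definition
#'
#' @param panel An `amplicon_panel`.
#' @param path Output path.
#' @param dialect See [read_panel()].
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path, dialect = c("tsv", "bed6+pool"),
                        header = NULL) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (dialect == "tsv") {
    utils::write.table(as.data.frame(panel), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(panel$chrom, panel$start, panel$end, panel$amplicon_id,
                      0L, "+", panel$gene, panel$exon_label, panel$pool)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon panel: ", nrow(x), " amplicons, ",
      length(unique(x$gene)), " gene(s), pools {",
      paste(attr(x, "pools"), collapse = ","), "}\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# panel row indices for a gene's exon labels (internal)
panel_exon_indices <- function(panel, exon_labels) {
  which(panel$exon_label %in% exon_labels)
}
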