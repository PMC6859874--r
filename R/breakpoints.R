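#' Parse an HGVS-style genomic deletion descriptor
#'
#' Accepts descriptors of the form `<reference>:g.<start>_<end>del[<n>]`,
#' e.g. a RefSeqGene-anchored `"NG_xxxxxx.y: g.163181_169408del6228"`
#' (whitespace after the colon is tolerated).  Coordinates are 1-based
#' inclusive; when the optional `del<n>` suffix is present it must equal
#' `end - start + 1`.  Transcript-anchored descriptors with unknowable
#' intronic bounds (`c. ... -?_ ... +?del`) are rejected explicitly: their
#' genomic extent is undefined by construction.
#'
#' @param descriptor Character scalar.
#' @return Object of class `genomic_deletion`: list with `reference_id`,
#'   `start`, `end`, `declared_length` (NA when absent).
#' @export
parse_genomic_deletion <- function(descriptor) {
  stopifnot(is.character(descriptor), length(descriptor) == 1L)
  if (grepl("\\?", descriptor)) {
    stop("descriptor '", descriptor, "' has unknown ('?') breakpoint ",
         "bounds; only fully specified g.<start>_<end>del[<n>] ",
         "descriptors can be parsed")
  }
  m <- regmatches(descriptor,
                  regexec(paste0("^\\s*([A-Za-z0-9_.-]+)\\s*:\\s*",
                                 "g\\.(\\d+)_(\\d+)del(\\d*)\\s*$"),
                          descriptor))[[1L]]
  if (length(m) == 0L) {
    stop("cannot parse genomic deletion descriptor: '", descriptor,
         "' (expected <ref>:g.<start>_<end>del[<n>])")
  }
  start <- as.numeric(m[3L])
  end <- as.numeric(m[4L])
  if (end < start) {
    stop("descriptor '", descriptor, "': end (", end,
         ") is smaller than start (", start, ")")
  }
  declared <- if (nzchar(m[5L])) as.numeric(m[5L]) else NA_real_
  if (!is.na(declared) && declared != end - start + 1) {
    stop("descriptor '", descriptor, "': declared length ", declared,
         " does not match the coordinate span ", end - start + 1)
  }
  structure(list(reference_id = m[2L], start = start, end = end,
                 declared_length = declared),
            class = "genomic_deletion")
}

#' Length of a genomic deletion
#'
#' @param d A `genomic_deletion`.
#' @return `end - start + 1` (1-based inclusive span).
#' @export
deletion_length <- function(d) {
  stopifnot(inherits(d, "genomic_deletion"))
  d$end - d$start + 1
}

#' Format a genomic deletion back to descriptor text
#'
#' Inverse of [parse_genomic_deletion()]; the `del<n>` suffix is emitted
#' only when `declared_length` is set, so parse -> format -> parse is the
#' identity.
#'
#' @param d A `genomic_deletion`.
#' @export
format_genomic_deletion <- function(d) {
  stopifnot(inherits(d, "genomic_deletion"))
  suffix <- if (is.na(d$declared_length)) "" else
    format(d$declared_length, scientific = FALSE)
  paste0(d$reference_id, ":g.", format(d$start, scientific = FALSE), "_",
         format(d$end, scientific = FALSE), "del", suffix)
}

#' @export
print.genomic_deletion <- function(x, ...) {
  cat("Genomic deletion ", format_genomic_deletion(x), " (",
      format(deletion_length(x), scientific = FALSE), " bp)\n", sep = "")
  invisible(x)
}

#' Junction microhomology of a deletion
#'
#' Finds the perfectly repeated stretch shared by the two breakpoint
#' junctions — the signature of Alu-mediated non-allelic homologous
#' recombination.  Using the right-slide convention, the homology length is
#' the largest `h` such that
#' `reference[start .. start+h-1] == reference[end+1 .. end+h]`:
#' the deletion interval can then be shifted right by up to `h` positions
#' without changing the rejoined sequence, so `h` is also the width of the
#' breakpoint ambiguity window.  Note HGVS 3'-rule normalization uses the
#' same downstream direction; some literature reports the repeat upstream
#' instead.
#'
#' @param reference Reference nucleotide sequence as a single character
#'   string (or anything `as.character()`-coercible, e.g. a
#'   `Biostrings::DNAString`); deletion coordinates are 1-based positions
#'   within this string.
#' @param d A `genomic_deletion` whose coordinates lie inside `reference`.
#' @param max_probe Maximum homology length searched (bp).
#' @return Object of class `junction_homology`: list with `length`,
#'   `repeat_sequence`, `ambiguity_window` (`c(start, start + length)`, the
#'   admissible range of the left breakpoint, of width `length`).
#' @export
find_junction_homology <- function(reference, d, max_probe = 500L) {
  stopifnot(inherits(d, "genomic_deletion"))
  s <- toupper(as.character(reference))
  if (length(s) != 1L) stop("reference must be a single sequence")
  n <- nchar(s)
  if (d$end + 1 > n || d$start < 1) {
    stop("reference sequence (", n, " bp) does not cover the deletion [",
         d$start, ", ", d$end, "] plus its right junction")
  }
  left <- substring(s, d$start, min(n, d$start + max_probe - 1))
  right <- substring(s, d$end + 1, min(n, d$end + max_probe))
  a <- strsplit(left, "", fixed = TRUE)[[1L]]
  b <- strsplit(right, "", fixed = TRUE)[[1L]]
  lim <- min(length(a), length(b))
  h <- 0L
  while (h < lim && a[h + 1L] == b[h + 1L]) h <- h + 1L
  structure(list(length = h,
                 repeat_sequence = substring(s, d$start, d$start + h - 1L),
                 ambiguity_window = c(d$start, d$start + h)),
            class = "junction_homology")
}

#' @export
print.junction_homology <- function(x, ...) {
  if (x$length == 0L) {
    cat("No junction microhomology (blunt breakpoints)\n")
  } else {
    cat("Junction microhomology: ", x$length, " bp perfect repeat '",
        x$repeat_sequence, "'\n  left breakpoint ambiguity window [",
        x$ambiguity_window[1L], ", ", x$ambiguity_window[2L], "]\n",
        sep = "")
  }
  invisible(x)
}

#' Apply a deletion to a reference sequence
#'
#' Returns the rejoined sequence; shifting the deletion interval within the
#' homology ambiguity window leaves this product unchanged.
#'
#' @param reference Character scalar nucleotide sequence.
#' @param d A `genomic_deletion` in the sequence's coordinate frame.
#' @export
apply_deletion <- function(reference, d) {
  stopifnot(inherits(d, "genomic_deletion"))
  s <- as.character(reference)
  paste0(substring(s, 1L, d$start - 1), substring(s, d$end + 1, nchar(s)))
}
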