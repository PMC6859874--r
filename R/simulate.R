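#' Build a synthetic two-gene amplicon panel
#'
#' Deterministic panel with the structure of a commercial two-gene breast
#' cancer amplicon design: ~60% of amplicons on a BRCA1-like gene (chr17),
#' the rest on a BRCA2-like gene (chr13), exons covered by 1-4 amplicons in
#' a repeating pattern (so some exons are covered by a single amplicon — the
#' configuration that defeats minimum-two-amplicon HMM callers), and primer
#' pools assigned cyclically across the coordinate-sorted panel.
#' Coordinates are synthetic.
#'
#' @param n_amplicons Total number of amplicons (default 167).
#' @param n_pools Number of primer pools (default 3).
#' @return An `amplicon_panel`.
#' @export
simulate_panel <- function(n_amplicons = 167L, n_pools = 3L) {
  stopifnot(n_amplicons >= 4L, n_pools >= 1L)
  pattern <- c(4L, 3L, 4L, 1L, 3L, 4L, 2L, 4L)
  gene_block <- function(gene, chrom, gstart, n) {
    sizes <- integer()
    while (sum(sizes) < n) {
      sizes <- c(sizes, pattern[(length(sizes) %% length(pattern)) + 1L])
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    exon <- rep(seq_along(sizes), sizes)
    pos_in_exon <- unlist(lapply(sizes, seq_len))
    start <- gstart + (exon - 1L) * 1200L + (pos_in_exon - 1L) * 150L
    data.frame(chrom = chrom, start = start, end = start + 125L,
               amplicon_id = NA_character_, gene = gene,
               exon_label = paste0(gene, "_ex", exon),
               pool = NA_integer_)
  }
  n1 <- ceiling(0.6 * n_amplicons)
  df <- rbind(gene_block("BRCA2", "chr13", 32315000L, n_amplicons - n1),
              gene_block("BRCA1", "chr17", 43044000L, n1))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$amplicon_id <- sprintf("AMPL%05d", seq_len(nrow(df)))
  df$pool <- rep_len(seq_len(n_pools), nrow(df))
  as_amplicon_panel(df)
}

#' Simulate an amplicon-coverage cohort
#'
#' Generative model: sample `s` has library size
#' `L_s ~ logNormal(log(library_size_mean) - sdlog^2/2, sdlog)`; amplicon
#' `a` has a fixed amplification efficiency
#' `e_a ~ logNormal(0, efficiency_sigma)` shared by all samples; each
#' (sample, pool) pair carries a batch factor
#' `g_sp ~ logNormal(0, pool_effect_sigma)`.  With copy number `c_sa`
#' (2 except inside injected events) the expected count is
#' `mu_sa = L_s * w_sa / sum_a(w_sa)` with
#' `w_sa = e_a * g_s,pool(a) * c_sa / 2` (so expected totals equal the
#' library size), and counts are drawn negative-binomially with that mean.
#'
#' DNA quality is heterogeneous, as in real diagnostic cohorts: standard
#' samples use NB size `dispersion`; an independent `low_quality_fraction`
#' of samples uses NB size `low_quality_dispersion` (noisier profiles — the
#' main source of false-positive dosage calls); samples listed in
#' `degraded_samples` use `dispersion / degraded_factor` (heavily degraded
#' DNA with many out-of-threshold amplicons).  Samples listed in
#' `standard_quality_samples` are never drawn into the low-quality subset.
#'
#' @param panel An `amplicon_panel`.
#' @param n_samples Number of samples.
#' @param sample_ids Sample ids (default `S001`, `S002`, ...).
#' @param library_size_mean,library_size_sdlog Mean reads per sample and
#'   log-scale spread of the library size.
#' @param efficiency_sigma Log-scale SD of per-amplicon efficiency.
#' @param pool_effect_sigma Log-scale SD of the per-sample-per-pool factor.
#' @param dispersion NB size parameter of standard samples.
#' @param low_quality_fraction,low_quality_dispersion Fraction and NB size
#'   of the low-quality subpopulation.
#' @param events Optional data frame with columns `sample` (row index),
#'   `first`, `last` (panel indices) and `copy_number` (1 or 3) describing
#'   injected heterozygous deletions/duplications over contiguous amplicon
#'   runs.
#' @param degraded_samples Row indices of degraded samples.
#' @param degraded_factor Divisor applied to `dispersion` for degraded
#'   samples.
#' @param standard_quality_samples Row indices protected from the
#'   low-quality draw.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `sim_cohort`: list with `panel`, `counts`
#'   (samples x amplicons integer matrix), `truth` (per-sample status and
#'   event coordinates), `events`, `quality` (per-sample NB size) and
#'   `config` (the effective parameters).
#' @export
simulate_cohort <- function(panel, n_samples,
                            sample_ids = sprintf("S%03d",
                                                 seq_len(n_samples)),
                            library_size_mean = 5e5,
                            library_size_sdlog = 0.25,
                            efficiency_sigma = 0.5,
                            pool_effect_sigma = 0.1,
                            dispersion = 300,
                            low_quality_fraction = 0.20,
                            low_quality_dispersion = 15,
                            events = NULL,
                            degraded_samples = integer(),
                            degraded_factor = 25,
                            standard_quality_samples = integer(),
                            seed = 1L) {
  A <- nrow(panel)
  n <- as.integer(n_samples)
  stopifnot(length(sample_ids) == n, !anyDuplicated(sample_ids))
  if (!is.null(events) && nrow(events) > 0L) {
    ok <- events$sample >= 1L & events$sample <= n &
      events$first >= 1L & events$last <= A &
      events$first <= events$last & events$copy_number %in% c(1L, 3L)
    if (!all(ok)) {
      stop("invalid event range or copy number in events row(s): ",
           paste(which(!ok), collapse = ", "))
    }
  }
  set.seed(as.integer(seed))
  eff <- exp(stats::rnorm(A, 0, efficiency_sigma))
  lib <- stats::rlnorm(n, log(library_size_mean) - library_size_sdlog^2 / 2,
                       library_size_sdlog)
  pools <- attr(panel, "pools")
  poolfac <- matrix(exp(stats::rnorm(n * length(pools), 0,
                                     pool_effect_sigma)),
                    n, length(pools))
  low_quality <- stats::runif(n) < low_quality_fraction
  low_quality[standard_quality_samples] <- FALSE
  low_quality[degraded_samples] <- FALSE
  size <- rep(dispersion, n)
  size[low_quality] <- low_quality_dispersion
  size[degraded_samples] <- dispersion / degraded_factor
  cn <- matrix(2L, n, A)
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      cn[events$sample[i], events$first[i]:events$last[i]] <-
        events$copy_number[i]
    }
  }
  pool_col <- match(panel$pool, pools)
  counts <- matrix(0L, n, A, dimnames = list(sample_ids,
                                             panel$amplicon_id))
  for (s in seq_len(n)) {
    w <- eff * poolfac[s, pool_col] * cn[s, ] / 2
    mu <- lib[s] * w / sum(w)
    counts[s, ] <- stats::rnbinom(A, mu = mu, size = size[s])
  }
  truth <- data.frame(sample_id = sample_ids, lgr_status = FALSE,
                      type = NA_character_,
                      first_amplicon = NA_character_,
                      last_amplicon = NA_character_)
  ev <- NULL
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- data.frame(sample_id = sample_ids[events$sample],
                     first = events$first, last = events$last,
                     copy_number = events$copy_number,
                     type = ifelse(events$copy_number < 2L, "del", "dup"),
                     first_amplicon = panel$amplicon_id[events$first],
                     last_amplicon = panel$amplicon_id[events$last])
    truth$lgr_status[events$sample] <- TRUE
    truth$type[events$sample] <- ev$type
    truth$first_amplicon[events$sample] <- ev$first_amplicon
    truth$last_amplicon[events$sample] <- ev$last_amplicon
  }
  structure(list(panel = panel, counts = counts, truth = truth,
                 events = ev, efficiency = eff, library_size = lib,
                 quality = data.frame(sample_id = sample_ids, nb_size = size,
                                      low_quality = low_quality),
                 config = list(n_samples = n,
                               library_size_mean = library_size_mean,
                               library_size_sdlog = library_size_sdlog,
                               efficiency_sigma = efficiency_sigma,
                               pool_effect_sigma = pool_effect_sigma,
                               dispersion = dispersion,
                               low_quality_fraction = low_quality_fraction,
                               low_quality_dispersion =
                                 low_quality_dispersion,
                               degraded_samples = degraded_samples,
                               degraded_factor = degraded_factor,
                               seed = as.integer(seed))),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " amplicons (seed ", x$config$seed, ")\n  events: ",
      if (is.null(x$events)) 0L else nrow(x$events),
      "; degraded: ", length(x$config$degraded_samples),
      "; low-quality: ", sum(x$quality$low_quality), "\n", sep = "")
  invisible(x)
}

# event index ranges used by the validation scenario (internal)
scenario_events <- function(panel) {
  span <- function(labels) {
    idx <- panel_exon_indices(panel, labels)
    if (length(idx) == 0L) stop("panel lacks exon(s) ",
                                paste(labels, collapse = ","))
    c(min(idx), max(idx))
  }
  list(multi = span(c("BRCA1_ex21", "BRCA1_ex22")),
       double = span("BRCA1_ex23"),
       single = span("BRCA1_ex20"))
}

#' Simulated validation cohort for the full pipeline
#'
#' Fixed cohort layout emulating a diagnostic validation study: 127
#' rearrangement-negative reference samples (`REF001`-`REF127`, the DQ
#' baseline; the first 20 double as the HMM baseline) plus 85 test samples
#' (`VS001`-`VS085`) of which exactly three carry heterozygous BRCA1
#' deletions — a 7-amplicon exon 21-22 deletion (`VS010`), a 2-amplicon
#' exon 23 deletion (`VS040`) and a single-amplicon exon 20 deletion
#' (`VS070`, the event a minimum-two-amplicon HMM caller cannot report).
#' One negative test sample (`VS025`) is heavily degraded.  The three
#' carriers are standard-quality samples; all other simulator settings are
#' the [simulate_cohort()] defaults.
#'
#' @param seed Integer seed.
#' @return A `sim_cohort` with extra elements `reference_ids`,
#'   `hmm_reference_ids`, `test_ids`.
#' @export
validation_scenario <- function(seed = 1L) {
  panel <- simulate_panel(167L, 3L)
  ev <- scenario_events(panel)
  n_ref <- 127L
  n_test <- 85L
  ids <- c(sprintf("REF%03d", seq_len(n_ref)),
           sprintf("VS%03d", seq_len(n_test)))
  carriers <- n_ref + c(10L, 40L, 70L)
  events <- data.frame(sample = carriers,
                       first = c(ev$multi[1L], ev$double[1L],
                                 ev$single[1L]),
                       last = c(ev$multi[2L], ev$double[2L], ev$single[2L]),
                       copy_number = 1L)
  cohort <- simulate_cohort(panel, n_ref + n_test, sample_ids = ids,
                            events = events,
                            degraded_samples = n_ref + 25L,
                            standard_quality_samples = carriers,
                            seed = seed)
  cohort$reference_ids <- ids[seq_len(n_ref)]
  cohort$hmm_reference_ids <- ids[seq_len(20L)]
  cohort$test_ids <- ids[n_ref + seq_len(n_test)]
  cohort
}

#' Write / read a truth table
#'
#' TSV with columns `sample_id`, `lgr_status`, `type`, `first_amplicon`,
#' `last_amplicon` (event columns `NA` for negative samples).
#'
#' @param truth Truth data frame (e.g. `cohort$truth`).
#' @param path File path.
#' @param header Optional comment lines.
#' @export
write_truth <- function(truth, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  df$lgr_status <- as.logical(df$lgr_status)
  df
}
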