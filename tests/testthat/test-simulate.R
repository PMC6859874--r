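test_that("the synthetic panel has the advertised structure", {
  panel <- simulate_panel(167L, 3L)
  expect_equal(nrow(panel), 167L)
  expect_equal(attr(panel, "pools"), 1:3)
  expect_equal(sort(unique(panel$gene)), c("BRCA1", "BRCA2"))
  expect_true(!is.unsorted(panel$start[panel$chrom == "chr17"]))
  # at least one exon covered by a single amplicon (the HMM blind spot)
  per_exon <- table(panel$exon_label)
  expect_true(any(per_exon == 1L))
  expect_equal(unname(per_exon["BRCA1_ex20"]), 1L)
})

test_that("identical seeds give identical cohorts, byte-for-byte on disk", {
  panel <- simulate_panel(30L)
  a <- simulate_cohort(panel, 10L, seed = 99L)
  b <- simulate_cohort(panel, 10L, seed = 99L)
  expect_identical(a$counts, b$counts)
  fa <- tempfile()
  fb <- tempfile()
  write_coverage(a$counts, fa, panel)
  write_coverage(b$counts, fb, panel)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(a$counts,
                         simulate_cohort(panel, 10L, seed = 100L)$counts))
})

test_that("in the noise-free limit every DQ is 1 within 1e-2", {
  panel <- simulate_panel(20L)
  sim <- simulate_cohort(panel, 10L, library_size_mean = 1e7,
                         dispersion = 1e9, low_quality_fraction = 0,
                         pool_effect_sigma = 0, seed = 2L)
  fit <- dq_fit(sim$counts, panel, "dqa")
  expect_true(all(abs(fit$dq - 1) < 1e-2))
})

test_that("empirical amplicon means track the generative efficiencies", {
  panel <- simulate_panel(20L)
  sim <- simulate_cohort(panel, 2000L, pool_effect_sigma = 0, seed = 31L)
  got <- colMeans(sim$counts) / mean(rowSums(sim$counts))
  want <- sim$efficiency / sum(sim$efficiency)
  expect_true(all(abs(got / want - 1) < 0.02))
})

test_that("an injected heterozygous deletion halves the expected counts", {
  panel <- simulate_panel(30L)
  events <- data.frame(sample = 5L, first = 10L, last = 12L,
                       copy_number = 1L)
  ratios <- vapply(1:200, function(r) {
    with_ev <- simulate_cohort(panel, 8L, events = events,
                               standard_quality_samples = 5L,
                               seed = 4000L + r)
    without <- simulate_cohort(panel, 8L, standard_quality_samples = 5L,
                               seed = 4000L + r)
    sum(with_ev$counts[5L, 10:12]) / sum(without$counts[5L, 10:12])
  }, numeric(1L))
  expect_gt(mean(ratios), 0.45)
  expect_lt(mean(ratios), 0.55)
})

test_that("mean DQ over a 3-amplicon deletion sits near one half copy dose", {
  panel <- simulate_panel(40L)
  events <- data.frame(sample = 21L, first = 15L, last = 17L,
                       copy_number = 1L)
  inside <- vapply(1:100, function(r) {
    sim <- simulate_cohort(panel, 21L, events = events,
                           standard_quality_samples = 21L,
                           seed = 5000L + r)
    fit <- dq_fit(sim$counts, panel, "dqb2",
                  reference_ids = rownames(sim$counts)[1:20])
    m <- mean(fit$dq["S021", 15:17])
    m > 0.4 && m < 0.6
  }, logical(1L))
  expect_gte(mean(inside), 0.99)
})

test_that("the validation scenario carries the advertised truth structure", {
  co <- validation_scenario(seed = 3L)
  expect_equal(length(co$reference_ids), 127L)
  expect_equal(length(co$test_ids), 85L)
  expect_equal(length(co$hmm_reference_ids), 20L)
  expect_equal(sum(co$truth$lgr_status), 3L)
  sizes <- co$events$last - co$events$first + 1L
  expect_equal(sort(sizes), c(1L, 2L, 7L))
  expect_equal(sum(sizes == 1L), 1L)  # exactly one single-amplicon event
  expect_true(all(co$truth$lgr_status[match(co$events$sample_id,
                                            co$truth$sample_id)]))
  # truth table round trip
  f <- tempfile()
  write_truth(co$truth, f)
  expect_equal(read_truth(f), co$truth)
})

test_that("invalid event definitions are rejected", {
  panel <- simulate_panel(20L)
  expect_error(simulate_cohort(panel, 4L,
                               events = data.frame(sample = 1L, first = 5L,
                                                   last = 25L,
                                                   copy_number = 1L)),
               "invalid event")
  expect_error(simulate_cohort(panel, 4L,
                               events = data.frame(sample = 1L, first = 5L,
                                                   last = 6L,
                                                   copy_number = 2L)),
               "invalid event")
})
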