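test_that("normalization yields the expected fractions in both scopes", {
  panel <- toy_panel(3L)
  counts <- toy_counts(c(10L, 30L, 60L), "S1", panel)
  norm <- normalize_coverage(counts, panel, "panel_wide")
  expect_equal(unname(norm[1L, ]), c(0.1, 0.3, 0.6))
  p4 <- toy_panel(4L)
  eq <- toy_counts(rep(25L, 4L), "S1", p4)
  expect_equal(unname(normalize_coverage(eq, p4)[1L, ]), rep(0.25, 4L))
  pp <- toy_panel(3L, pools = c(1L, 1L, 2L))
  counts2 <- toy_counts(c(10L, 10L, 40L), "S1", pp)
  expect_equal(unname(normalize_coverage(counts2, pp, "per_pool")[1L, ]),
               c(0.5, 0.5, 1.0))
  zero <- toy_counts(c(0L, 0L, 5L), "S1", pp)
  expect_error(normalize_coverage(zero, pp, "per_pool"), "S1.*pool 1")
})

test_that("dqa self-normalizes and matches the closed-form hand computation", {
  panel <- toy_panel(4L)
  counts <- toy_counts(rep(100L, 32L), sprintf("S%d", 1:8), panel)
  fit <- dq_fit(counts, panel, "dqa")
  expect_true(all(abs(fit$dq - 1) < 1e-12))
  # one sample's first amplicon halved among 9 identical co-samples:
  # hand formula dq = f1 / mean(f) with f the panel-wide fractions
  counts10 <- toy_counts(rep(100L, 40L), sprintf("S%d", 1:10), panel)
  counts10["S10", 1L] <- 50L
  fit10 <- dq_fit(counts10, panel, "dqa")
  f_case <- 50 / 350
  f_other <- 100 / 400
  expected <- f_case / ((9 * f_other + f_case) / 10)
  expect_equal(unname(fit10$dq["S10", 1L]), expected, tolerance = 1e-12)
  expect_lt(fit10$dq["S10", 1L], 1)
  expect_true(all(fit10$dq["S10", 1L] < fit10$dq[1:9, 1L]))
  # below the chip-size minimum, dqa refuses and points at dqb
  expect_error(dq_fit(counts10[1:5, ], panel, "dqa"), "dqb")
})

test_that("baselines reproduce textbook statistics and respect the SD floor", {
  panel <- toy_panel(4L)
  ident <- toy_counts(rep(c(10L, 20L, 30L, 40L), 2L), c("R1", "R2"), panel)
  b <- build_baseline(ident, panel, c("R1", "R2"), "B1_panel_wide")
  expect_equal(b$mean, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(b$sd, 0.01 * b$mean)  # identical refs -> floored SD
  # known fractions -> n-1 sample statistics, recomputed independently
  counts <- toy_counts(c(10L, 20L, 30L, 40L,
                         20L, 20L, 30L, 30L,
                         15L, 25L, 25L, 35L), c("R1", "R2", "R3"), panel)
  b3 <- build_baseline(counts, panel, c("R1", "R2", "R3"), "B1_panel_wide")
  frac <- counts / rowSums(counts)
  for (a in 1:4) {
    m <- sum(frac[, a]) / 3
    s <- sqrt(sum((frac[, a] - m)^2) / 2)
    expect_equal(b3$mean[a], m)
    expect_equal(b3$sd[a], max(s, 0.01 * m))
  }
  # per-pool mode: means sum to 1 within each pool
  pp <- toy_panel(4L, pools = c(1L, 1L, 2L, 2L))
  b2 <- build_baseline(counts, pp, c("R1", "R2", "R3"), "B2_per_pool")
  expect_equal(sum(b2$mean[1:2]), 1)
  expect_equal(sum(b2$mean[3:4]), 1)
  expect_error(build_baseline(counts, panel, c("R1", "nope")), "nope")
  expect_error(build_baseline(counts, panel, "R1"), "2 reference")
  zero <- counts
  zero[, 2L] <- 0L
  expect_error(build_baseline(zero, panel, c("R1", "R2", "R3"),
                              "B1_panel_wide"), "A02")
})

test_that("dqb is exact on the baseline profile and absorbs pool batch effects only in dqb2", {
  pp <- toy_panel(4L, pools = c(1L, 1L, 2L, 2L))
  refs <- toy_counts(rep(c(100L, 100L, 200L, 200L), 2L), c("R1", "R2"), pp)
  b1 <- build_baseline(refs, pp, c("R1", "R2"), "B1_panel_wide")
  b2 <- build_baseline(refs, pp, c("R1", "R2"), "B2_per_pool")
  same <- toy_counts(c(100L, 100L, 200L, 200L), "T1", pp)
  expect_equal(unname(dq_fit(same, pp, "dqb1", baseline = b1)$dq[1L, ]),
               rep(1, 4L))
  expect_equal(unname(dq_fit(same, pp, "dqb2", baseline = b2)$dq[1L, ]),
               rep(1, 4L))
  # pool 2 uniformly doubled: invisible to dqb2, visible to dqb1
  batch <- toy_counts(c(100L, 100L, 400L, 400L), "T1", pp)
  expect_equal(unname(dq_fit(batch, pp, "dqb2", baseline = b2)$dq[1L, ]),
               rep(1, 4L), tolerance = 1e-9)
  dq1 <- dq_fit(batch, pp, "dqb1", baseline = b1)$dq[1L, ]
  expect_equal(unname(dq1), c(0.6, 0.6, 1.2, 1.2))  # hand computation
  expect_error(dq_fit(batch, pp, "dqb1", baseline = b2), "does not match")
})

test_that("a heterozygous deletion lands below threshold at the closed-form DQ", {
  panel <- toy_panel(6L)
  refs <- toy_counts(rep(100L, 12L), c("R1", "R2"), panel)
  b <- build_baseline(refs, panel, c("R1", "R2"), "B1_panel_wide")
  test <- toy_counts(c(50L, 50L, 50L, 100L, 100L, 100L), "T1", panel)
  fit <- dq_fit(test, panel, "dqb1", baseline = b)
  # renormalization: deleted fraction (50/450) over baseline mean (1/6)
  expect_equal(unname(fit$dq[1L, 1:3]), rep(0.5 / (450 / 600), 3L))
  expect_true(all(fit$dq[1L, 1:3] < fit$lo[1:3]))
  del <- fit$calls[fit$calls$type == "del", ]
  expect_equal(del$n_amplicons, 3L)
  expect_equal(del$first_amplicon, "A01")
  expect_equal(del$evidence, "hard")
  # removing half the panel dose inflates the remaining fractions to 4/3,
  # which this extreme toy reports as a complementary duplication run
  expect_equal(fit$calls$type[fit$calls$type != "del"], "dup")
})

test_that("library-size invariance holds in every DQ mode", {
  panel <- toy_panel(5L)
  set.seed(42)
  counts <- matrix(rpois(50L, 500L), 10L, 5L,
                   dimnames = list(sprintf("S%d", 1:10), panel$amplicon_id))
  b1 <- build_baseline(counts, panel, sprintf("S%d", 1:4), "B1_panel_wide")
  b2 <- build_baseline(counts, panel, sprintf("S%d", 1:4), "B2_per_pool")
  scaled <- counts
  scaled["S7", ] <- scaled["S7", ] * 10L
  for (args in list(list(mode = "dqa"),
                    list(mode = "dqb1", baseline = b1),
                    list(mode = "dqb2", baseline = b2))) {
    f0 <- do.call(dq_fit, c(list(counts, panel), args))
    f1 <- do.call(dq_fit, c(list(scaled, panel), args))
    expect_equal(f0$dq, f1$dq, tolerance = 1e-9,
                 label = paste("dq in mode", args$mode))
  }
})

test_that("hard flags use strict inequalities", {
  expect_equal(flag_amplicons(c(1.0, 0.5, 0.8, 1.2, 1.3),
                              lo = rep(0.8, 5L), hi = rep(1.2, 5L)),
               c("normal", "del_hard", "normal", "normal", "dup_hard"))
  expect_error(flag_amplicons(1, lo = 1.2, hi = 0.8), "lo < hi")
})

test_that("run calling distinguishes hard runs, soft runs and sub-threshold noise", {
  center <- 1
  sd <- 0.1  # lo/hi = 0.8/1.2, soft band 0.9/1.1
  dq <- c(1, 0.5, 0.5, 0.5, 1, 1)
  runs <- cnv_runs(dq, center, sd)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$first, 2L)
  expect_equal(runs$n_amplicons, 3L)
  expect_equal(runs$evidence, "hard")
  single <- cnv_runs(c(1, 1, 0.5, 1), center, sd)
  expect_equal(single$n_amplicons, 1L)
  expect_equal(single$evidence, "hard")
  # three consecutive inside (lo, center - 1 sd): soft call
  soft <- cnv_runs(c(1, 0.85, 0.85, 0.85, 1), center, sd)
  expect_equal(soft$evidence, "soft")
  expect_equal(soft$first, 2L)
  expect_equal(soft$last, 4L)
  # only two consecutive: no call
  expect_equal(nrow(cnv_runs(c(1, 0.85, 0.85, 1, 1), center, sd)), 0L)
  # duplication side, mixed hard/soft run reported over its full extent
  mixed <- cnv_runs(c(1, 1.15, 1.3, 1.15, 1), center, sd)
  expect_equal(mixed$evidence, c("soft", "hard"))  # ordered by position
  expect_equal(mixed$n_amplicons, c(3L, 1L))
  expect_equal(mixed$type, c("dup", "dup"))
})

test_that("zero-count amplicons give dq = 0 and a hard deletion flag", {
  panel <- toy_panel(4L)
  refs <- toy_counts(rep(100L, 8L), c("R1", "R2"), panel)
  b <- build_baseline(refs, panel, c("R1", "R2"), "B1_panel_wide")
  test <- toy_counts(c(0L, 100L, 100L, 100L), "T1", panel)
  fit <- dq_fit(test, panel, "dqb1", baseline = b)
  expect_equal(unname(fit$dq[1L, 1L]), 0)
  expect_equal(unname(fit$flags[1L, 1L]), "del_hard")
})

test_that("sample QC counts outliers and flags degraded profiles", {
  flags <- matrix("normal", 1L, 100L,
                  dimnames = list("S1", sprintf("A%03d", 1:100)))
  fake <- structure(list(dq = matrix(1, 1L, 100L,
                                     dimnames = dimnames(flags)),
                         flags = flags, degraded_threshold = 0.10),
                    class = "dq_fit")
  qc <- sample_qc(fake)
  expect_equal(qc$outlier_fraction, 0)
  expect_false(qc$degraded)
  fake$flags[1L, 1:20] <- "del_hard"
  qc2 <- sample_qc(fake)
  expect_equal(qc2$outlier_fraction, 0.20)
  expect_true(qc2$degraded)
})

test_that("simulated degraded samples are flagged degraded almost always", {
  panel <- simulate_panel(167L)
  hits <- vapply(1:200, function(r) {
    sim <- simulate_cohort(panel, 41L, degraded_samples = 41L,
                           seed = 7000L + r)
    fit <- dq_fit(sim$counts, panel, "dqb2",
                  reference_ids = rownames(sim$counts)[1:40])
    fit$qc$degraded[fit$qc$sample_id == "S041"]
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})
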