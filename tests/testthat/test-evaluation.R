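mk_call <- function(sample, first, last, panel, caller = "DQ",
                    type = "del") {
  dqcnv:::annotate_calls(
    data.frame(first = first, last = last, type = type, evidence = "hard",
               n_amplicons = last - first + 1L, score = 1),
    panel, sample_id = sample, caller = caller)
}

test_that("caller concordance detects overlapping and disjoint regions", {
  panel <- toy_panel(25L)
  dq <- mk_call("S1", 10L, 12L, panel)
  hmm_overlap <- mk_call("S1", 11L, 13L, panel, caller = "HMM")
  cc <- match_calls(dq, hmm_overlap, panel)
  expect_true(cc$shared_region)
  hmm_far <- mk_call("S1", 20L, 22L, panel, caller = "HMM")
  cc2 <- match_calls(dq, hmm_far, panel)
  expect_true(cc2$dq_positive && cc2$hmm_positive)
  expect_false(cc2$shared_region)
  none <- dqcnv:::annotate_calls(NULL, panel)
  cc3 <- match_calls(dq, none, panel)
  expect_true(cc3$dq_positive)
  expect_false(cc3$hmm_positive)
})

test_that("triage routes samples per the operative decision rule", {
  cc <- data.frame(sample_id = c("neg", "both", "dqonly", "hmmonly"),
                   dq_positive = c(FALSE, TRUE, TRUE, FALSE),
                   hmm_positive = c(FALSE, TRUE, FALSE, TRUE),
                   shared_region = c(FALSE, TRUE, FALSE, FALSE))
  tr <- triage(cc)
  expect_equal(tr$decision,
               c("REPORT_NEGATIVE", "DIRECT_CONFIRMATION", "MLPA_REQUIRED",
                 "REPORT_NEGATIVE"))
  expect_equal(tr$review_flag, c(FALSE, FALSE, FALSE, TRUE))
  # double positive with disjoint regions still needs MLPA
  cc$shared_region[2L] <- FALSE
  expect_equal(triage(cc)$decision[2L], "MLPA_REQUIRED")
  # pure function: permuting the cohort permutes, never changes, decisions
  perm <- sample(nrow(cc))
  tr_perm <- triage(cc[perm, ])
  expect_equal(tr_perm$decision[order(perm)], triage(cc)$decision)
})

test_that("confusion counts cross-tabulate and demand matching sample sets", {
  pred <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  truth <- c(d = FALSE, c = TRUE, b = FALSE, a = TRUE)
  cm <- confusion(pred, truth)
  expect_equal(cm$tp, 2L)
  expect_equal(cm$fp + cm$fn, 0L)
  expect_equal(cm$tn, 2L)
  expect_error(confusion(pred, truth[1:3]), "different sample sets")
  expect_error(confusion(unname(pred), truth), "named")
  expect_error(confusion_counts(1, -1, 0, 0), "non-negative")
})

test_that("metric point estimates match the defining ratios on published-style counts", {
  m <- compute_metrics(confusion_counts(3L, 30L, 52L, 0L))
  get <- function(x, what) x$estimate[x$metric == what]
  expect_equal(get(m, "accuracy"), 55 / 85)
  expect_equal(get(m, "sensitivity"), 1)
  expect_equal(get(m, "specificity"), 52 / 82)
  expect_equal(get(m, "npv"), 1)
  m2 <- compute_metrics(confusion_counts(2L, 27L, 55L, 1L))
  expect_equal(get(m2, "sensitivity"), 2 / 3)
  expect_equal(get(m2, "npv"), 55 / 56)
  # undefined metrics are absent, not zero
  m3 <- compute_metrics(confusion_counts(0L, 2L, 5L, 0L))
  expect_false("sensitivity" %in% m3$metric)
  expect_true(all(c("accuracy", "specificity", "npv") %in% m3$metric))
  expect_error(compute_metrics(confusion_counts(0L, 0L, 0L, 0L)), "zero")
})

test_that("wilson intervals hit exact boundaries and agree with prop.test", {
  expect_equal(wilson_ci(10L, 10L)[["upper"]], 1)
  expect_equal(wilson_ci(0L, 10L)[["lower"]], 0)
  for (case in list(c(26L, 52L), c(3L, 3L), c(1L, 85L), c(52L, 52L),
                    c(17L, 123L))) {
    got <- wilson_ci(case[1L], case[2L], 0.95)
    ref <- suppressWarnings(
      prop.test(case[1L], case[2L], correct = FALSE))$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-9,
                 label = paste("wilson", case[1L], "/", case[2L]))
  }
  expect_error(wilson_ci(5L, 3L), "successes")
})

test_that("wilson intervals contain the estimate and shrink with n", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:500, 1L)
    x <- sample(0:n, 1L)
    ci <- wilson_ci(x, n)
    expect_lte(ci[["lower"]], x / n)
    expect_gte(ci[["upper"]], x / n)
    expect_gte(ci[["lower"]], 0)
    expect_lte(ci[["upper"]], 1)
  }
  widths <- vapply(c(10L, 20L, 40L, 80L, 160L), function(n)
    diff(wilson_ci(n %/% 2L, n)), numeric(1L))
  expect_true(all(diff(widths) < 0))
})

test_that("report rounding is half-up, not banker's", {
  expect_equal(round_half_up(64.70588, 1L), 64.7)
  expect_equal(round_half_up(66.66667, 1L), 66.7)
  expect_equal(round_half_up(0.25, 1L), 0.3)
  expect_equal(round_half_up(-0.25, 1L), -0.3)
})

test_that("sample positivity pools evidence across call sets", {
  panel <- toy_panel(10L)
  a <- mk_call("S2", 1L, 2L, panel)
  b <- mk_call("S3", 4L, 5L, panel)
  pos <- sample_positivity(a, b, sample_ids = c("S1", "S2", "S3"))
  expect_equal(unname(pos), c(FALSE, TRUE, TRUE))
})
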