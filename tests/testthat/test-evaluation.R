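test_that("pair-counting AUROC matches hand-enumerated cases", {
  expect_equal(auroc(c(0.9, 0.8), c(0.7, 0.1)), 1.0)
  # 4 pairs: (0.8 beats both) + (0.4 beats 0.2 only) = 3/4
  expect_equal(auroc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  set.seed(1)
  expect_lt(abs(auroc(rnorm(2000), rnorm(2000)) - 0.5), 0.05)
  expect_error(auroc(numeric(0), 1), "non-empty")

  # ties count one half
  expect_equal(auroc(c(0.5), c(0.5)), 0.5)
})

test_that("roc_curve endpoints and monotonicity are sane", {
  rc <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$tpr[1], 0); expect_equal(rc$fpr[1], 0)
  expect_equal(utils::tail(rc$tpr, 1), 1)
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
})

test_that("per-base precision/recall honours tolerance and edge cases", {
  mk <- function(v) list(plus = list(c1 = v), minus = list(c1 = rep(FALSE, length(v))))
  truth <- rep(FALSE, 400); truth[101:200] <- TRUE
  pred <- rep(FALSE, 400); pred[151:250] <- TRUE

  r0 <- pr_per_base(mk(pred), mk(truth), tolerance_bp = 0)
  expect_equal(r0$precision, 0.5)
  expect_equal(r0$recall, 0.5)

  r100 <- pr_per_base(mk(pred), mk(truth), tolerance_bp = 100)
  expect_equal(r100$precision, 1.0)    # all predicted within 100 bp of truth
  expect_equal(r100$recall, 0.5)       # tolerance applies to precision only

  ident <- pr_per_base(mk(truth), mk(truth))
  expect_equal(ident$precision, 1); expect_equal(ident$recall, 1)

  none <- pr_per_base(mk(rep(FALSE, 400)), mk(truth))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
})

test_that("random baseline converges to the guessing probability", {
  set.seed(2)
  r <- random_baseline_pr(0.5, 0.5, n = 50000, replicates = 5)
  expect_lt(abs(r$precision - 0.5), 0.02)
  expect_lt(abs(r$recall - 0.5), 0.02)

  r1 <- random_baseline_pr(1 - 1e-9, 0.3, n = 50000, replicates = 3)
  expect_equal(r1$recall, 1, tolerance = 1e-4)
  expect_lt(abs(r1$precision - 0.3), 0.02)
})

test_that("transcript matching agrees with exhaustive assignment", {
  tr <- transcript_annotations(data.frame(
    id = c("a", "b", "c"), chrom = "c1", strand = "+",
    start = c(100, 1000, 2000), end = c(600, 1600, 2600),
    tss_pos = c(100, 1000, 2000), cpa_pos = c(599, 1599, 2599)))
  ident <- transcript_match(tr, tr, 200)
  expect_equal(ident$precision, 1); expect_equal(ident$recall, 1)

  shifted <- tr; shifted$tss_pos <- shifted$tss_pos + 300
  expect_equal(transcript_match(shifted, tr, 200)$recall, 0)

  pred <- tr[1:2, ]; pred$tss_pos[2] <- 5000; pred$cpa_pos[2] <- 5400
  m <- transcript_match(pred, tr, 200)
  expect_equal(m$precision, 1 / 2)
  expect_equal(m$recall, 1 / 3)
  expect_identical(nrow(m$matching), bf_transcript_match(pred, tr, 200))

  set.seed(3)
  for (i in 1:10) {
    n <- 5
    strand <- sample(c("+", "-"), n, TRUE)
    lo <- seq(0, by = 2000, length.out = n) + sample(30:130, n, TRUE)
    hi <- seq(1000, by = 2000, length.out = n) - sample(30:130, n, TRUE)
    t2 <- transcript_annotations(data.frame(
      id = paste0("t", 1:n), chrom = "c1", strand = strand,
      start = lo, end = hi,
      tss_pos = ifelse(strand == "+", lo, hi - 1),
      cpa_pos = ifelse(strand == "+", hi - 1, lo)))
    p2 <- t2[sample(n, 4), ]
    p2$tss_pos <- p2$tss_pos + sample(c(-250, 0, 150, 400), 4, TRUE)
    expect_identical(nrow(transcript_match(p2, t2, 200)$matching),
                     bf_transcript_match(p2, t2, 200))
  }
})

test_that("strand cross-correlation recovers a known offset", {
  set.seed(4)
  base <- as.numeric(arima.sim(list(ar = 0.9), 3000))
  minus <- c(rep(0, 50), base)[1:3000]   # plus shifted by +50
  r <- strand_cross_correlation(base, minus, offset_range = -100:100)
  expect_identical(r$best_offset, 50L)
  expect_gt(r$best_correlation, 0.99)

  # hand-computable short tracks: every offset checked against cor()
  a <- c(1, 3, 2, 5, 4, 6); b <- c(2, 1, 4, 3, 6, 5)
  r2 <- strand_cross_correlation(a, b, offset_range = -2:2)
  for (k in -2:2) {
    i <- seq(max(1, 1 - k), min(6, 6 - k))
    expect_equal(r2$profile$correlation[r2$profile$offset == k],
                 cor(a[i], b[i + k]), tolerance = 1e-12)
  }
  expect_error(strand_cross_correlation(a, b, offset_range = 100:120),
               "overlap")
})

test_that("threshold rates count the confusion matrix directly", {
  sc <- c(0.9, 0.8, 0.2, 0.1); lb <- c(TRUE, TRUE, FALSE, FALSE)
  r <- threshold_rates(sc, lb, 0.5)
  expect_equal(r$tpr, 1); expect_equal(r$fpr, 0)
  r2 <- threshold_rates(sc, lb, 0.0)
  expect_equal(r2$tpr, 1); expect_equal(r2$fpr, 1)
  # 4-point worked case at threshold 0.85: TP=1/2, FP=0/2
  r3 <- threshold_rates(sc, lb, 0.85)
  expect_equal(r3$tpr, 0.5); expect_equal(r3$fpr, 0)
  expect_error(threshold_rates(sc, rep(TRUE, 4), 0.5), "both classes")
})

test_that("dependence rank-sum test behaves under null and extreme cases", {
  # disjoint supports reach the smallest attainable p for the sample sizes
  d <- c(10, 11, 12, 13); ind <- c(0.1, 0.2, 0.3, 0.4)
  r <- dependence_expression_test(d, ind)
  expect_lt(r$p_value, 0.05)

  # invariance to monotone transforms of the changes
  r2 <- dependence_expression_test(d^3, ind^3)
  expect_equal(r$statistic, r2$statistic)

  # null calibration: p-values roughly uniform
  set.seed(5)
  ps <- replicate(300, dependence_expression_test(rnorm(12), rnorm(12))$p_value)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.1), 0.03); expect_lt(mean(ps < 0.1), 0.2)
  expect_error(dependence_expression_test(numeric(0), 1), "non-empty")
})

test_that("evaluation report assembles tabular metadata", {
  rep_ <- evaluation_report(c("auroc", "recall"), c(0.93, 0.8), n = c(100, 50))
  expect_identical(nrow(rep_), 2L)
  expect_true(all(c("metric", "value", "n", "settings") %in% names(rep_)))
})
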