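# small separable data grouped by pseudo-chromosome
make_separable <- function(n_per_chrom = 12, n_chrom = 4, noise_cols = 3,
                           seed = 2) {
  set.seed(seed)
  n <- n_per_chrom * n_chrom
  y <- rep(c("positive", "negative"), length.out = n)
  x <- cbind(signal = ifelse(y == "positive", 1, 0) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * noise_cols), n,
                    dimnames = list(NULL, paste0("noise", seq_len(noise_cols)))))
  list(x = x, y = y, chrom = rep(paste0("c", seq_len(n_chrom)),
                                 each = n_per_chrom))
}

test_that("ensemble structure yields folds x replicates x trees total trees", {
  d <- make_separable(n_chrom = 8)
  ens <- train_ensemble(d$x, d$y, d$chrom,
                        ensemble_config(replicates_per_fold = 4,
                                        trees_per_forest = 50, seed = 1))
  expect_identical(ens$n_trees, 8L * 4L * 50L)  # the canonical 1600
  expect_identical(length(ens$folds), 8L)

  ens2 <- train_ensemble(d$x[d$chrom %in% c("c1", "c2"), ],
                         d$y[d$chrom %in% c("c1", "c2")],
                         d$chrom[d$chrom %in% c("c1", "c2")],
                         ensemble_config(1, 10, seed = 1))
  expect_identical(ens2$n_trees, 20L)

  expect_error(train_ensemble(d$x[0, ], character(0), character(0)),
               "empty")
  one_class <- d; one_class$y[one_class$chrom != "c1"] <- "negative"
  expect_error(train_ensemble(one_class$x, one_class$y, one_class$chrom,
                              ensemble_config(1, 5)), "single class")
})

test_that("held-out predictions separate separable classes perfectly", {
  d <- make_separable()
  ens <- train_ensemble(d$x, d$y, d$chrom, ensemble_config(2, 20, seed = 3))
  sc <- txunify:::predict_heldout(ens, d$x, d$chrom)
  expect_equal(auroc(sc[d$y == "positive"], sc[d$y == "negative"]), 1.0)
})

test_that("ensemble score is the mean of per-forest probabilities", {
  d <- make_separable()
  ens <- train_ensemble(d$x, d$y, d$chrom, ensemble_config(2, 10, seed = 4))
  x <- d$x[1:5, ]
  manual <- rowMeans(do.call(cbind, lapply(ens$folds, function(f)
    sapply(f$forests, function(rf)
      predict(rf, x, type = "prob")[, "positive"]))))
  expect_equal(unname(predict(ens, x)), unname(manual), tolerance = 1e-12)
  expect_true(all(predict(ens, d$x) >= 0 & predict(ens, d$x) <= 1))
  expect_error(predict(ens, d$x[, -1]), "feature names")
})

test_that("regularized logistic classifier honours the scoring contract", {
  d <- make_separable(n_per_chrom = 30)
  lg <- train_logistic(d$x, d$y)
  sc <- predict(lg, d$x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(auroc(sc[d$y == "positive"], sc[d$y == "negative"]), 1.0)

  # pure-noise features give chance-level discrimination
  set.seed(6)
  xn <- matrix(rnorm(4000), 1000, dimnames = list(NULL, paste0("n", 1:4)))
  yn <- rep(c("positive", "negative"), 500)
  scn <- predict(train_logistic(xn, yn), xn)
  expect_lt(abs(auroc(scn[yn == "positive"], scn[yn == "negative"]) - 0.5),
            0.08)

  # constant features are dropped with a warning; fit is deterministic
  xc <- cbind(d$x, flat = 1)
  expect_warning(lgc <- train_logistic(xc, d$y), "constant")
  lg2 <- train_logistic(d$x, d$y)
  expect_equal(predict(lg2, d$x), predict(lg, d$x))
})

test_that("importance-ordered reduction keeps one copy of duplicated signal", {
  set.seed(10)
  n <- 160
  y <- rep(c("positive", "negative"), n / 2)
  sig <- ifelse(y == "positive", 1, 0) + rnorm(n, 0, 0.05)
  x <- cbind(sig1 = sig, sig2 = sig,
             n1 = rnorm(n), n2 = rnorm(n))
  chrom <- rep(c("c1", "c2", "c3"), length.out = n)
  refine <- chrom == "c3"
  ens <- train_ensemble(x[!refine, ], y[!refine], chrom[!refine],
                        ensemble_config(1, 25, seed = 2))
  kept <- reduce_features(ens, x[!refine, ], y[!refine], chrom[!refine],
                          x[refine, ], y[refine],
                          improvement_threshold = 0.002)
  expect_identical(sum(c("sig1", "sig2") %in% kept), 1L)
  expect_false(any(c("n1", "n2") %in% kept))

  # raising the threshold never enlarges the retained set
  kept_hi <- reduce_features(ens, x[!refine, ], y[!refine], chrom[!refine],
                             x[refine, ], y[refine],
                             improvement_threshold = 0.2)
  expect_true(all(kept_hi %in% kept))
  expect_error(reduce_features(ens, x, y, chrom, x[0, ], character(0)),
               "empty refinement")
})

test_that("genome scoring produces [0,1] tracks with the documented geometry", {
  mc <- micro_init_classifier()
  g <- Genome(c(c1 = strrep("A", 1500)))
  tr <- score_genome(g, mc$ensemble, mc$scheme, mc$specs, toy_motifs(),
                     stride = 10)
  v <- tr$plus$c1
  expect_length(v, 1500L)
  expect_true(all(v >= 0 & v <= 1))
  # homogeneous sequence: constant in the window-feasible interior
  expect_identical(length(unique(v[501:1400])), 1L)

  # stride-1 scoring agrees with the stride-10 track at the anchors
  sim <- small_sim2()
  sub <- Genome(c(chr01 = substr(sim$genome[["chr01"]], 1, 2500)))
  t10 <- score_genome(sub, mc$ensemble, mc$scheme, mc$specs, toy_motifs(), 10)
  t1 <- score_genome(sub, mc$ensemble, mc$scheme, mc$specs, toy_motifs(), 1)
  anchors <- seq(500, 2400, by = 10)
  expect_equal(t10$plus$chr01[anchors + 1], t1$plus$chr01[anchors + 1],
               tolerance = 1e-12)

  # reverse-complementing the genome swaps and reverses the strand tracks
  rc <- score_genome(reverse_complement_genome(sub), mc$ensemble, mc$scheme,
                     mc$specs, toy_motifs(), 10)
  L <- 2500
  a10 <- seq(500, 2400, by = 10)          # anchors scored on both layouts
  expect_equal(rc$minus$chr01[L - a10], t10$plus$chr01[a10 + 1],
               tolerance = 1e-12)
})

test_that("score tracks are reproducible and survive bedGraph export", {
  d <- make_separable()
  g <- Genome(c(c1 = paste(sample(c("A","C","G","T"), 1500, TRUE), collapse = "")))
  e1 <- train_ensemble(d$x, d$y, d$chrom, ensemble_config(1, 10, seed = 77))
  e2 <- train_ensemble(d$x, d$y, d$chrom, ensemble_config(1, 10, seed = 77))
  x <- d$x[1:8, ]
  expect_identical(predict(e1, x), predict(e2, x))

  mc <- micro_init_classifier()
  tr <- score_genome(g, mc$ensemble, mc$scheme, mc$specs, toy_motifs(), 25)
  pre <- tempfile()
  write_score_track(tr, pre)
  gr <- rtracklayer::import(paste0(pre, ".plus.bedGraph"))
  expect_equal(sum(GenomicRanges::width(gr)), 1500)
})

test_that("feature dependence reacts to neutralization as documented", {
  mc <- micro_init_classifier()
  pos_rows <- which(mc$anchors$label == "positive")
  x <- mc$features[pos_rows[1], ]
  # neutralizing everything the score uses collapses it toward background
  all_feats <- mc$ensemble$feature_names
  full <- feature_dependence(mc$ensemble, x, all_feats, threshold = 0.1)
  expect_equal(full$neutralized_score,
               unname(predict(mc$ensemble, mc$ensemble$neg_median)),
               tolerance = 1e-9)
  # dependence at a stricter threshold implies dependence at a looser one
  if (full$dependent) expect_true(full$delta >= 0.1)
  expect_true(full$delta >= full$delta - 1e-9)
  expect_error(feature_dependence(mc$ensemble, x, "nope"), "unknown")

  # a feature the example never uses cannot change the score when neutral
  x0 <- x
  x0[all_feats] <- mc$ensemble$neg_median
  r0 <- feature_dependence(mc$ensemble, x0, all_feats[1])
  expect_equal(r0$delta, 0, tolerance = 1e-9)
})

test_that("model persistence round-trips through the versioned container", {
  d <- make_separable()
  ens <- train_ensemble(d$x, d$y, d$chrom, ensemble_config(1, 5, seed = 1))
  p <- tempfile(fileext = ".rds")
  save_ensemble(ens, p)
  back <- load_ensemble(p)
  expect_identical(predict(back, d$x[1:4, ]), predict(ens, d$x[1:4, ]))
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(load_ensemble(bad), "container")
})
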