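test_that("random genomes hit the target composition and are reproducible", {
  spec <- synthetic_genome_spec(n_genes = 10, n_chrom = 1, seed = 33)
  g1 <- generate_random_genome(spec)
  g2 <- generate_random_genome(spec)
  expect_identical(unclass(g1$genome), unclass(g2$genome))
  expect_identical(g1$annotations$tss_pos, g2$annotations$tss_pos)

  big <- generate_random_genome(synthetic_genome_spec(n_genes = 40,
                                                      n_chrom = 2, seed = 44))
  n <- sum(seq_lengths(big$genome))
  gc <- sum(genome_composition(big$genome)[c("C", "G")])
  # bodies carry an A:T skew but G/C content stays at the genomic 38%
  expect_lt(abs(gc - 0.38), 3 * sqrt(0.38 * 0.62 / n) + 0.01)
})

test_that("implanted promoter and terminator grammars are present verbatim", {
  sim <- small_sim()
  ann <- sim$annotations
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    sq <- sim$genome[[a$chrom]]
    if (a$strand == "+") {
      expect_identical(substr(sq, a$tss_pos, a$tss_pos + 1), "CA")
      expect_true(substr(sq, a$cpa_pos, a$cpa_pos + 2) %in% c("GAA", "CAA"))
      term <- substr(sq, a$cpa_pos - 60, a$cpa_pos)
    } else {
      expect_identical(substr(sq, a$tss_pos + 1, a$tss_pos + 2), "TG")
      expect_true(substr(sq, a$cpa_pos, a$cpa_pos + 2) %in% c("TTG", "TTC"))
      term <- reverse_complement(substr(sq, a$cpa_pos + 2, a$cpa_pos + 62))
    }
    expect_gte(count_matches(term, "TATATA"), 1L)
  }
  # implant inventory records at least GRF + polyA + initiator + Hrp1 + cleavage
  inv <- sim$implants
  expect_true(all(c("initiator", "cleavage", "Hrp1") %in% inv$what))
  expect_true(any(inv$what %in% c("Reb1", "Abf1", "Rap1")))
})

test_that("ground-truth state map is consistent with the annotations", {
  sim <- small_sim()
  expect_identical(
    vapply(sim$state_map$states, length, integer(1)),
    seq_lengths(sim$genome))
  # convergent pairs produce Term states
  tab <- table(unlist(sim$state_map$states))
  expect_gt(tab[[as.character(match("Term", UM_STATES))]], 0)
})

test_that("expression simulation follows the abundance model", {
  g <- Genome(c(c1 = strrep("A", 2000)))
  len <- seq_lengths(g)
  ann0 <- transcript_annotations(data.frame(
    id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer()))
  expect_true(all(simulate_expression(ann0, len)$c1 == 0))

  ann1 <- transcript_annotations(data.frame(
    id = "t", chrom = "c1", strand = "+", start = 500, end = 900,
    tss_pos = 500, cpa_pos = 899), g)
  set.seed(2)
  tr <- simulate_expression(ann1, len, noise_sd = 0)
  expect_identical(length(unique(tr$c1[501:900])), 1L)   # rectangle
  expect_true(all(tr$c1[-(501:900)] == 0))

  # many transcripts: mean abundance approaches the log-normal mean
  annN <- transcript_annotations(data.frame(
    id = paste0("t", 1:400), chrom = "c1", strand = "+",
    start = 100, end = 300, tss_pos = 100, cpa_pos = 299), g,
    tss_width = 2, cpa_width = 2)
  set.seed(3)
  trN <- simulate_expression(annN, len, meanlog = 2, sdlog = 0.5,
                             noise_sd = 0)
  per_tx <- trN$c1[200] / 400
  expect_lt(abs(per_tx - exp(2 + 0.5^2 / 2)) / exp(2 + 0.5^2 / 2), 0.15)
})

test_that("sort-seq expression estimation is the fluorescence-weighted mean", {
  f <- c(10, 100)
  expect_equal(estimate_sortseq_expression(matrix(c(5, 0), 1), f), 10)
  expect_equal(estimate_sortseq_expression(matrix(c(3, 3), 1), f), 55)
  expect_equal(estimate_sortseq_expression(matrix(c(1, 3), 1), f), 77.5)
  # invariant to rescaling all counts
  cnt <- matrix(c(2, 5, 1, 8, 0, 4), 1)
  f6 <- exp(seq(0, 5, length.out = 6))
  expect_equal(estimate_sortseq_expression(cnt, f6),
               estimate_sortseq_expression(10 * cnt, f6))
  expect_error(estimate_sortseq_expression(matrix(0, 1, 2), f), "zero total")
  expect_error(estimate_sortseq_expression(matrix(1, 1, 3), f), "per bin")

  # simulated counts rank-correlate with the true expression
  set.seed(4)
  expr <- exp(rnorm(50, 2, 1))
  ss <- simulate_sortseq_counts(expr, n_reads = 200)
  est <- estimate_sortseq_expression(ss$counts, ss$bin_fluorescence)
  expect_gt(cor(est, expr, method = "spearman"), 0.8)
  expect_identical(ncol(ss$counts), 6L)   # six fluorescence bins
})

test_that("promoter library design enumerates and controls combinations", {
  set.seed(5)
  mc <- micro_init_classifier()
  lib <- design_promoter_library(mc$ensemble, mc$scheme, mc$specs,
                                 toy_motifs(),
                                 n_candidates = c(2L, 3L, 4L),
                                 keep = c(2L, 2L, 2L), tfbs_prob = 1)
  expect_identical(lib$n_scored, 24L)      # 2 x 3 x 4 combinations scored
  expect_identical(lib$n_combinations, 8)  # kept set product
  for (si in 1:3) {
    sec <- lib$sections[[si]]
    for (r in seq_len(nrow(sec))) {
      if (is.na(sec$tfbs[r])) next
      s <- strsplit(sec$sequence[r], "")[[1]]
      ctl <- strsplit(sec$control[r], "")[[1]]
      diffs <- which(s != ctl)
      expect_gt(length(diffs), 0)
      w <- nchar(sample_site(toy_motifs()[[sec$tfbs[r]]]))
      expect_true(all(diffs > sec$tfbs_pos[r] &
                        diffs <= sec$tfbs_pos[r] + w))
    }
  }
})

test_that("random fragments carry the requested consensus insertions", {
  set.seed(6)
  fr <- design_random_fragment(3000, 0.38,
                               c(Abf1 = 2L, Rap1 = 0L),
                               motifs = toy_motifs())
  expect_identical(nchar(fr$sequence), 3000L)
  cons <- paste(c("A","C","G","T")[apply(toy_motifs()$Abf1$pfm, 1, which.max)],
                collapse = "")
  expect_gte(count_matches(fr$sequence, cons, both_strands = TRUE), 2L)

  # background-only fragments match the analytic consensus density
  set.seed(7)
  pat <- "CGCGC"   # the Rsc3 consensus
  lambda <- expected_match_density(pat, c(0.31, 0.19, 0.19, 0.31))
  tot <- 0; n <- 40
  for (i in seq_len(n))
    tot <- tot + count_matches(design_random_fragment(3000, 0.38)$sequence, pat)
  mu <- lambda * 3 * n
  expect_lt(abs(tot - mu), 4 * sqrt(mu))
})
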