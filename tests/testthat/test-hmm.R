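test_that("canonical structure has 24 allowed transitions, closed under sigma", {
  st <- build_structure()
  expect_identical(sum(st$allowed), 24L)
  expect_identical(sum(!st$allowed), 40L)
  expect_false(st$allowed["Gene+", "Gene-"])
  # sigma closure: (a -> b) allowed iff (sigma(b) -> sigma(a)) allowed
  sig <- st$sigma_state
  for (a in st$states) for (b in st$states)
    expect_identical(st$allowed[a, b], st$allowed[sig[[b]], sig[[a]]])
  # the two strand cycles are present
  expect_true(st$allowed["IG", "TSS+"] && st$allowed["TSS-", "IG"])
  expect_true(st$allowed["Gene+", "Term"] && st$allowed["Term", "Gene-"])
})

test_that("free-parameter counting ties emission orbits, not transitions", {
  expect_identical(count_free_parameters(build_structure()), 56L)

  # one-state, one-observation toy with a self loop: mean + var + transition
  toy <- list(states = "S", obs = "o", allowed = matrix(TRUE, 1, 1),
              sigma_state = c(S = "S"), sigma_obs = c(o = "o"))
  expect_identical(count_free_parameters(toy), 3L)

  # untied counting on the canonical structure: 24 + 32 + 32
  st <- build_structure()
  untied <- sum(st$allowed) + 2L * length(st$states) * length(st$obs)
  expect_identical(untied, 88L)
})

test_that("symmetrization averages emission orbits and is idempotent", {
  st <- build_structure()
  set.seed(1)
  means <- matrix(runif(32), 8, 4, dimnames = list(st$states, st$obs))
  vars <- matrix(runif(32, 0.01, 0.05), 8, 4)
  A <- matrix(0, 8, 8); A[st$allowed] <- runif(24, 0.1, 1)
  diag(A) <- diag(A) + 10
  A <- A / rowSums(A)
  means["TSS+", "init+"] <- 0.8
  means["TSS-", "init-"] <- 0.6
  p <- um_parameters(means, vars, A, structure = st)
  s1 <- symmetrize(p)
  expect_equal(s1$means["TSS+", "init+"], 0.7)
  expect_equal(s1$means["TSS-", "init-"], 0.7)
  expect_true(all(abs(rowSums(s1$transitions) - 1) < 1e-12))
  expect_lt(txunify:::symmetry_residual(s1), 1e-9)

  s2 <- symmetrize(s1)
  expect_equal(s2$means, s1$means, tolerance = 1e-12)
  expect_equal(s2$transitions, s1$transitions, tolerance = 1e-10)
  expect_equal(s2$initial, s1$initial, tolerance = 1e-10)

  # the initial distribution is stationary and sigma-invariant
  expect_equal(as.numeric(s1$initial %*% s1$transitions), s1$initial,
               tolerance = 1e-10)
  sig_i <- match(st$sigma_state[st$states], st$states)
  expect_equal(s1$initial, s1$initial[sig_i], tolerance = 1e-10)
})

# a sigma-palindromic labelled chromosome containing all eight states
toy_labels <- function() {
  code <- function(x) match(x, UM_STATES)
  c(rep(code("IG"), 10), rep(code("TSS+"), 4), rep(code("Gene+"), 50),
    rep(code("CPA+"), 4), rep(code("Term"), 3), rep(code("CPA-"), 4),
    rep(code("Gene-"), 50), rep(code("TSS-"), 4), rep(code("IG"), 10))
}

test_that("parameter estimation recovers empirical moments and counts", {
  lab <- toy_labels()
  T_ <- length(lab)
  # sigma-symmetric observations: Gene+ sees init+ {0.2, 0.4} repeated,
  # Gene- the mirrored init- values, so tying leaves the moments intact
  obs <- matrix(0.1, T_, 4, dimnames = list(NULL, UM_OBS))
  gp <- which(lab == match("Gene+", UM_STATES))
  gm <- which(lab == match("Gene-", UM_STATES))
  obs[gp, "init+"] <- rep(c(0.2, 0.4), length.out = length(gp))
  obs[gm, "init-"] <- rep(c(0.2, 0.4), length.out = length(gm))
  sm <- StateMap(list(c1 = lab))
  par <- estimate_parameters(sm, list(c1 = obs))
  expect_equal(par$means["Gene+", "init+"], 0.3, tolerance = 1e-12)
  expect_equal(par$variances["Gene+", "init+"], 0.01, tolerance = 1e-9)

  # transition estimate: Gene+ has 50 bases -> 49 self-transitions of 50
  # outgoing (the mirrored Gene- run makes the counts sigma-symmetric)
  expect_equal(par$transitions["Gene+", "Gene+"], 49 / 50, tolerance = 0.02)
  expect_lt(txunify:::symmetry_residual(par), 1e-8)

  # unobserved states are an error
  lab2 <- lab[lab != match("Term", UM_STATES)]
  expect_error(estimate_parameters(StateMap(list(c1 = lab2)),
                                   list(c1 = obs[seq_along(lab2), ])),
               "never observed")
})

test_that("masked bases are excluded from moments", {
  lab <- toy_labels()
  obs <- matrix(0.1, length(lab), 4, dimnames = list(NULL, UM_OBS))
  gp <- which(lab == match("Gene+", UM_STATES))
  # poison two Gene+ bases and mask them (sigma-symmetrically)
  gm <- which(lab == match("Gene-", UM_STATES))
  obs[gp[1:2], ] <- 50
  obs[gm[1:2], ] <- 50
  msk <- rep(FALSE, length(lab)); msk[c(gp[1:2], gm[1:2])] <- TRUE
  par <- estimate_parameters(StateMap(list(c1 = lab), list(c1 = msk)),
                             list(c1 = obs))
  expect_lt(par$means["Gene+", "init+"], 1)
})

test_that("posterior decoding matches degenerate closed forms", {
  p <- random_symmetric_params(2)
  # identical emissions for all states: posterior equals the chain prior
  p_eq <- p
  p_eq$means[] <- 0.5; p_eq$variances[] <- 0.01
  obs <- matrix(runif(4 * 4), 4, 4)
  post <- posterior_decode(p_eq, obs)$posterior$seq
  prior <- p_eq$initial
  expect_equal(post[1, ], prior, tolerance = 1e-9, ignore_attr = TRUE)

  # one-base sequence: the initial distribution exactly
  post1 <- posterior_decode(p_eq, obs[1, , drop = FALSE])$posterior$seq
  expect_equal(as.numeric(post1), p_eq$initial, tolerance = 1e-12)

  # every row sums to one
  post2 <- posterior_decode(p, matrix(runif(40), 10, 4))$posterior$seq
  expect_true(all(abs(rowSums(post2) - 1) < 1e-9))
})

test_that("two-state posterior equals brute-force path enumeration", {
  set.seed(5)
  means <- matrix(runif(2), 2, 1)
  vars <- matrix(runif(2, 0.05, 0.2), 2, 1)
  A <- matrix(runif(4), 2, 2); A <- A / rowSums(A)
  init <- c(0.3, 0.7)
  obs <- matrix(rnorm(3, 0.5, 0.3), 3, 1)
  got <- txunify:::forward_backward_gaussian(obs, means, vars, A, init)
  want <- bf_posterior(obs, means, vars, A, init)
  expect_equal(got$posterior, want$posterior, tolerance = 1e-10)
  expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
})

test_that("dwell times follow the self-transition geometry", {
  p <- random_symmetric_params(3)
  d <- expected_dwell(p)
  expect_equal(unname(d), unname(1 / (1 - diag(p$transitions))),
               tolerance = 1e-12)
})

test_that("parameters round-trip through the structured text format", {
  p <- random_symmetric_params(4)
  f <- tempfile(fileext = ".txt")
  write_um_parameters(p, f)
  q <- read_um_parameters(f)
  expect_equal(q$means, p$means, tolerance = 1e-12)
  expect_equal(q$variances, p$variances, tolerance = 1e-12)
  expect_equal(q$transitions, p$transitions, tolerance = 1e-12)
  expect_equal(q$initial, p$initial, tolerance = 1e-12)
})

test_that("mean tuning never worsens the expression correlation", {
  set.seed(11)
  p <- random_symmetric_params(6)
  sim <- simulate_um(p, c(c1 = 1500L))
  # expression proportional to being in a non-IG state, plus noise
  tx <- as.numeric(sim$state_map$states$c1 != match("IG", UM_STATES))
  expr <- list(c1 = tx * exp(rnorm(1500, 2, 0.1)))
  r0 <- tune_means(p, sim$observations, expr, max_eval = 40)
  expect_gte(r0$objective, r0$initial_objective - 1e-9)
  expect_lt(txunify:::symmetry_residual(r0$params), 1e-6)

  # corrupt one tied mean: tuning must strictly improve the objective
  bad <- p
  bad$means[, "init+"] <- bad$means[, "init+"] + 0.4
  bad <- symmetrize(bad)
  r1 <- tune_means(bad, sim$observations, expr, max_eval = 150)
  expect_gt(r1$objective, r1$initial_objective)

  expect_error(tune_means(p, sim$observations, list(c1 = rep(1, 1500))),
               "constant")
})

test_that("transcript calling respects thresholds and degenerate input", {
  # all-intergenic posterior: nothing called
  p0 <- matrix(0, 500, 8, dimnames = list(NULL, UM_STATES))
  p0[, "IG"] <- 1
  pt0 <- structure(list(posterior = list(c1 = p0), loglik = 0),
                   class = "PosteriorTrack")
  expect_identical(nrow(predict_transcripts(pt0)), 0L)

  # one clean plus-strand gene
  p1 <- p0
  gene <- 101:400
  p1[, ] <- 0; p1[, "IG"] <- 1
  p1[101:130, ] <- 0; p1[101:130, "TSS+"] <- 1
  p1[131:360, ] <- 0; p1[131:360, "Gene+"] <- 1
  p1[361:400, ] <- 0; p1[361:400, "CPA+"] <- 1
  pt1 <- structure(list(posterior = list(c1 = p1), loglik = 0),
                   class = "PosteriorTrack")
  tx <- predict_transcripts(pt1, min_length = 200)
  expect_identical(nrow(tx), 1L)
  expect_identical(tx$strand, "+")
  expect_lt(abs(tx$tss_pos - 110), 30)
  expect_lt(abs(tx$cpa_pos - 380), 30)

  # a stricter threshold calls a subset of the bases called at 0.45
  tx_hi <- predict_transcripts(pt1, threshold = 0.99, min_length = 200)
  for (i in seq_len(nrow(tx_hi))) {
    j <- which(tx$chrom == tx_hi$chrom[i] & tx$strand == tx_hi$strand[i] &
                 tx$start <= tx_hi$start[i] & tx$end >= tx_hi$end[i])
    expect_gte(length(j), 1L)
  }
})
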