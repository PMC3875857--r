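# Independent oracles used to freeze expected values. These deliberately
# re-derive results by brute force, never by calling the code under test.

# posterior marginals by explicit enumeration over all K^T state paths
bf_posterior <- function(obs, means, vars, trans, init) {
  T_ <- nrow(obs); K <- nrow(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  post <- matrix(0, T_, K)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    pr <- init[s[1]]
    if (T_ > 1)
      for (t in 2:T_) pr <- pr * trans[s[t - 1], s[t]]
    for (t in seq_len(T_))
      pr <- pr * prod(stats::dnorm(obs[t, ], means[s[t], ], sqrt(vars[s[t], ])))
    total <- total + pr
    for (t in seq_len(T_)) post[t, s[t]] <- post[t, s[t]] + pr
  }
  list(posterior = post / total, loglik = log(total))
}

# AUROC by explicit trapezoidal integration of the ROC curve
trapezoid_auroc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# position-by-position IUPAC matcher
bf_iupac_count <- function(seq, pattern, overlapping = TRUE) {
  map <- Biostrings::IUPAC_CODE_MAP
  pat <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  w <- length(pat)
  hits <- integer(0)
  i <- 1
  while (i <= length(s) - w + 1) {
    ok <- all(vapply(seq_len(w), function(j)
      grepl(s[i + j - 1], map[[pat[j]]], fixed = TRUE), logical(1)))
    if (ok) {
      hits <- c(hits, i)
      i <- i + if (overlapping) 1 else w
    } else i <- i + 1
  }
  length(hits)
}

# exhaustive one-to-one transcript matching (n <= 10)
bf_transcript_match <- function(predicted, truth, off) {
  compat <- matrix(FALSE, nrow(predicted), nrow(truth))
  for (i in seq_len(nrow(predicted))) for (j in seq_len(nrow(truth)))
    compat[i, j] <- predicted$chrom[i] == truth$chrom[j] &&
      predicted$strand[i] == truth$strand[j] &&
      abs(predicted$tss_pos[i] - truth$tss_pos[j]) <= off &&
      abs(predicted$cpa_pos[i] - truth$cpa_pos[j]) <= off
  best <- 0
  rec <- function(i, used) {
    if (i > nrow(predicted)) return(0)
    m <- rec(i + 1, used)
    for (j in seq_len(nrow(truth)))
      if (compat[i, j] && !(j %in% used))
        m <- max(m, 1 + rec(i + 1, c(used, j)))
    m
  }
  if (nrow(predicted)) best <- rec(1, integer(0))
  as.integer(best)
}

# brute-force negative-anchor tiler mirroring the documented rules
bf_init_negative_anchors <- function(L, tss_same_strand, stride, exclusion,
                                     window_start = -500L, window_end = 100L,
                                     strand = "+") {
  if (strand == "+") {
    first <- -window_start; last <- L - window_end
  } else {
    first <- window_end - 1L; last <- L - 1L + window_start
  }
  anchors <- seq(first, last, by = stride)
  anchors[vapply(anchors, function(p)
    all(abs(p - tss_same_strand) >= exclusion), logical(1))]
}

# reverse-complement a transcript annotation table onto a genome of known
# chromosome lengths
revcomp_annotations <- function(ann, len) {
  out <- ann
  for (i in seq_len(nrow(ann))) {
    L <- len[[ann$chrom[i]]]
    out$strand[i] <- if (ann$strand[i] == "+") "-" else "+"
    out$start[i] <- L - ann$end[i]
    out$end[i] <- L - ann$start[i]
    out$tss_pos[i] <- L - 1L - ann$tss_pos[i]
    out$cpa_pos[i] <- L - 1L - ann$cpa_pos[i]
    ts <- ann$tss_start[i]; te <- ann$tss_end[i]
    out$tss_start[i] <- L - te; out$tss_end[i] <- L - ts
    cs <- ann$cpa_start[i]; ce <- ann$cpa_end[i]
    out$cpa_start[i] <- L - ce; out$cpa_end[i] <- L - cs
  }
  out
}

# random symmetric parameters on the canonical 8-state structure
random_symmetric_params <- function(seed = 1) {
  set.seed(seed)
  st <- build_structure()
  means <- matrix(runif(32, 0, 1), 8, 4)
  vars <- matrix(runif(32, 0.005, 0.05), 8, 4)
  A <- matrix(0, 8, 8)
  A[st$allowed] <- runif(sum(st$allowed), 0.05, 1)
  diag(A) <- diag(A) + 20            # plausible dwell times
  A <- A / rowSums(A)
  symmetrize(um_parameters(means, vars, A, structure = st))
}
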