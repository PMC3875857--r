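#' @useDynLib txunify, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The four observation tracks of the unified model
#'
#' Initiation and termination classifier scores on each strand.
#' @export
UM_OBS <- c("init+", "term+", "init-", "term-")

#' Strand-swap involution on states
#' @return named character vector mapping each state to its sigma partner.
#' @export
sigma_states <- function() {
  c("IG" = "IG", "TSS+" = "TSS-", "Gene+" = "Gene-", "CPA+" = "CPA-",
    "TSS-" = "TSS+", "Gene-" = "Gene+", "CPA-" = "CPA+", "Term" = "Term")
}

#' Strand-swap involution on observation tracks
#' @return named character vector mapping each track to its sigma partner.
#' @export
sigma_obs <- function() {
  c("init+" = "init-", "term+" = "term-", "init-" = "init+",
    "term-" = "term+")
}

#' Build the canonical 8-state strand-symmetric model structure
#'
#' Eight self-loops, the ten core transitions of the two strand cycles
#' (IG -> TSS+ -> Gene+ -> CPA+ -> IG; its sigma mirror through CPA-,
#' Gene-, TSS-; and Gene+ -> Term -> Gene- for the shared terminator), and
#' six shortcut transitions for divergent, tandem and convergent gene
#' adjacencies — 24 allowed transitions, leaving 40 of the 64 at zero.
#' The allowed set is closed under the strand-swap symmetry
#' `(a -> b) <-> (sigma(b) -> sigma(a))`.
#'
#' @return a `UMStructure`: list with `states`, `obs`, `allowed` (8 x 8
#'   logical), `sigma_state`, `sigma_obs`.
#' @export
build_structure <- function() {
  allowed <- matrix(FALSE, 8, 8, dimnames = list(UM_STATES, UM_STATES))
  diag(allowed) <- TRUE
  core <- rbind(
    c("IG", "TSS+"), c("TSS+", "Gene+"), c("Gene+", "CPA+"), c("CPA+", "IG"),
    c("IG", "CPA-"), c("CPA-", "Gene-"), c("Gene-", "TSS-"), c("TSS-", "IG"),
    c("Gene+", "Term"), c("Term", "Gene-"))
  shortcut <- rbind(
    c("TSS-", "TSS+"),   # divergent promoter, back to back starts
    c("CPA+", "TSS+"),   # tandem genes on +
    c("TSS-", "CPA-"),   # tandem genes on -
    c("CPA+", "CPA-"),   # convergent ends without a shared Term
    c("CPA+", "Term"), c("Term", "CPA-"))
  for (r in seq_len(nrow(core))) allowed[core[r, 1], core[r, 2]] <- TRUE
  for (r in seq_len(nrow(shortcut))) allowed[shortcut[r, 1], shortcut[r, 2]] <- TRUE
  structure(list(states = UM_STATES, obs = UM_OBS, allowed = allowed,
                 sigma_state = sigma_states(), sigma_obs = sigma_obs()),
            class = "UMStructure")
}

# orbit partition of (state, obs) cells under (s,o) -> (sigma s, sigma o)
emission_orbits <- function(structure) {
  S <- structure$states; O <- structure$obs
  sig_s <- match(structure$sigma_state[S], S)
  sig_o <- match(structure$sigma_obs[O], O)
  seen <- matrix(FALSE, length(S), length(O))
  orbits <- list()
  for (i in seq_along(S)) for (j in seq_along(O)) {
    if (seen[i, j]) next
    i2 <- sig_s[i]; j2 <- sig_o[j]
    seen[i, j] <- TRUE; seen[i2, j2] <- TRUE
    orbits[[length(orbits) + 1L]] <- unique(rbind(c(i, j), c(i2, j2)))
  }
  orbits
}

#' Count the free nonzero parameters of a symmetric model structure
#'
#' Nonzero transition probabilities are counted individually; emission
#' means and variances are counted once per symmetry orbit. For the
#' canonical structure this gives 24 + 16 + 16 = 56.
#'
#' @param structure a [build_structure()] result (or any structure-shaped
#'   list with `states`, `obs`, `allowed` and the sigma maps).
#' @return integer parameter count.
#' @export
count_free_parameters <- function(structure) {
  sum(structure$allowed) + 2L * length(emission_orbits(structure))
}

#' Construct the parameter set of the unified model
#'
#' @param means,variances 8 x 4 (state x track) matrices; variances > 0.
#' @param transitions 8 x 8 row-stochastic matrix, zero outside the allowed
#'   transition set.
#' @param initial initial state distribution (default uniform, the
#'   stationary distribution of any symmetry-tied transition matrix).
#' @param structure a [build_structure()] result.
#' @return a `UMParameters` object.
#' @export
um_parameters <- function(means, variances, transitions,
                          initial = rep(1 / 8, 8),
                          structure = build_structure()) {
  K <- length(structure$states)
  means <- as.matrix(means); variances <- as.matrix(variances)
  transitions <- as.matrix(transitions)
  stopifnot(nrow(means) == K, ncol(means) == length(structure$obs),
            identical(dim(variances), dim(means)),
            identical(dim(transitions), c(K, K)), length(initial) == K)
  if (any(variances <= 0)) stop("variances must be positive")
  if (any(abs(rowSums(transitions) - 1) > 1e-6))
    stop("transition rows must sum to 1")
  if (any(transitions[!structure$allowed] != 0))
    stop("nonzero transition outside the allowed set")
  if (abs(sum(initial) - 1) > 1e-8) stop("initial distribution must sum to 1")
  dimnames(means) <- dimnames(variances) <-
    list(structure$states, structure$obs)
  dimnames(transitions) <- list(structure$states, structure$states)
  structure(list(means = means, variances = variances,
                 transitions = transitions, initial = as.numeric(initial),
                 structure = structure),
            class = "UMParameters")
}

#' Stationary distribution of a transition matrix
#' @param A row-stochastic matrix.
#' @return probability vector `p` with `p A = p`.
#' @export
stationary_distribution <- function(A) {
  K <- nrow(A)
  solve_for <- function(A) {
    M <- rbind(t(A) - diag(K), rep(1, K))
    qr.solve(M, c(rep(0, K), 1), tol = 1e-12)
  }
  p <- tryCatch(solve_for(A), error = function(e) {
    # reducible chain (can arise from sparse empirical counts): damp
    # towards the uniform kernel to select a unique distribution
    solve_for((1 - 1e-4) * A + 1e-4 / K)
  })
  p <- pmax(p, 0)
  p / sum(p)
}

# max deviation from the sigma symmetry ties: emission orbits, the flow
# symmetry pi(a) A[a,b] = pi(sigma b) A[sigma b, sigma a], stationarity of
# the initial distribution, and pi(sigma s) = pi(s)
symmetry_residual <- function(params) {
  st <- params$structure
  si <- match(st$sigma_state[st$states], st$states)
  oj <- match(st$sigma_obs[st$obs], st$obs)
  p <- params$initial
  Fl <- p * params$transitions
  max(abs(params$means - params$means[si, oj]),
      abs(params$variances - params$variances[si, oj]),
      abs(Fl - t(Fl[si, si])),
      abs(p %*% params$transitions - p),
      abs(p - p[si]))
}

#' Enforce the strand-swap symmetry ties on a parameter set
#'
#' Emission means and variances are averaged over their sigma orbits.
#' Transitions are tied so that decoding is invariant under reverse
#' complement: the state flows `pi(a) A[a,b]` are averaged with their
#' sigma mirrors `pi(sigma b) A[sigma b, sigma a]` (with `pi` the
#' stationary distribution, itself averaged over sigma orbits) and rows
#' renormalized, iterating to machine precision. Under these ties every
#' state path has exactly the probability of its reverse-complement image,
#' so posterior marginals are strand-swap symmetric. The initial
#' distribution is set to the stationary distribution. Idempotent.
#'
#' @param params a [um_parameters()] set.
#' @return a symmetric `UMParameters`.
#' @export
symmetrize <- function(params) {
  st <- params$structure
  si <- match(st$sigma_state[st$states], st$states)
  oj <- match(st$sigma_obs[st$obs], st$obs)
  means <- (params$means + params$means[si, oj]) / 2
  vars <- (params$variances + params$variances[si, oj]) / 2
  A <- params$transitions
  p0 <- stationary_distribution(A)
  p0 <- pmax(p0, 1e-12); p0 <- p0 / sum(p0)
  p <- (p0 + p0[si]) / 2                 # sigma-symmetric target occupancy
  W <- p0 * A                            # flows diag(p0) %*% A
  W <- (W + t(W[si, si])) / 2            # sigma-tied flow kernel
  # Sinkhorn balancing of the tied flows to row and column marginals p:
  # the balanced matrix diag(u) W diag(v) is unique, and applying sigma to
  # it yields another solution, so the flow tie survives balancing exactly;
  # equal row/column sums make p stationary for the resulting chain.
  Fl <- W
  for (it in seq_len(5000)) {
    r <- rowSums(Fl)
    Fl <- Fl * (p / r)
    cs <- colSums(Fl)
    Fl <- t(t(Fl) * (p / cs))
    if (max(abs(rowSums(Fl) - p), abs(cs - p)) < 1e-15) break
  }
  A <- Fl / rowSums(Fl)
  A[!st$allowed] <- 0
  A <- A / rowSums(A)
  um_parameters(means, vars, A, p, st)
}

#' Assemble the four-track observation matrices from two score tracks
#'
#' @param init_track,term_track `ScoreTrack`s from [score_genome()] for the
#'   initiation and termination classifiers.
#' @return named list (per chromosome) of `T x 4` matrices with columns
#'   [UM_OBS].
#' @export
um_observations <- function(init_track, term_track) {
  nms <- names(init_track$plus)
  stopifnot(identical(nms, names(term_track$plus)))
  out <- lapply(nms, function(nm) {
    m <- cbind(init_track$plus[[nm]], term_track$plus[[nm]],
               init_track$minus[[nm]], term_track$minus[[nm]])
    colnames(m) <- UM_OBS
    m
  })
  names(out) <- nms
  out
}

#' Estimate unified-model parameters from a labelled transcript map
#'
#' Emission means and variances are the empirical moments of each
#' observation track within each state; transitions are normalized
#' adjacent-base transition counts restricted to the allowed set
#' (disallowed transitions observed in the map are dropped with a warning).
#' Masked bases are excluded. The result is then symmetrized.
#'
#' @param state_map a [StateMap()].
#' @param observations per-chromosome observation matrices from
#'   [um_observations()].
#' @param structure a [build_structure()] result.
#' @param var_floor lower bound applied to variances.
#' @param variance_pooling fraction in `[0, 1]` by which each state's
#'   variances are shrunk toward the occupancy-weighted within-state pooled
#'   variance of its track. 0 (default) keeps the raw per-state moments;
#'   1 gives every state the same variance per track, so that emission
#'   differences act through the means alone. Pooling guards decoding
#'   against normalization artifacts of heteroscedastic Gaussians: a state
#'   whose variance is deflated relative to the others is otherwise
#'   favoured wherever the tracks are quiet, regardless of its mean.
#' @param variance_pool_floor floor each state's variances at the pooled
#'   value: low-signal states (whose narrow spreads would otherwise win
#'   quiet regions on Gaussian normalization alone) are equalized, while
#'   peak states (TSS/CPA/Term, whose score profiles are genuinely broad)
#'   keep their wide spreads and so tolerate peak shoulders.
#' @param robust use median/MAD instead of mean/variance for the emission
#'   moments. Classifier score tracks bleed beyond state boundaries (the
#'   score peaks are wider than the annotated TSS/CPA states), which
#'   contaminates the tails of each state's score distribution; robust
#'   location/scale estimates keep the contamination out of the emission
#'   model.
#' @return a symmetric `UMParameters`.
#' @export
estimate_parameters <- function(state_map, observations,
                                structure = build_structure(),
                                var_floor = 1e-6, variance_pooling = 0,
                                variance_pool_floor = FALSE,
                                robust = FALSE) {
  K <- length(structure$states); D <- length(structure$obs)
  nms <- names(state_map$states)
  stopifnot(all(nms %in% names(observations)))
  lab <- unlist(state_map$states, use.names = FALSE)
  msk <- unlist(state_map$mask, use.names = FALSE)
  obs <- do.call(rbind, observations[nms])
  stopifnot(nrow(obs) == length(lab))
  lab_u <- lab[!msk]; obs_u <- obs[!msk, , drop = FALSE]
  if (!all(seq_len(K) %in% lab_u))
    stop("state(s) never observed: ",
         paste(structure$states[setdiff(seq_len(K), unique(lab_u))],
               collapse = ", "))
  means <- vars <- matrix(0, K, D)
  occ <- numeric(K)
  for (k in seq_len(K)) {
    x <- obs_u[lab_u == k, , drop = FALSE]
    occ[k] <- nrow(x)
    if (robust) {
      means[k, ] <- apply(x, 2, stats::median)
      vars[k, ] <- pmax(apply(x, 2, stats::mad)^2, var_floor)
    } else {
      means[k, ] <- colMeans(x)
      vars[k, ] <- pmax(colMeans(x^2) - colMeans(x)^2, var_floor)
    }
  }
  if (variance_pooling > 0 || variance_pool_floor) {
    pooled <- matrix(colSums(vars * occ) / sum(occ), K, D, byrow = TRUE)
    if (variance_pooling > 0)
      vars <- (1 - variance_pooling) * vars + variance_pooling * pooled
    if (variance_pool_floor)
      vars <- pmax(vars, pooled)
  }
  counts <- matrix(0, K, K)
  for (nm in nms) {
    s <- state_map$states[[nm]]
    m <- state_map$mask[[nm]]
    ok <- !m[-length(m)] & !m[-1]
    a <- s[-length(s)][ok]; b <- s[-1][ok]
    counts <- counts + table(factor(a, seq_len(K)), factor(b, seq_len(K)))
  }
  counts <- unclass(counts)
  bad <- counts[!structure$allowed]
  if (any(bad > 0)) {
    warning(sum(bad), " observed transition(s) outside the allowed set dropped")
    counts[!structure$allowed] <- 0
  }
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows)) {                 # default unobserved rows to self-loop
    d <- diag(counts); d[zero_rows] <- 1; diag(counts) <- d
  }
  A <- counts / rowSums(counts)
  symmetrize(um_parameters(means, vars, A, structure = structure))
}

#' Posterior-marginal decoding of the unified model
#'
#' Runs scaled forward-backward with diagonal-Gaussian emissions over the
#' four score tracks; per-base state posteriors sum to 1 and underflow is
#' impossible by construction.
#'
#' @param params a symmetric `UMParameters`.
#' @param observations per-chromosome matrices from [um_observations()]
#'   (a single matrix is also accepted).
#' @return a `PosteriorTrack`: list with `posterior` (named list of `T x 8`
#'   matrices) and `loglik`.
#' @export
posterior_decode <- function(params, observations) {
  if (is.matrix(observations)) observations <- list(seq = observations)
  if (symmetry_residual(params) > 1e-6)
    warning("parameters are not symmetric; decoding will not be strand-invariant")
  post <- list(); ll <- 0
  for (nm in names(observations)) {
    o <- as.matrix(observations[[nm]])
    r <- forward_backward_gaussian(o, params$means, params$variances,
                                   params$transitions, params$initial)
    colnames(r$posterior) <- params$structure$states
    post[[nm]] <- r$posterior
    ll <- ll + r$loglik
  }
  structure(list(posterior = post, loglik = ll), class = "PosteriorTrack")
}

#' Simulate state paths and observations from unified-model parameters
#'
#' @param params a `UMParameters`.
#' @param lengths named integer vector of chromosome lengths.
#' @return list with `state_map` (a [StateMap()]) and `observations`
#'   (per-chromosome `T x 4` matrices).
#' @export
simulate_um <- function(params, lengths) {
  K <- nrow(params$means)
  states <- obs <- list()
  cum <- t(apply(params$transitions, 1, cumsum))
  for (nm in names(lengths)) {
    T_ <- lengths[[nm]]
    s <- integer(T_)
    s[1] <- sample.int(K, 1, prob = params$initial)
    u <- stats::runif(T_)
    if (T_ >= 2)
      for (t in 2:T_) s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
    o <- params$means[s, ] +
      matrix(stats::rnorm(T_ * ncol(params$means)), T_) *
        sqrt(params$variances[s, ])
    colnames(o) <- params$structure$obs
    states[[nm]] <- s
    obs[[nm]] <- o
  }
  list(state_map = StateMap(states), observations = obs)
}

#' Per-base probability of being inside a transcript
#'
#' @param posterior a `PosteriorTrack`.
#' @param strand `"any"` (1 - P(IG)), `"+"` or `"-"` (sum of that strand's
#'   states, with `Term` counted for both).
#' @return named list of per-chromosome numeric vectors.
#' @export
transcript_probability <- function(posterior, strand = c("any", "+", "-")) {
  strand <- match.arg(strand)
  cols <- switch(strand,
                 any = setdiff(UM_STATES, "IG"),
                 "+" = c("TSS+", "Gene+", "CPA+", "Term"),
                 "-" = c("TSS-", "Gene-", "CPA-", "Term"))
  lapply(posterior$posterior, function(p) rowSums(p[, cols, drop = FALSE]))
}

#' Tune the tied observation means against an expression track
#'
#' Nelder-Mead optimization of the 16 symmetry-tied emission means (variances
#' and transitions fixed) to maximize the Pearson correlation between the
#' posterior probability of being a transcript (1 - P(IG)) and per-base
#' log-expression. Returns symmetric parameters whose objective is at least
#' the starting objective.
#'
#' @param params a symmetric `UMParameters`.
#' @param observations per-chromosome matrices from [um_observations()].
#' @param expression per-chromosome numeric vectors of expression (linear
#'   scale; log1p is applied internally).
#' @param max_eval maximum objective evaluations.
#' @return list with `params` (tuned `UMParameters`), `objective` and
#'   `initial_objective` (Pearson correlations).
#' @export
tune_means <- function(params, observations, expression, max_eval = 500L) {
  ex <- log1p(unlist(expression[names(observations)], use.names = FALSE))
  if (stats::sd(ex) == 0) stop("constant expression track: correlation undefined")
  orbits <- emission_orbits(params$structure)
  pack <- vapply(orbits, function(o) params$means[o[1, 1], o[1, 2]], numeric(1))
  unpack <- function(theta) {
    m <- params$means
    for (i in seq_along(orbits))
      for (r in seq_len(nrow(orbits[[i]])))
        m[orbits[[i]][r, 1], orbits[[i]][r, 2]] <- theta[i]
    m
  }
  objective <- function(theta) {
    p <- params
    p$means <- unpack(theta)
    pt <- unlist(transcript_probability(posterior_decode(p, observations)),
                 use.names = FALSE)
    if (stats::sd(pt) == 0) return(1)   # degenerate: worst objective
    -stats::cor(pt, ex)
  }
  f0 <- objective(pack)
  opt <- stats::optim(pack, objective, method = "Nelder-Mead",
                      control = list(maxit = max_eval))
  best <- if (opt$value < f0) opt$par else pack
  out <- params
  out$means <- unpack(best)
  list(params = out, objective = -min(opt$value, f0),
       initial_objective = -f0)
}

# peaks of runs >= thr that are at least min_width long
posterior_peaks_wide <- function(signal, thr, min_width) {
  above <- signal >= thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values & r$lengths >= min_width)
  vapply(k, function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(signal[idx])]
  }, integer(1))
}

# 1-based positions of local maxima of `signal` within maximal runs >= thr
posterior_peaks <- function(signal, thr) {
  above <- signal >= thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vapply(which(r$values), function(i) {
    idx <- starts[i]:ends[i]
    idx[which.max(signal[idx])]
  }, integer(1))
}

#' Call transcripts from posterior marginals
#'
#' Transcripts are parsed from the posterior's anchor states. Along each
#' chromosome, confidently decoded TSS peaks of a strand and
#' cleavage/terminator peaks (`CPA+ + CPA- + Term`; terminator location is
#' strand-ambiguous because cleavage signals act bidirectionally, so the
#' transcript's own context assigns it) alternate in transcription order:
#' scanning 5' to 3' along the strand, a TSS peak opens a transcript and
#' the next terminator peak closes it. A closed pair is accepted if the
#' strand-transcript posterior supports the span: its rolling
#' `support_window`-mean must stay at or above `threshold` throughout
#' (brief interior dips pass, intergenic stretches fail; the terminal
#' 300 bp on the terminator side are not judged since the bidirectional
#' terminator complex may have been absorbed by either strand's CPA
#' state).
#'
#' @param posterior a `PosteriorTrack`.
#' @param threshold minimum rolling-mean strand-transcript posterior
#'   across the span, in (0, 1).
#' @param anchor_threshold minimum posterior for TSS/terminator anchor
#'   peaks.
#' @param min_length minimum transcript span (bp).
#' @param min_peak_width minimum width (bp) of an anchor peak's run above
#'   `anchor_threshold`.
#' @param support_window width (bp) of the rolling support window.
#' @return a [transcript_annotations()] table (single-base TSS/CPA regions).
#' @export
predict_transcripts <- function(posterior, threshold = 0.45,
                                anchor_threshold = 0.5, min_length = 300L,
                                min_peak_width = 20L,
                                support_window = 700L) {
  stopifnot(threshold > 0, threshold < 1)
  rows <- list()
  for (nm in names(posterior$posterior)) {
    p <- posterior$posterior[[nm]]
    cpa_sig <- p[, "CPA+"] + p[, "CPA-"] + p[, "Term"]
    cpa_peaks <- posterior_peaks_wide(cpa_sig, anchor_threshold,
                                      min_peak_width)
    for (st in c("+", "-")) {
      if (st == "+") {
        ptx <- rowSums(p[, c("TSS+", "Gene+", "CPA+", "Term")])
        ptss <- p[, "TSS+"]
      } else {
        ptx <- rowSums(p[, c("TSS-", "Gene-", "CPA-", "Term")])
        ptss <- p[, "TSS-"]
      }
      tss_peaks <- posterior_peaks_wide(ptss, anchor_threshold,
                                        min_peak_width)
      if (!length(tss_peaks) || !length(cpa_peaks)) next
      w <- support_window
      n <- length(ptx)
      cs <- cumsum(c(0, ptx))
      rm_ <- if (n >= w) (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
             else mean(ptx)
      span_ok <- function(a, b) {
        if (b < a) return(TRUE)
        if (b - a + 1L < w) return(mean(ptx[a:b]) >= threshold)
        min(rm_[a:(b - w + 1L)]) >= threshold
      }
      # scan anchor events in transcription order: a TSS opens a
      # transcript and the farthest posterior-supported terminator closes
      # it. Supported terminator candidates are held rather than committed
      # (a nearer candidate may be a spurious blip inside the body);
      # commitment happens when support breaks — at an unsupported
      # terminator, at a TSS whose span from the open TSS is unsupported,
      # or at the end of the chromosome. Unsupported terminator blips with
      # no candidate yet are skipped with the transcript kept open.
      ev <- rbind(cbind(tss_peaks, 1L), cbind(cpa_peaks, 2L))
      ev <- ev[order(ev[, 1], decreasing = (st == "-")), , drop = FALSE]
      # local terminator posterior mass around a candidate: a genuine
      # terminator complex sustains near-1 posterior over hundreds of
      # bases, a spurious blip does not
      cpa_mass <- function(pk)
        sum(cpa_sig[max(1L, pk - 200L):min(length(cpa_sig), pk + 200L)])
      open_t <- NA_integer_
      cand_c <- integer(0)
      emit <- function(t) {
        cp <- cand_c[which.max(vapply(cand_c, cpa_mass, numeric(1)))]
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = nm, strand = st,
          start = min(t, cp) - 1L, end = max(t, cp),
          tss_pos = t - 1L, cpa_pos = cp - 1L)
      }
      for (i in seq_len(nrow(ev))) {
        pos <- ev[i, 1]
        if (ev[i, 2] == 1L) {
          if (is.na(open_t)) open_t <- pos
          else {
            alive <- if (st == "+") span_ok(open_t, pos)
                     else span_ok(pos, open_t)
            if (!alive) {
              if (length(cand_c)) emit(open_t)
              open_t <- pos
              cand_c <- integer(0)
            }
          }
        } else if (!is.na(open_t)) {
          if (abs(pos - open_t) < min_length) next
          ok <- if (st == "+") span_ok(open_t, max(open_t, pos - 300L))
                else span_ok(min(open_t, pos + 300L), open_t)
          if (ok) cand_c <- c(cand_c, pos)
          else if (length(cand_c)) {
            emit(open_t)
            open_t <- NA_integer_
            cand_c <- integer(0)
          }
        }
      }
      if (!is.na(open_t) && length(cand_c)) emit(open_t)
    }
  }
  if (!length(rows))
    return(transcript_annotations(
      data.frame(id = character(), chrom = character(), strand = character(),
                 start = integer(), end = integer(),
                 tss_pos = integer(), cpa_pos = integer())))
  df <- do.call(rbind, rows)
  df$id <- sprintf("txp%04d", seq_len(nrow(df)))
  df$tss_start <- df$tss_pos; df$tss_end <- df$tss_pos + 1L
  df$cpa_start <- df$cpa_pos; df$cpa_end <- df$cpa_pos + 1L
  transcript_annotations(df)
}

#' Expected dwell time of each state
#'
#' `1 / (1 - self-transition)`: the number of bases the model expects to
#' remain in each state.
#'
#' @param params a `UMParameters`.
#' @return named numeric vector of expected dwell times (bases).
#' @export
expected_dwell <- function(params) {
  d <- 1 / (1 - diag(params$transitions))
  stats::setNames(d, params$structure$states)
}

#' Write unified-model parameters as a structured text file
#' @param params a `UMParameters`.
#' @param path output path.
#' @export
write_um_parameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# txunify unified-model parameters v1", con)
  wr <- function(tag, m) {
    writeLines(paste0("[", tag, "]"), con)
    writeLines(paste(c("state", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 17)),
                       collapse = "\t"), con)
  }
  wr("means", params$means)
  wr("variances", params$variances)
  wr("transitions", params$transitions)
  writeLines("[initial]", con)
  writeLines(paste(format(params$initial, digits = 17), collapse = "\t"), con)
  invisible(path)
}

#' Read unified-model parameters from the structured text format
#' @param path file written by [write_um_parameters()].
#' @param structure a [build_structure()] result.
#' @return a `UMParameters`.
#' @export
read_um_parameters <- function(path, structure = build_structure()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  sect <- function(tag, n) {
    i <- match(paste0("[", tag, "]"), lines)
    if (is.na(i)) stop("missing section [", tag, "]")
    rows <- lines[(i + 2L):(i + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(rows, "\t"),
                               function(x) as.numeric(x[-1])))
    rownames(m) <- vapply(strsplit(rows, "\t"), `[`, character(1), 1)
    m
  }
  K <- length(structure$states)
  means <- sect("means", K)
  vars <- sect("variances", K)
  trans <- sect("transitions", K)
  i <- match("[initial]", lines)
  init <- as.numeric(strsplit(lines[i + 1L], "\t")[[1]])
  um_parameters(means[structure$states, ], vars[structure$states, ],
                trans[structure$states, ], init, structure)
}
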