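random_dna <- function(n, composition) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition), collapse = "")
}

splice_in <- function(seq, at0, insert) {
  # overwrite (not insert) `insert` starting at 0-based position at0
  substr(seq, at0 + 1L, at0 + nchar(insert)) <- insert
  seq
}

#' Specification of a synthetic genome with implanted gene grammars
#'
#' The background is i.i.d. sequence at the yeast-like composition
#' (A = T = 0.31, C = G = 0.19, i.e. 38% G/C). Each implanted gene carries
#' the promoter grammar (one general-regulatory-factor site in the
#' `[-150,-80)` window, a poly(dA:dT) tract, an optional TATA box in
#' `[-80,-50)`, and a CA initiator at the TSS) and the terminator grammar
#' (2-4 TATATA Hrp1 sites within 60 bp upstream of the CPA inside an
#' AT-rich 150-bp window, with a [G/C]AA cleavage site).
#'
#' @param n_genes number of genes to implant.
#' @param n_chrom number of chromosomes (genes split evenly).
#' @param composition background base probabilities (A, C, G, T).
#' @param gene_length_range transcript length range (TSS to CPA, bp).
#' @param gap_range extra intergenic background between gene cassettes (bp).
#' @param grf_names motif names treated as GRF sites for promoters.
#' @param tata_prob probability a promoter carries a TATA box.
#' @param polyA_range poly(dA:dT) tract length range.
#' @param body_at_skew excess of A over T frequency on the coding strand of
#'   transcribed bodies (G/C content unchanged); transcribed yeast sequence
#'   is A-rich on the coding strand, and the A:T ratio of the first
#'   transcribed bases is one of the model's discriminative features.
#' @param tss_at_skew stronger A-over-T excess applied to the first 100
#'   transcribed bases.
#' @param tatata_range number of TATATA terminator sites per gene.
#' @param terminator_at AT-richness of the terminator window.
#' @param convergent_prob probability that the next unit is a convergent
#'   gene pair sharing a bidirectional terminator (their CPA regions
#'   overlap, producing `Term` states).
#' @param convergent_tail_range range of the half-gap between the two CPA
#'   sites of a convergent pair (bp; CPA separation is `2 * tail + 1`).
#' @param seed RNG seed.
#' @return a `SyntheticGenomeSpec` list.
#' @export
synthetic_genome_spec <- function(n_genes = 200L, n_chrom = 4L,
                                  composition = c(0.31, 0.19, 0.19, 0.31),
                                  gene_length_range = c(500L, 1500L),
                                  gap_range = c(800L, 1400L),
                                  grf_names = c("Reb1", "Abf1", "Rap1"),
                                  tata_prob = 0.5,
                                  polyA_range = c(10L, 20L),
                                  body_at_skew = 0.16,
                                  tss_at_skew = 0.24,
                                  tatata_range = c(2L, 4L),
                                  terminator_at = 0.8,
                                  convergent_prob = 0.35,
                                  convergent_tail_range = c(2L, 15L),
                                  seed = 1L) {
  composition <- as.numeric(composition)
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  structure(list(n_genes = n_genes, n_chrom = n_chrom,
                 composition = composition,
                 gene_length_range = gene_length_range,
                 gap_range = gap_range, grf_names = grf_names,
                 tata_prob = tata_prob, polyA_range = polyA_range,
                 body_at_skew = body_at_skew, tss_at_skew = tss_at_skew,
                 tatata_range = tatata_range, terminator_at = terminator_at,
                 convergent_prob = convergent_prob,
                 convergent_tail_range = convergent_tail_range,
                 seed = seed),
            class = "SyntheticGenomeSpec")
}

# one oriented gene cassette: 150 bp promoter + gene + tail.
# Returns the cassette string plus 0-based cassette coordinates of TSS/CPA
# and the implant inventory (offsets relative to the TSS).
make_gene_cassette <- function(spec, motifs, gene_len, tail = 50L) {
  prom <- 150L
  L <- prom + gene_len + tail
  skew_comp <- function(s) spec$composition + c(s / 2, 0, 0, -s / 2)
  n_first <- min(100L, gene_len)
  seq <- paste0(random_dna(prom, spec$composition),
                random_dna(n_first, skew_comp(spec$tss_at_skew)),
                random_dna(gene_len - n_first, skew_comp(spec$body_at_skew)),
                random_dna(tail, spec$composition))
  tss <- prom                      # cassette coordinate of the TSS base
  cpa <- prom + gene_len - 1L
  implants <- list()
  put <- function(seq, off, s, what) {   # off relative to TSS
    at <- tss + off
    implants[[length(implants) + 1L]] <<- data.frame(what = what, offset = off,
                                                     width = nchar(s))
    splice_in(seq, at, s)
  }
  grf <- sample(spec$grf_names, 1)
  s <- sample_site(motifs[[grf]])
  seq <- put(seq, sample(seq(-150L, -80L - nchar(s)), 1), s, grf)
  if (stats::runif(1) < spec$tata_prob) {
    s <- sample_site(motifs[["TATA"]])
    seq <- put(seq, sample(seq(-80L, -50L - nchar(s)), 1), s, "TATA")
  }
  plen <- sample(spec$polyA_range[1]:spec$polyA_range[2], 1)
  pbase <- sample(c("A", "T"), 1)
  seq <- put(seq, sample(seq(-45L, -15L - plen), 1),
             strrep(pbase, plen), paste0("poly", pbase))
  seq <- put(seq, -1L, "CA", "initiator")
  # terminator: AT-rich 150-bp window around the CPA site
  at <- spec$terminator_at
  win_off <- -100L
  win <- random_dna(150L, c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
  seq <- splice_in(seq, cpa + win_off, win)
  n_sites <- sample(spec$tatata_range[1]:spec$tatata_range[2], 1)
  starts <- integer(0)
  for (tries in seq_len(200)) {
    cand <- sample(seq(-60L, -7L), 1)
    if (all(abs(cand - starts) >= 6L)) starts <- c(starts, cand)
    if (length(starts) == n_sites) break
  }
  co <- cpa - tss                  # CPA offset relative to TSS
  for (st in starts)
    seq <- put(seq, co + st, "TATATA", "Hrp1")
  seq <- put(seq, co - 1L, paste0(sample(c("G", "C"), 1), "AA"), "cleavage")
  list(seq = seq, tss = tss, cpa = cpa,
       implants = do.call(rbind, implants))
}

#' Generate a random genome with implanted transcripts and ground truth
#'
#' @param spec a [synthetic_genome_spec()].
#' @param motifs motif library (default [default_motif_library()]).
#' @return list with `genome` (a [Genome()]), `annotations`
#'   (ground-truth [transcript_annotations()]), `state_map` (a
#'   [StateMap()]), and `implants` (per-gene element inventory).
#' @export
generate_random_genome <- function(spec, motifs = default_motif_library()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pad <- 600L                       # chromosome-end padding for windows
  per_chrom <- diff(c(0L, round(seq_len(spec$n_chrom) / spec$n_chrom *
                                  spec$n_genes)))
  seqs <- list(); ann <- list(); inv <- list()
  g <- 0L
  for (ci in seq_len(spec$n_chrom)) {
    nm <- sprintf("chr%02d", ci)
    parts <- list(random_dna(pad, spec$composition))
    cursor <- pad
    remaining <- per_chrom[ci]
    add_gene <- function(tss_pos, cpa_pos, strand, implants) {
      g <<- g + 1L
      id <- sprintf("gene%04d", g)
      ann[[g]] <<- data.frame(id = id, chrom = nm, strand = strand,
                              start = min(tss_pos, cpa_pos),
                              end = max(tss_pos, cpa_pos) + 1L,
                              tss_pos = tss_pos, cpa_pos = cpa_pos)
      inv[[g]] <<- cbind(id = id, chrom = nm, strand = strand, implants)
    }
    while (remaining > 0L) {
      gap <- sample(spec$gap_range[1]:spec$gap_range[2], 1)
      parts[[length(parts) + 1L]] <- random_dna(gap, spec$composition)
      cursor <- cursor + gap
      glen <- function() sample(spec$gene_length_range[1]:
                                  spec$gene_length_range[2], 1)
      pair <- remaining >= 2L && stats::runif(1) < spec$convergent_prob
      if (!pair) {
        cas <- make_gene_cassette(spec, motifs, glen())
        strand <- sample(c("+", "-"), 1)
        Lc <- nchar(cas$seq)
        if (strand == "+") {
          add_gene(cursor + cas$tss, cursor + cas$cpa, "+", cas$implants)
          parts[[length(parts) + 1L]] <- cas$seq
        } else {
          add_gene(cursor + (Lc - 1L - cas$tss), cursor + (Lc - 1L - cas$cpa),
                   "-", cas$implants)
          parts[[length(parts) + 1L]] <- reverse_complement(cas$seq)
        }
        cursor <- cursor + Lc
        remaining <- remaining - 1L
      } else {
        # convergent pair sharing a bidirectional terminator: cassette1 (+)
        # followed by the reverse complement of cassette2, with short tails
        # so the CPA regions overlap (separation 2 * tail + 1 < 36)
        tl <- sample(spec$convergent_tail_range[1]:
                       spec$convergent_tail_range[2], 1)
        cas1 <- make_gene_cassette(spec, motifs, glen(), tail = tl)
        cas2 <- make_gene_cassette(spec, motifs, glen(), tail = tl)
        add_gene(cursor + cas1$tss, cursor + cas1$cpa, "+", cas1$implants)
        off2 <- cursor + nchar(cas1$seq)
        Lc2 <- nchar(cas2$seq)
        add_gene(off2 + (Lc2 - 1L - cas2$tss), off2 + (Lc2 - 1L - cas2$cpa),
                 "-", cas2$implants)
        parts[[length(parts) + 1L]] <- cas1$seq
        parts[[length(parts) + 1L]] <- reverse_complement(cas2$seq)
        cursor <- off2 + Lc2
        remaining <- remaining - 2L
      }
    }
    parts[[length(parts) + 1L]] <- random_dna(pad, spec$composition)
    seqs[[nm]] <- paste(unlist(parts), collapse = "")
  }
  genome <- Genome(seqs)
  annotations <- transcript_annotations(do.call(rbind, ann), genome)
  list(genome = genome, annotations = annotations,
       state_map = build_state_map(annotations, genome),
       implants = do.call(rbind, inv))
}

#' Simulate a per-base expression track from transcript annotations
#'
#' Each transcript draws a log-normal abundance; a base's expression is the
#' sum of the abundances of transcripts covering it, with per-base
#' multiplicative log-normal noise; zero elsewhere.
#'
#' @param annotations a [transcript_annotations()] table.
#' @param lengths named chromosome lengths (e.g. [seq_lengths()]).
#' @param meanlog,sdlog abundance model (log-normal).
#' @param noise_sd standard deviation of per-base log-noise (0 = none).
#' @return named list of per-chromosome numeric vectors.
#' @export
simulate_expression <- function(annotations, lengths, meanlog = 2,
                                sdlog = 1, noise_sd = 0.2) {
  ab <- stats::rlnorm(nrow(annotations), meanlog, sdlog)
  out <- lapply(lengths, function(L) numeric(L))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    idx <- (a$start + 1L):a$end
    out[[a$chrom]][idx] <- out[[a$chrom]][idx] + ab[i]
  }
  if (noise_sd > 0)
    out <- lapply(out, function(v) {
      nz <- v > 0
      v[nz] <- v[nz] * exp(stats::rnorm(sum(nz), 0, noise_sd))
      v
    })
  out
}

#' Write an expression (or any per-base) track as bedGraph
#' @param track named list of per-chromosome numeric vectors.
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  grl <- lapply(names(track), function(nm) {
    r <- rle(track[[nm]])
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(nm, IRanges::IRanges(ends - r$lengths + 1L, ends),
                           score = r$values)
  })
  rtracklayer::export(do.call(c, grl), path, format = "bedGraph")
  invisible(path)
}

# disrupt a sampled site: set the motif's most informative positions to the
# base that motif position likes least
disrupt_site <- function(site, motif, n_positions = 3L) {
  info <- apply(motif$pfm, 1, function(p) {
    p <- p[p > 0]; log2(4) + sum(p * log2(p))
  })
  pos <- order(info, decreasing = TRUE)[seq_len(min(n_positions, nrow(motif$pfm)))]
  s <- strsplit(site, "")[[1]]
  for (i in pos) s[i] <- DNA_BASES[which.min(motif$pfm[i, ])]
  paste(s, collapse = "")
}

#' Design a combinatorial promoter library
#'
#' Candidate segments for the three promoter sections (`-150:-80`,
#' `-80:TSS`, `TSS:+80`) are generated as random sequences of varying G/C
#' content, optionally with a sampled TFBS embedded; every cross-section
#' combination is scored by the initiation classifier in a neutral flank
#' context, and the segments with the highest mean score across
#' combinations are retained. Each TFBS-bearing segment gets a paired
#' control identical except that the site is disrupted at its most
#' informative bases.
#'
#' @param classifier a trained initiation classifier (`TrainedEnsemble`).
#' @param scheme,specs the classifier's bin scheme and feature specs.
#' @param motifs motif library.
#' @param n_candidates candidates generated per section.
#' @param keep number of segments retained per section.
#' @param section_motifs motif names eligible per section (list of 3).
#' @param tfbs_prob probability a candidate carries a TFBS.
#' @param gc_range G/C content range for candidate backgrounds.
#' @param score_floor minimum acceptable best combination score.
#' @return a `LibraryDesign`: list with `sections` (per-section data.frames
#'   of `sequence`, `tfbs`, `tfbs_pos`, `control`), `n_combinations`, and
#'   `mean_scores`.
#' @export
design_promoter_library <- function(classifier, scheme, specs, motifs,
                                    n_candidates = c(6L, 6L, 6L),
                                    keep = c(3L, 3L, 3L),
                                    section_motifs = list(
                                      c("Reb1", "Abf1", "Rap1", "Rsc3"),
                                      "TATA", character(0)),
                                    tfbs_prob = 0.7,
                                    gc_range = c(0.2, 0.6),
                                    score_floor = 0) {
  sec_len <- c(70L, 80L, 80L)          # -150:-80, -80:TSS, TSS:+80
  sections <- lapply(1:3, function(si) {
    cand <- lapply(seq_len(n_candidates[si]), function(i) {
      gc <- stats::runif(1, gc_range[1], gc_range[2])
      s <- random_dna(sec_len[si], c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      tf <- NA_character_; tp <- NA_integer_; ctrl <- NA_character_
      if (length(section_motifs[[si]]) && stats::runif(1) < tfbs_prob) {
        tf <- sample(section_motifs[[si]], 1)
        site <- sample_site(motifs[[tf]])
        tp <- sample(0:(sec_len[si] - nchar(site)), 1)
        s <- splice_in(s, tp, site)
        ctrl <- splice_in(s, tp, disrupt_site(site, motifs[[tf]]))
      }
      data.frame(sequence = s, tfbs = tf, tfbs_pos = tp, control = ctrl,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, cand)
  })
  # neutral flanks with uniform composition, no promoter grammar
  up <- random_dna(350L, rep(0.25, 4))
  down <- random_dna(20L, rep(0.25, 4))
  combos <- expand.grid(i1 = seq_len(nrow(sections[[1]])),
                        i2 = seq_len(nrow(sections[[2]])),
                        i3 = seq_len(nrow(sections[[3]])))
  seqs <- vapply(seq_len(nrow(combos)), function(r) {
    paste0(up, sections[[1]]$sequence[combos$i1[r]],
           sections[[2]]$sequence[combos$i2[r]],
           sections[[3]]$sequence[combos$i3[r]], down)
  }, character(1))
  g <- Genome(stats::setNames(as.list(seqs), sprintf("c%05d", seq_along(seqs))))
  anchors <- data.frame(chrom = names(g), pos = 350L + 70L + 80L, strand = "+")
  fx <- extract_feature_matrix(g, anchors, scheme, specs, motifs)
  sc <- predict(classifier, fx)
  if (max(sc) < score_floor) stop("no combination reaches the score floor")
  mean_scores <- lapply(1:3, function(si) {
    idx <- combos[[paste0("i", si)]]
    vapply(seq_len(nrow(sections[[si]])), function(i) mean(sc[idx == i]),
           numeric(1))
  })
  kept <- lapply(1:3, function(si) {
    ord <- order(mean_scores[[si]], decreasing = TRUE)[seq_len(keep[si])]
    cbind(sections[[si]][ord, , drop = FALSE],
          mean_score = mean_scores[[si]][ord])
  })
  structure(list(sections = kept,
                 n_combinations = prod(vapply(kept, nrow, numeric(1))),
                 n_scored = nrow(combos), scores = sc),
            class = "LibraryDesign")
}

#' Estimate per-construct expression from sort-seq bin counts
#'
#' Expression is the count-weighted mean of the bins' average fluorescence:
#' `sum_b (count_b / total) * meanFluor_b`; invariant to rescaling all of a
#' construct's counts.
#'
#' @param counts matrix of read counts, constructs x bins.
#' @param bin_fluorescence per-bin mean fluorescence.
#' @return numeric vector of expression estimates, one per construct.
#' @export
estimate_sortseq_expression <- function(counts, bin_fluorescence) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(bin_fluorescence))
    stop("one fluorescence value per bin required")
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("construct(s) with zero total reads")
  as.numeric((counts %*% bin_fluorescence) / tot)
}

#' Simulate sort-seq bin counts for constructs of known expression
#'
#' Reads are distributed over six log-spaced fluorescence bins with a
#' Gaussian kernel on log-fluorescence around each construct's true level.
#'
#' @param expression true expression per construct (linear scale).
#' @param n_reads reads per construct.
#' @param bin_fluorescence per-bin mean fluorescence (default six log-spaced
#'   bins spanning the expression range).
#' @param spread kernel SD on the log-fluorescence scale.
#' @return list with `counts` (constructs x bins) and `bin_fluorescence`.
#' @export
simulate_sortseq_counts <- function(expression, n_reads = 100L,
                                    bin_fluorescence = NULL, spread = 0.5) {
  if (is.null(bin_fluorescence))
    bin_fluorescence <- exp(seq(log(max(min(expression), 1e-3)),
                                log(max(expression)), length.out = 6))
  counts <- t(vapply(expression, function(e) {
    w <- stats::dnorm(log(bin_fluorescence), log(e), spread)
    if (sum(w) == 0) w <- rep(1, length(bin_fluorescence))
    as.numeric(stats::rmultinom(1, n_reads, w))
  }, numeric(length(bin_fluorescence))))
  list(counts = counts, bin_fluorescence = bin_fluorescence)
}

#' Design a pseudo-random DNA fragment with inserted consensus sites
#'
#' Background sequence at the target G/C content with the requested numbers
#' of consensus binding sites inserted at uniform random non-overlapping
#' positions on random strands.
#'
#' @param length fragment length (bp).
#' @param gc_target G/C content of the background.
#' @param site_counts named integer vector: motif name -> number of
#'   consensus insertions.
#' @param motifs motif library supplying the consensi.
#' @param max_tries rejection-sampling budget for non-overlapping placement.
#' @return list with `sequence` and `inventory` (data.frame of `what`,
#'   `start`, `width`, `strand`).
#' @export
design_random_fragment <- function(length = 3000L, gc_target = 0.38,
                                   site_counts = integer(0),
                                   motifs = default_motif_library(),
                                   max_tries = 1000L) {
  comp <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  seq <- random_dna(length, comp)
  inv <- list()
  placed <- matrix(numeric(0), ncol = 2)
  for (nm in names(site_counts)) {
    if (site_counts[[nm]] < 1) next
    if (is.null(motifs[[nm]])) stop("unknown motif: ", nm)
    cons <- paste(DNA_BASES[apply(motifs[[nm]]$pfm, 1, which.max)],
                  collapse = "")
    w <- nchar(cons)
    for (k in seq_len(site_counts[[nm]])) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        at <- sample(0:(length - w), 1)
        if (!nrow(placed) ||
            all(at + w <= placed[, 1] | at >= placed[, 2])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place all sites without overlap")
      strand <- sample(c("+", "-"), 1)
      s <- if (strand == "+") cons else reverse_complement(cons)
      seq <- splice_in(seq, at, s)
      placed <- rbind(placed, c(at, at + w))
      inv[[length(inv) + 1L]] <- data.frame(what = nm, start = at, width = w,
                                            strand = strand)
    }
  }
  list(sequence = seq,
       inventory = if (length(inv)) do.call(rbind, inv)
                   else data.frame(what = character(), start = integer(),
                                   width = integer(), strand = character()))
}
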