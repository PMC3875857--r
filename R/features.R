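#' Define a binning scheme around an anchor base
#'
#' Offsets are signed base positions relative to the anchor, read 5' to 3'
#' along the putative transcript (negative = upstream). Interior boundaries
#' split `[window_start, window_end)` into contiguous bins.
#'
#' @param window_start,window_end signed offsets of the window.
#' @param boundaries strictly increasing interior cut points.
#' @return a `BinScheme`: list with `window_start`, `window_end` and a
#'   `bins` matrix of per-bin `[start, end)` offsets.
#' @export
bin_scheme <- function(window_start, window_end, boundaries = NULL) {
  boundaries <- as.integer(boundaries)
  if (window_start >= window_end) stop("window_start must be < window_end")
  if (length(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE)) stop("boundaries must be strictly increasing")
    if (min(boundaries) <= window_start || max(boundaries) >= window_end)
      stop("boundaries must lie strictly inside the window")
  }
  cuts <- c(window_start, boundaries, window_end)
  bins <- cbind(start = cuts[-length(cuts)], end = cuts[-1])
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end), bins = bins),
            class = "BinScheme")
}

#' Default initiation binning: six bins over 600 bp around the TSS
#'
#' Window `[-500, +100)` relative to the TSS, cut at -300, -150, -80, -50
#' and 0: the `[-150,-80)` bin hosts the general regulatory factor sites,
#' `[-80,-50)` the TATA box, and `[0,+100)` the first transcribed bases.
#'
#' @return a [bin_scheme()] with six bins.
#' @export
default_initiation_scheme <- function() {
  bin_scheme(-500L, 100L, c(-300L, -150L, -80L, -50L, 0L))
}

#' Default termination binning: three 50-base bins over 150 bp around the CPA
#' @return a [bin_scheme()] with bins `[-75,-25)`, `[-25,+25)`, `[+25,+75)`.
#' @export
default_termination_scheme <- function() {
  bin_scheme(-75L, 75L, c(-25L, 25L))
}

FEATURE_KINDS <- c("motif_max_score", "base_fraction", "at_ratio",
                   "polyA_tract", "polyT_tract", "dinucleotide_property_mean")

#' Define one binned feature
#'
#' @param kind one of `motif_max_score`, `base_fraction`, `at_ratio`,
#'   `polyA_tract`, `polyT_tract`, `dinucleotide_property_mean`.
#' @param bin 1-based bin index into the scheme.
#' @param param kind-specific parameter: motif name, base set (e.g. `"GC"`),
#'   or dinucleotide property name.
#' @return one-row data.frame with columns `name`, `kind`, `bin`, `param`.
#' @export
feature_spec <- function(kind, bin, param = "") {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (kind == "motif_max_score" && !nzchar(param)) stop("motif name required")
  if (kind == "base_fraction" && !nzchar(param)) stop("base set required")
  if (kind == "dinucleotide_property_mean" && !nzchar(param)) stop("property name required")
  name <- if (nzchar(param)) sprintf("bin%d.%s.%s", bin, kind, param)
          else sprintf("bin%d.%s", bin, kind)
  data.frame(name = name, kind = kind, bin = as.integer(bin), param = param,
             stringsAsFactors = FALSE)
}

#' Default feature vocabulary for the initiation classifier
#'
#' Per bin: max log-odds score of each promoter-defining motif (GRFs Reb1,
#' Abf1, Rap1, plus Rsc3 and the TATA box), G/C fraction, and the longest
#' poly(dA)/poly(dT) run; the A:T ratio is computed only in the transcribed
#' `[0,+100)` bin, where it is informative.
#'
#' @param motif_names motif names to score per bin.
#' @param n_bins number of bins in the scheme.
#' @param at_ratio_bin bin index for the A:T ratio feature (NA for none).
#' @return data.frame of feature specs.
#' @export
default_initiation_specs <- function(motif_names = c("Reb1", "Abf1", "Rap1",
                                                     "Rsc3", "TATA"),
                                     n_bins = 6L, at_ratio_bin = 6L) {
  specs <- list()
  for (b in seq_len(n_bins)) {
    for (m in motif_names)
      specs[[length(specs) + 1L]] <- feature_spec("motif_max_score", b, m)
    specs[[length(specs) + 1L]] <- feature_spec("base_fraction", b, "GC")
    specs[[length(specs) + 1L]] <- feature_spec("polyA_tract", b)
    specs[[length(specs) + 1L]] <- feature_spec("polyT_tract", b)
  }
  if (!is.na(at_ratio_bin))
    specs[[length(specs) + 1L]] <- feature_spec("at_ratio", at_ratio_bin)
  do.call(rbind, specs)
}

#' Default feature vocabulary for the termination classifier
#'
#' G/C content and Hrp1 efficiency-element scores per bin — the two feature
#' types that dominate cleavage/polyadenylation prediction — plus poly(dA)/
#' poly(dT) runs.
#'
#' @param motif_names motif names to score per bin (default Hrp1).
#' @param n_bins number of bins in the scheme.
#' @return data.frame of feature specs.
#' @export
default_termination_specs <- function(motif_names = "Hrp1", n_bins = 3L) {
  specs <- list()
  for (b in seq_len(n_bins)) {
    for (m in motif_names)
      specs[[length(specs) + 1L]] <- feature_spec("motif_max_score", b, m)
    specs[[length(specs) + 1L]] <- feature_spec("base_fraction", b, "GC")
    specs[[length(specs) + 1L]] <- feature_spec("polyA_tract", b)
    specs[[length(specs) + 1L]] <- feature_spec("polyT_tract", b)
  }
  do.call(rbind, specs)
}

#' Bundled dinucleotide structural property scales
#' @return data.frame with dinucleotide rows and one column per property.
#' @export
dinucleotide_properties <- function() {
  path <- system.file("extdata", "dinuc_properties.tsv", package = "txunify")
  utils::read.table(path, header = TRUE, sep = "\t", row.names = 1)
}

# ---- per-chromosome cached arrays -----------------------------------------

# All arrays are computed on the oriented sequence (reverse complement for
# minus-strand anchor groups), so offsets read 5'->3' of the transcript.
chrom_feature_cache <- function(seq, specs, motifs) {
  b <- encode_dna(seq)
  L <- length(b)
  cache <- list(L = L)
  base_sets <- unique(specs$param[specs$kind == "base_fraction"])
  need_at <- any(specs$kind == "at_ratio")
  need_bases <- unique(c(unlist(strsplit(base_sets, "")),
                         if (need_at) c("A", "T")))
  cache$prefix <- lapply(stats::setNames(nm = need_bases), function(bs) {
    cumsum(c(0L, as.integer(!is.na(b) & b == match(bs, DNA_BASES))))
  })
  run_starting <- function(code) {
    # r[i] = number of consecutive bases == code starting at i
    ind <- !is.na(b) & b == code
    r <- integer(L)
    rl <- rle(ind)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    k <- which(rl$values)
    if (length(k)) {
      lens <- rl$lengths[k]
      r[sequence(lens, from = starts[k])] <- sequence(lens, from = lens, by = -1L)
    }
    r
  }
  if (any(specs$kind == "polyA_tract")) cache$runA <- run_starting(1L)
  if (any(specs$kind == "polyT_tract")) cache$runT <- run_starting(4L)
  motif_names <- unique(specs$param[specs$kind == "motif_max_score"])
  cache$motif <- list()
  for (m in motif_names) {
    if (is.null(motifs[[m]])) stop("unknown motif: ", m)
    pwm <- pfm_to_pwm(motifs[[m]])
    worst <- sum(apply(pwm, 1, min))
    s <- if (L >= nrow(pwm)) score_positions(seq, pwm) else numeric(0)
    cache$motif[[m]] <- c(s, rep(worst, L - length(s)))  # pad tail
  }
  props <- unique(specs$param[specs$kind == "dinucleotide_property_mean"])
  if (length(props)) {
    tab <- dinucleotide_properties()
    dn <- paste0(DNA_BASES[b[-L]], DNA_BASES[b[-1]])
    for (p in props) {
      if (!p %in% colnames(tab)) stop("unknown dinucleotide property: ", p)
      v <- tab[dn, p]
      v[is.na(v)] <- mean(tab[[p]])
      cache[[paste0("dinuc_", p)]] <- cumsum(c(0, v))
      cache[[paste0("dinucn_", p)]] <- cumsum(c(0L, as.integer(!is.na(v))))
    }
  }
  cache
}

# windowed maximum of x over [starts_i, starts_i + width) via offset pmax
window_max <- function(x, starts, width, floor_val = -Inf) {
  out <- rep(floor_val, length(starts))
  L <- length(x)
  for (o in 0:(width - 1L)) {
    idx <- starts + o
    v <- ifelse(idx >= 1L & idx <= L, x[pmin(pmax(idx, 1L), L)], floor_val)
    out <- pmax(out, v)
  }
  out
}

# longest homopolymer run within [starts_i, starts_i + width), from
# run-length-starting array r
window_longest_run <- function(r, starts, width) {
  out <- numeric(length(starts))
  L <- length(r)
  for (o in 0:(width - 1L)) {
    idx <- starts + o
    v <- ifelse(idx >= 1L & idx <= L, r[pmin(pmax(idx, 1L), L)], 0L)
    out <- pmax(out, pmin(v, width - o))
  }
  out
}

# feature matrix for anchors all on one oriented sequence; pos0 are 0-based
# anchor positions on that sequence
features_for_oriented <- function(cache, pos0, scheme, specs) {
  n <- length(pos0)
  vals <- matrix(NA_real_, n, nrow(specs), dimnames = list(NULL, specs$name))
  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    bs <- scheme$bins[sp$bin, "start"]; be <- scheme$bins[sp$bin, "end"]
    w <- be - bs
    ws1 <- pos0 + bs + 1L                     # 1-based start of bin
    we1 <- pos0 + be                          # 1-based inclusive end
    vals[, k] <- switch(sp$kind,
      base_fraction = {
        cnt <- 0
        for (ch in strsplit(sp$param, "")[[1]])
          cnt <- cnt + (cache$prefix[[ch]][we1 + 1L] - cache$prefix[[ch]][ws1])
        cnt / w
      },
      at_ratio = {
        a <- cache$prefix[["A"]][we1 + 1L] - cache$prefix[["A"]][ws1]
        t <- cache$prefix[["T"]][we1 + 1L] - cache$prefix[["T"]][ws1]
        ifelse(a + t == 0, 0, (a - t) / (a + t))
      },
      polyA_tract = window_longest_run(cache$runA, ws1, w),
      polyT_tract = window_longest_run(cache$runT, ws1, w),
      motif_max_score = {
        x <- cache$motif[[sp$param]]
        window_max(x, ws1, w, floor_val = min(x))
      },
      dinucleotide_property_mean = {
        s <- cache[[paste0("dinuc_", sp$param)]]
        cn <- cache[[paste0("dinucn_", sp$param)]]
        hi <- pmin(we1, cache$L - 1L)         # dinucleotide start positions
        tot <- s[hi + 1L] - s[ws1]
        nn <- cn[hi + 1L] - cn[ws1]
        ifelse(nn > 0, tot / nn, 0)
      })
  }
  vals
}

#' Extract binned feature vectors for a set of anchors
#'
#' For minus-strand anchors the window sequence is the reverse complement,
#' so offsets always read 5' to 3' along the putative transcript; feature
#' extraction is therefore strand-symmetric by construction.
#'
#' @param genome a [Genome()].
#' @param anchors data.frame with columns `chrom`, `pos` (0-based anchor
#'   base), `strand` (`+`/`-`).
#' @param scheme a [bin_scheme()].
#' @param specs feature-spec data.frame (e.g. [default_initiation_specs()]).
#' @param motifs named list of [motif_model()]s.
#' @param on_oob `"error"` to reject anchors whose window leaves the
#'   chromosome, `"clip"` to compute them against an edge-padded sequence
#'   (used for genome scoring, where edge bases are masked downstream).
#' @return numeric matrix, one row per anchor (in input order), one column
#'   per feature.
#' @export
extract_feature_matrix <- function(genome, anchors, scheme, specs, motifs,
                                   on_oob = c("error", "clip")) {
  on_oob <- match.arg(on_oob)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(anchors)))
  len <- seq_lengths(genome)
  out <- matrix(NA_real_, nrow(anchors), nrow(specs),
                dimnames = list(NULL, specs$name))
  for (nm in unique(anchors$chrom)) {
    L <- len[[nm]]
    for (st in c("+", "-")) {
      sel <- which(anchors$chrom == nm & anchors$strand == st)
      if (!length(sel)) next
      pos <- anchors$pos[sel]
      pos0 <- if (st == "+") pos else L - 1L - pos
      lo <- pos0 + scheme$window_start
      hi <- pos0 + scheme$window_end
      if (on_oob == "error" && (any(lo < 0L) || any(hi > L)))
        stop("feature window out of chromosome bounds")
      seq_o <- if (st == "+") genome[[nm]] else reverse_complement(genome[[nm]])
      cache <- chrom_feature_cache(seq_o, specs, motifs)
      out[sel, ] <- features_for_oriented(cache, pos0, scheme, specs)
    }
  }
  out
}

#' Extract the feature vector of a single anchor
#'
#' @inheritParams extract_feature_matrix
#' @param chrom,pos,strand the anchor (0-based base, stranded).
#' @param label optional class label stored as an attribute.
#' @return named numeric vector of feature values.
#' @export
extract_features <- function(genome, chrom, pos, strand, scheme, specs,
                             motifs, label = "unlabeled") {
  m <- extract_feature_matrix(genome,
                              data.frame(chrom = chrom, pos = pos,
                                         strand = strand),
                              scheme, specs, motifs)
  structure(m[1, ], label = label,
            anchor = list(chrom = chrom, pos = pos, strand = strand))
}

#' Build positive and negative training anchors for both classifiers
#'
#' Initiation positives sit at annotated TSS bases; negatives tile the rest
#' of the genome in overlapping 600-bp windows (stride half a window),
#' excluding anchors near any annotated TSS. Termination positives sit at
#' CPA bases; negatives tile transcript bodies in overlapping 150-bp
#' segments, excluding the CPA window. Transcripts too short to host a
#' negative segment contribute none (with a warning).
#'
#' @param genome a [Genome()].
#' @param annotations a [transcript_annotations()] table.
#' @param init_scheme,term_scheme bin schemes (defaults as in the model).
#' @param init_stride,term_stride negative tiling strides (bp).
#' @param init_exclusion minimum distance (bp) between an initiation
#'   negative anchor and any annotated TSS.
#' @param term_exclusion minimum distance (bp) between a termination
#'   negative anchor and its transcript's CPA region.
#' @return list with `initiation` and `termination`, each a data.frame of
#'   anchors (`chrom`, `pos`, `strand`, `label` in `{positive, negative}`).
#' @export
make_training_sets <- function(genome, annotations,
                               init_scheme = default_initiation_scheme(),
                               term_scheme = default_termination_scheme(),
                               init_stride = 300L, term_stride = 75L,
                               init_exclusion = 500L, term_exclusion = 150L) {
  len <- seq_lengths(genome)
  init_pos <- if (nrow(annotations)) data.frame(
    chrom = annotations$chrom, pos = annotations$tss_pos,
    strand = annotations$strand, label = "positive") else NULL

  neg <- list()
  for (nm in names(len)) {
    L <- len[[nm]]
    for (st in c("+", "-")) {
      # exclusion is same-strand: an anchor reading the reverse strand of a
      # promoter is a legitimate (and informative) non-TSS negative
      tss_here <- annotations$tss_pos[annotations$chrom == nm &
                                        annotations$strand == st]
      # window-feasible anchor range depends on strand orientation
      if (st == "+") {
        first <- -init_scheme$window_start
        last <- L - init_scheme$window_end
      } else {
        first <- init_scheme$window_end - 1L
        last <- L - 1L + init_scheme$window_start
      }
      if (last < first) next
      anchors <- seq(first, last, by = init_stride)
      keep <- if (length(tss_here))
        vapply(anchors, function(p) all(abs(p - tss_here) >= init_exclusion),
               logical(1))
      else rep(TRUE, length(anchors))
      if (any(keep))
        neg[[length(neg) + 1L]] <- data.frame(chrom = nm, pos = anchors[keep],
                                              strand = st, label = "negative")
    }
  }
  initiation <- rbind(init_pos, do.call(rbind, neg))

  term_pos <- if (nrow(annotations)) data.frame(
    chrom = annotations$chrom, pos = annotations$cpa_pos,
    strand = annotations$strand, label = "positive") else NULL
  tneg <- list()
  short <- character(0)
  half <- -term_scheme$window_start
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    # anchors whose 150-bp segment fits inside the transcript body,
    # clear of the CPA region
    if (a$strand == "+") {
      lo <- a$start + half
      hi <- a$cpa_start - term_exclusion
    } else {
      lo <- a$cpa_end + term_exclusion
      hi <- a$end - (term_scheme$window_end)
    }
    if (hi < lo) { short <- c(short, a$id); next }
    p <- seq(lo, hi, by = term_stride)
    tneg[[length(tneg) + 1L]] <- data.frame(chrom = a$chrom, pos = p,
                                            strand = a$strand,
                                            label = "negative")
  }
  if (length(short))
    warning(length(short), " transcript(s) too short to host a negative window")
  termination <- rbind(term_pos, do.call(rbind, tneg))
  list(initiation = initiation, termination = termination)
}

#' Write a feature matrix with anchors as TSV
#' @param features numeric feature matrix from [extract_feature_matrix()].
#' @param anchors the matching anchor data.frame.
#' @param path output path.
#' @export
write_feature_matrix <- function(features, anchors, path) {
  utils::write.table(cbind(anchors, as.data.frame(features)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
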