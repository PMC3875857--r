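DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> base sets
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) stop("not an IUPAC code: ", code)
  strsplit(map[[code]], "")[[1]]
}

iupac_to_regex <- function(pattern) {
  paste0(vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    b <- iupac_bases(ch)
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Construct a motif model (position frequency matrix)
#'
#' @param name motif name.
#' @param pfm width x 4 matrix of per-position base frequencies, columns in
#'   A, C, G, T order. Rows are renormalized to sum to 1.
#' @param pseudocount small frequency added to every entry before log-odds
#'   conversion so scores stay finite.
#' @param background base-probability 4-vector (A, C, G, T), summing to 1.
#' @return a `MotifModel` object.
#' @export
motif_model <- function(name, pfm, pseudocount = 0.001,
                        background = rep(0.25, 4)) {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4 || nrow(pfm) < 1) stop("pfm must be width x 4, width >= 1")
  if (any(pfm < 0)) stop("pfm frequencies must be non-negative")
  if (any(rowSums(pfm) == 0)) stop("pfm row with zero total")
  pfm <- pfm / rowSums(pfm)
  colnames(pfm) <- DNA_BASES
  if (pseudocount <= 0) stop("pseudocount must be positive")
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive probabilities")
  background <- background / sum(background)
  structure(list(name = name, pfm = pfm, pseudocount = pseudocount,
                 background = background),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$pfm, 1, which.max)], collapse = "")
  cat(sprintf("MotifModel '%s': width %d, consensus %s\n",
              x$name, nrow(x$pfm), cons))
  invisible(x)
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' Entry `[i, b]` is `log2(((f[i,b] + pc) / (1 + 4 pc)) / background[b])`;
#' the pseudocount keeps every entry finite.
#'
#' @param motif a [motif_model()].
#' @return width x 4 numeric matrix of log2 odds.
#' @export
pfm_to_pwm <- function(motif) {
  pc <- motif$pseudocount
  p <- (motif$pfm + pc) / (1 + 4 * pc)
  lw <- log2(sweep(p, 2, motif$background, "/"))
  colnames(lw) <- DNA_BASES
  lw
}

# integer encoding of a DNA string: A=1 C=2 G=3 T=4, N/other = NA
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

#' Per-offset PWM scores along a sequence
#'
#' @param seq DNA string of length `L`.
#' @param pwm log-odds matrix from [pfm_to_pwm()].
#' @param n_penalty score contribution of an N (or other non-ACGT) base.
#' @return numeric vector of length `L - width + 1`: the summed log-odds of
#'   the motif starting at each 0-based offset.
#' @export
score_positions <- function(seq, pwm, n_penalty = min(pwm)) {
  w <- nrow(pwm)
  b <- encode_dna(seq)
  L <- length(b)
  if (L < w) stop("sequence shorter than motif")
  n <- L - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    col <- unname(pwm[j, ])[b[j:(j + n - 1L)]]
    col[is.na(col)] <- n_penalty
    s <- s + col
  }
  s
}

#' Best PWM match in a sequence
#'
#' Maximum summed log-odds over all offsets (and optionally both strands).
#' Ties break to the leftmost position, then to the `+` strand.
#'
#' @param seq DNA string.
#' @param pwm log-odds matrix from [pfm_to_pwm()].
#' @param both_strands also scan the reverse complement.
#' @return list with `score`, `pos` (0-based offset of the match on the
#'   forward sequence) and `strand`.
#' @export
scan_max_score <- function(seq, pwm, both_strands = FALSE) {
  fwd <- score_positions(seq, pwm)
  best <- list(score = max(fwd), pos = which.max(fwd) - 1L, strand = "+")
  if (both_strands) {
    w <- nrow(pwm)
    rc <- score_positions(reverse_complement(seq), pwm)
    # offset j (0-based) on the reverse complement starts at L - w - j forward
    pos_fwd <- (length(rc) - 1L):0L
    o <- order(pos_fwd)
    rev_scores <- rc[o]            # indexed by forward position 0..L-w
    better <- rev_scores > fwd
    tie <- rev_scores == fwd       # + strand wins ties at equal position
    comb <- ifelse(better, rev_scores, fwd)
    i <- which.max(comb)
    best <- list(score = comb[i], pos = i - 1L,
                 strand = if (better[i]) "-" else "+")
  }
  best
}

#' Sample one binding-site instance from a PFM
#'
#' Draws each position independently using the frequency columns as weights.
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param motif a [motif_model()].
#' @return DNA string of the motif's width.
#' @export
sample_site <- function(motif) {
  paste(apply(motif$pfm, 1, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

#' Find matches of an IUPAC consensus pattern
#'
#' @param seq DNA string.
#' @param pattern IUPAC consensus (e.g. `"TATATA"`, `"SAA"`, `"YR"`).
#' @param overlapping count every matching offset (`TRUE`) or greedily
#'   consume matches left to right (`FALSE`).
#' @return integer vector of 0-based match offsets.
#' @export
find_matches <- function(seq, pattern, overlapping = TRUE) {
  rx <- iupac_to_regex(pattern)
  if (overlapping) rx <- paste0("(?=", rx, ")")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Count matches of an IUPAC consensus pattern
#'
#' @inheritParams find_matches
#' @param both_strands also count matches on the reverse complement.
#' @return integer match count.
#' @export
count_matches <- function(seq, pattern, overlapping = TRUE,
                          both_strands = FALSE) {
  n <- length(find_matches(seq, pattern, overlapping))
  if (both_strands)
    n <- n + length(find_matches(reverse_complement(seq), pattern, overlapping))
  n
}

#' Expected consensus-match density in random sequence
#'
#' Analytic overlap-ignoring approximation: the product over pattern
#' positions of the total probability of the allowed bases, times 1000
#' positions per kb, per strand.
#'
#' @param pattern IUPAC consensus.
#' @param composition base-probability 4-vector (A, C, G, T).
#' @return expected matches per kb per strand.
#' @export
expected_match_density <- function(pattern, composition = rep(0.25, 4)) {
  composition <- as.numeric(composition)
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  names(composition) <- DNA_BASES
  p <- vapply(strsplit(toupper(pattern), "")[[1]],
              function(ch) sum(composition[iupac_bases(ch)]), numeric(1))
  1000 * prod(p)
}

#' Write consensus matches as BED6
#' @param genome a [Genome()].
#' @param pattern IUPAC consensus.
#' @param path output BED path.
#' @param both_strands scan both strands.
#' @export
write_matches_bed <- function(genome, pattern, path, both_strands = TRUE) {
  w <- nchar(pattern)
  rows <- list()
  for (nm in names(genome)) {
    sq <- genome[[nm]]
    pos <- find_matches(sq, pattern)
    if (length(pos))
      rows[[length(rows) + 1L]] <- data.frame(chrom = nm, start = pos,
                                              end = pos + w, strand = "+")
    if (both_strands) {
      L <- nchar(sq)
      posm <- find_matches(reverse_complement(sq), pattern)
      if (length(posm))
        rows[[length(rows) + 1L]] <- data.frame(chrom = nm,
                                                start = L - posm - w,
                                                end = L - posm,
                                                strand = "-")
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character())
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$name <- rep(pattern, length(gr))
  gr$score <- rep(0, length(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read motif models from a plain-text PFM file
#'
#' Format: one or more records of a `>name` line followed by `width` rows of
#' four whitespace-separated frequencies (A C G T).
#'
#' @param path input file.
#' @param pseudocount,background passed to [motif_model()].
#' @return named list of [motif_model()]s.
#' @export
read_pfm <- function(path, pseudocount = 0.001, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    nm <- sub("^>\\s*", "", lines[starts[k]])
    rows <- lines[(starts[k] + 1L):ends[k]]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    out[[nm]] <- motif_model(nm, mat, pseudocount, background)
  }
  out
}

#' Read motif models from MEME minimal format
#' @inheritParams read_pfm
#' @return named list of [motif_model()]s.
#' @export
read_meme <- function(path, pseudocount = 0.001, background = rep(0.25, 4)) {
  lines <- readLines(path)
  heads <- grep("^MOTIF", lines)
  if (!length(heads)) stop("no MOTIF records in ", path)
  out <- list()
  for (h in heads) {
    nm <- strsplit(trimws(lines[h]), "\\s+")[[1]][2]
    mi <- grep("^letter-probability matrix", lines)
    mi <- mi[mi > h][1]
    if (is.na(mi)) stop("no letter-probability matrix for motif ", nm)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mi]))
    rows <- lines[(mi + 1L):(mi + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[nm]] <- motif_model(nm, mat, pseudocount, background)
  }
  out
}

#' The package's bundled illustrative motif library
#'
#' Small plain-text PFMs for the general regulatory factors (Reb1, Abf1,
#' Rap1), the RSC subunit Rsc3, the TATA box (Spt15/TBP) and the Hrp1
#' cleavage efficiency element. These are illustrative stand-ins shaped
#' after the factors' published consensi, suitable for simulation and
#' testing; users with curated matrices (e.g. YeTFaSCo) can load them with
#' [read_pfm()] or [read_meme()] instead.
#'
#' @param background base-probability 4-vector used for log-odds scoring.
#' @param pseudocount pseudocount frequency.
#' @return named list of [motif_model()]s.
#' @export
default_motif_library <- function(background = c(0.31, 0.19, 0.19, 0.31),
                                  pseudocount = 0.001) {
  path <- system.file("extdata", "pfm", "core_motifs_synthetic.pfm",
                      package = "txunify")
  read_pfm(path, pseudocount = pseudocount, background = background)
}
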