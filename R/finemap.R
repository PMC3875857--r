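#' Call peaks on a classifier score track
#'
#' Maximal runs of scores at or above `threshold`; runs separated by fewer
#' than `min_separation` bases are merged. The summit is the leftmost
#' maximal-score base of the peak.
#'
#' @param track a `ScoreTrack` from [score_genome()].
#' @param threshold score threshold in `[0, 1]`.
#' @param min_separation merge distance in bp (default 150, the termination
#'   window width).
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `summit` (0-based), `max_score`.
#' @export
call_peaks <- function(track, threshold = 0.5, min_separation = 150L) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- list()
  for (st in c("+", "-")) {
    lst <- if (st == "+") track$plus else track$minus
    for (nm in names(lst)) {
      v <- lst[[nm]]
      above <- v >= threshold
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- cbind(starts[r$values], ends[r$values])
      # merge runs closer than min_separation
      merged <- list(runs[1, ])
      if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
        last <- merged[[length(merged)]]
        if (runs[i, 1] - last[2] - 1L < min_separation)
          merged[[length(merged)]] <- c(last[1], runs[i, 2])
        else merged[[length(merged) + 1L]] <- runs[i, ]
      }
      for (m in merged) {
        seg <- v[m[1]:m[2]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = m[1] - 1L, end = m[2], strand = st,
          summit = m[1] - 1L + which.max(seg) - 1L, max_score = max(seg))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      summit = integer(), max_score = numeric()))
  do.call(rbind, out)
}

# nearest strand-oriented IUPAC match to the summit inside a peak; returns
# the 0-based genomic position of the base at `report_offset` within the
# match, or NA. Ties go to the 5'-most occurrence.
nearest_match_in_peak <- function(genome, peak, pattern, report_offset) {
  sq <- genome[[peak$chrom]]
  L <- nchar(sq)
  w <- nchar(pattern)
  if (peak$strand == "+") {
    sub <- substr(sq, peak$start + 1L, peak$end)
    off <- find_matches(sub, pattern)               # 0-based within peak
    if (!length(off)) return(NA_integer_)
    pos <- peak$start + off + report_offset         # genomic base reported
    d <- abs(pos - peak$summit)
    pos[order(d, pos)][1]                           # 5'-most on ties
  } else {
    # scan the reverse complement of the peak so the pattern reads 5'->3'
    sub <- reverse_complement(substr(sq, peak$start + 1L, peak$end))
    off <- find_matches(sub, pattern)
    if (!length(off)) return(NA_integer_)
    pos <- peak$end - 1L - (off + report_offset)    # map back to forward
    d <- abs(pos - peak$summit)
    pos[order(d, -pos)][1]                          # 5'-most = largest coord
  }
}

#' Fine-map the exact TSS base within an initiation-score peak
#'
#' Searches the peak for the initiator `CA` dinucleotide (strand-oriented)
#' and returns the purine (A) position of the occurrence nearest the peak
#' summit (5'-most on ties); with no `CA`, falls back to the general `YR`
#' initiator consensus, and finally to the summit itself.
#'
#' @param peak one row of [call_peaks()] output.
#' @param genome a [Genome()].
#' @return 0-based genomic position of the fine-mapped TSS.
#' @export
locate_tss <- function(peak, genome) {
  p <- nearest_match_in_peak(genome, peak, "CA", report_offset = 1L)
  if (is.na(p)) p <- nearest_match_in_peak(genome, peak, "YR", report_offset = 1L)
  if (is.na(p)) p <- peak$summit
  p
}

#' Fine-map the exact cleavage base within a termination-score peak
#'
#' Searches for the cleavage-site `SAA` motif (S = G or C, strand-oriented)
#' and returns the first A of the occurrence nearest the summit (5'-most on
#' ties), falling back to the summit.
#'
#' @inheritParams locate_tss
#' @return 0-based genomic position of the fine-mapped CPA site.
#' @export
locate_cpa <- function(peak, genome) {
  p <- nearest_match_in_peak(genome, peak, "SAA", report_offset = 1L)
  if (is.na(p)) p <- peak$summit
  p
}

#' Write peaks (or fine-mapped sites) as BED6
#' @param peaks data.frame from [call_peaks()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = peaks$strand)
  gr$name <- paste0("peak", seq_len(nrow(peaks)))
  gr$score <- peaks$max_score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
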