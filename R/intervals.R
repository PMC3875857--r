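#' @importFrom methods as is
NULL

#' The eight hidden states of the unified transcript model
#'
#' `IG` intergenic; `TSS+`/`TSS-` transcription start regions; `Gene+`/`Gene-`
#' transcript bodies; `CPA+`/`CPA-` cleavage/polyadenylation regions; `Term`
#' the bidirectional terminator shared by convergent transcripts.
#' @export
UM_STATES <- c("IG", "TSS+", "Gene+", "CPA+", "TSS-", "Gene-", "CPA-", "Term")

# default spans of start/cleavage heterogeneity used when annotations give
# single bases: starts vary over ~26 bp, cleavage over ~36 bases
TSS_REGION_WIDTH <- 26L
CPA_REGION_WIDTH <- 36L

#' Construct a stranded genomic interval
#'
#' Coordinates are 0-based and half-open throughout the package (BED
#' convention); GFF3 input is converted at the boundary.
#'
#' @param chrom chromosome name(s).
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  if (any(d$start < 0L) || any(d$start >= d$end))
    stop("require 0 <= start < end")
  if (!all(d$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  d
}

check_in_bounds <- function(intervals, genome) {
  len <- seq_lengths(genome)
  if (!all(intervals$chrom %in% names(len)))
    stop("unknown chromosome(s): ",
         paste(setdiff(intervals$chrom, names(len)), collapse = ", "))
  if (any(intervals$end > len[intervals$chrom]))
    stop("interval(s) extend beyond chromosome end")
  invisible(TRUE)
}

#' Build a table of transcript annotations
#'
#' Each transcript is a single stranded interval with a TSS region at its 5'
#' end and a CPA region at its 3' end. If only anchor bases (`tss_pos`,
#' `cpa_pos`) are given, regions default to 26 bp centred on the TSS and
#' 36 bp centred on the CPA site, reflecting the typical spread of start and
#' cleavage positions; if neither anchors nor regions are given, the
#' transcript's 5'/3' terminal bases are used as anchors.
#'
#' @param df data.frame with columns `id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (0-based half-open), and optionally `tss_pos`, `cpa_pos`
#'   (0-based anchor bases) and/or `tss_start`, `tss_end`, `cpa_start`,
#'   `cpa_end` (region bounds).
#' @param genome optional [Genome()]; if given, regions are clipped to
#'   chromosome bounds and bounds are checked.
#' @param tss_width,cpa_width region widths used when only anchors are given.
#' @return data.frame of class `"transcript_annotations"`.
#' @export
transcript_annotations <- function(df, genome = NULL,
                                   tss_width = TSS_REGION_WIDTH,
                                   cpa_width = CPA_REGION_WIDTH) {
  need <- c("id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("transcripts must be stranded")
  if (anyDuplicated(df$id)) stop("duplicate transcript ids")
  plus <- df$strand == "+"
  if (is.null(df$tss_pos)) df$tss_pos <- ifelse(plus, df$start, df$end - 1L)
  if (is.null(df$cpa_pos)) df$cpa_pos <- ifelse(plus, df$end - 1L, df$start)
  if (is.null(df$tss_start)) {
    half <- tss_width %/% 2L
    df$tss_start <- as.integer(df$tss_pos - half)
    df$tss_end   <- as.integer(df$tss_start + tss_width)
  }
  if (is.null(df$cpa_start)) {
    half <- cpa_width %/% 2L
    df$cpa_start <- as.integer(df$cpa_pos - half)
    df$cpa_end   <- as.integer(df$cpa_start + cpa_width)
  }
  df$tss_start <- pmax(df$tss_start, 0L)
  df$cpa_start <- pmax(df$cpa_start, 0L)
  if (!is.null(genome)) {
    len <- seq_lengths(genome)
    check_in_bounds(df, genome)
    df$tss_end <- pmin(df$tss_end, len[df$chrom])
    df$cpa_end <- pmin(df$cpa_end, len[df$chrom])
  }
  # TSS region 5' of CPA region along the transcript
  ok <- ifelse(plus, df$tss_end <= df$cpa_start, df$cpa_end <= df$tss_start)
  if (!all(ok))
    stop("TSS and CPA regions overlap or are mis-ordered for: ",
         paste(df$id[!ok], collapse = ", "))
  class(df) <- c("transcript_annotations", "data.frame")
  df
}

#' Convert transcript annotations to GRanges
#' @param annotations a [transcript_annotations()] table.
#' @return a `GRanges` with `id` metadata.
#' @export
annotations_to_granges <- function(annotations) {
  GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand,
    id = annotations$id)
}

#' Read transcript annotations from BED6 or GFF3
#'
#' BED is read as 0-based half-open, GFF3 as 1-based inclusive; both are
#' converted to the package's internal 0-based half-open convention.
#' Transcript 5'/3' terminal bases serve as TSS/CPA anchors.
#'
#' @param path input file (`.bed`, `.gff`, `.gff3`).
#' @param genome optional [Genome()] for bounds checking/clipping.
#' @return a [transcript_annotations()] table.
#' @export
read_annotations <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else if (!is.null(gr$ID)) as.character(gr$ID)
         else paste0("tx", seq_along(gr))
  df <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  transcript_annotations(df, genome = genome)
}

#' Write transcript annotations as BED6
#' @param annotations a [transcript_annotations()] table.
#' @param path output path.
#' @param score numeric score column (recycled).
#' @export
write_annotations_bed <- function(annotations, path, score = 0) {
  gr <- annotations_to_granges(annotations)
  gr$score <- rep_len(score, length(gr))
  gr$name <- gr$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
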