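#' Genome: named DNA sequences
#'
#' A `Genome` is an ordered named character vector of uppercase DNA strings
#' over the alphabet `{A,C,G,T,N}`. All coordinates elsewhere in the package
#' are 0-based, half-open, as in BED.
#'
#' @param sequences named character vector (or named list) of DNA strings.
#' @return a `Genome` object (named character vector with class `"Genome"`).
#' @export
Genome <- function(sequences) {
  sequences <- vapply(sequences, as.character, character(1))
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty sequence(s) not allowed")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("illegal characters (outside A,C,G,T,N) in: ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(sequences, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome with %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s: %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Lengths of the chromosomes of a Genome
#' @param genome a [Genome()].
#' @return named integer vector of sequence lengths.
#' @export
seq_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on input; characters outside `{A,C,G,T,N}` and
#' duplicated record names are rejected.
#'
#' @param path path to a FASTA file.
#' @return a [Genome()].
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  Genome(stats::setNames(as.character(ss), nms))
}

#' Write a genome to FASTA
#' @param genome a [Genome()].
#' @param path output path.
#' @param width line width.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Length-preserving involution over `{A,C,G,T,N}`.
#'
#' @param seq a single DNA string.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(seq) {
  if (grepl("[^ACGTNacgtn]", seq)) stop("illegal character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Reverse-complement every chromosome of a genome
#' @param genome a [Genome()].
#' @return a [Genome()] with each sequence reverse-complemented.
#' @export
reverse_complement_genome <- function(genome) {
  Genome(stats::setNames(vapply(unclass(genome), reverse_complement, character(1)),
                         names(genome)))
}

#' Base composition of a genome
#' @param genome a [Genome()].
#' @return numeric 4-vector of A, C, G, T frequencies (N excluded), summing to 1.
#' @export
genome_composition <- function(genome) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  cnt <- colSums(Biostrings::letterFrequency(ss, c("A", "C", "G", "T")))
  cnt / sum(cnt)
}
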