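#' Per-base 8-state transcript map
#'
#' A `StateMap` assigns one of the eight hidden states ([UM_STATES]) to every
#' base of every chromosome, plus a logical mask of bases excluded from
#' parameter estimation (bases covered by transcripts on both strands, which
#' the model cannot represent).
#'
#' @param states named list (one per chromosome) of integer vectors indexing
#'   [UM_STATES].
#' @param mask named list of logical vectors, same shape.
#' @return a `StateMap` object.
#' @export
StateMap <- function(states, mask = NULL) {
  if (is.null(mask))
    mask <- lapply(states, function(s) rep(FALSE, length(s)))
  stopifnot(identical(names(states), names(mask)))
  for (nm in names(states)) {
    s <- states[[nm]]
    if (any(s < 1L | s > 8L)) stop("state codes must index UM_STATES (1..8)")
    if (length(mask[[nm]]) != length(s)) stop("mask/state length mismatch")
  }
  structure(list(states = states, mask = mask), class = "StateMap")
}

#' @export
print.StateMap <- function(x, ...) {
  n <- sum(vapply(x$states, length, numeric(1)))
  cat(sprintf("StateMap over %d chromosome(s), %s bases (%d masked)\n",
              length(x$states), format(n, big.mark = ","),
              sum(vapply(x$mask, sum, numeric(1)))))
  tab <- table(factor(UM_STATES[unlist(x$states, use.names = FALSE)], levels = UM_STATES))
  print(tab)
  invisible(x)
}

state_code <- function(label) {
  i <- match(label, UM_STATES)
  if (anyNA(i)) stop("unknown state label(s): ", paste(label[is.na(i)], collapse = ", "))
  i
}

# label bases [start,end) of vector v (0-based half-open) with code
fill_span <- function(v, start, end, code) {
  if (end > start) v[(start + 1L):end] <- code
  v
}

#' Convert transcript annotations into a per-base 8-state map
#'
#' Bases in a transcript's TSS region become `TSS+`/`TSS-`, its CPA region
#' `CPA+`/`CPA-`, and the span between them `Gene+`/`Gene-`; where the CPA
#' regions of convergent transcripts overlap, the shared bases become the
#' bidirectional `Term` state. Everything else is `IG`. Bases covered by
#' transcripts on both strands in any other configuration are masked (the
#' model has no states for simultaneous sense/antisense transcription);
#' masked bases keep the label `IG`.
#'
#' @param annotations a [transcript_annotations()] table.
#' @param genome a [Genome()] providing chromosome names and lengths.
#' @return a [StateMap()].
#' @export
build_state_map <- function(annotations, genome) {
  len <- seq_lengths(genome)
  if (nrow(annotations) > 0) check_in_bounds(annotations, genome)
  states <- mask <- list()
  for (nm in names(len)) {
    L <- len[[nm]]
    # strand-wise layers: 0 = none, then TSS/Gene/CPA codes
    lay_p <- integer(L); lay_m <- integer(L)
    ann <- annotations[annotations$chrom == nm, , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      if (a$strand == "+") {
        lay_p <- fill_span(lay_p, a$tss_start, a$tss_end, state_code("TSS+"))
        lay_p <- fill_span(lay_p, a$tss_end, a$cpa_start, state_code("Gene+"))
        lay_p <- fill_span(lay_p, a$cpa_start, a$cpa_end, state_code("CPA+"))
      } else {
        lay_m <- fill_span(lay_m, a$cpa_start, a$cpa_end, state_code("CPA-"))
        lay_m <- fill_span(lay_m, a$cpa_end, a$tss_start, state_code("Gene-"))
        lay_m <- fill_span(lay_m, a$tss_start, a$tss_end, state_code("TSS-"))
      }
    }
    s <- rep(state_code("IG"), L)
    mk <- rep(FALSE, L)
    only_p <- lay_p > 0L & lay_m == 0L
    only_m <- lay_m > 0L & lay_p == 0L
    both <- lay_p > 0L & lay_m > 0L
    s[only_p] <- lay_p[only_p]
    s[only_m] <- lay_m[only_m]
    term <- both & lay_p == state_code("CPA+") & lay_m == state_code("CPA-")
    s[term] <- state_code("Term")
    clash <- both & !term
    mk[clash] <- TRUE          # label stays IG for decoding comparisons
    states[[nm]] <- s
    mask[[nm]] <- mk
  }
  StateMap(states, mask)
}

#' Apply the strand-swap involution to a StateMap
#'
#' Position-reverses each chromosome and swaps `+`/`-` states, i.e. the state
#' map of the reverse-complemented genome.
#'
#' @param state_map a [StateMap()].
#' @return a [StateMap()].
#' @export
sigma_state_map <- function(state_map) {
  sig <- state_code(sigma_states()[UM_STATES])
  StateMap(lapply(state_map$states, function(s) rev(sig[s])),
           lapply(state_map$mask, rev))
}

#' Export a StateMap as TSV (chrom, pos, state)
#' @param state_map a [StateMap()].
#' @param path output path.
#' @export
write_state_map <- function(state_map, path) {
  df <- do.call(rbind, lapply(names(state_map$states), function(nm) {
    data.frame(chrom = nm,
               pos = seq_along(state_map$states[[nm]]) - 1L,
               state = UM_STATES[state_map$states[[nm]]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-strand transcribed-base indicator from a StateMap
#'
#' @param state_map a [StateMap()].
#' @return list with `plus` and `minus`: named lists of logical vectors,
#'   `TRUE` where a base is part of a transcript on that strand (`Term`
#'   counts for both).
#' @export
transcribed_mask <- function(state_map) {
  p <- state_code(c("TSS+", "Gene+", "CPA+", "Term"))
  m <- state_code(c("TSS-", "Gene-", "CPA-", "Term"))
  list(plus = lapply(state_map$states, function(s) s %in% p),
       minus = lapply(state_map$states, function(s) s %in% m))
}
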