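#' Per-strand transcribed-base mask from posterior marginals
#'
#' @param posterior a `PosteriorTrack`.
#' @param threshold posterior threshold.
#' @return `list(plus = , minus = )` of per-chromosome logical vectors,
#'   suitable for [pr_per_base()].
#' @export
posterior_transcribed_mask <- function(posterior, threshold = 0.5) {
  list(plus = lapply(transcript_probability(posterior, "+"),
                     function(v) v >= threshold),
       minus = lapply(transcript_probability(posterior, "-"),
                      function(v) v >= threshold))
}

#' Train the full unified model on an annotated genome
#'
#' Builds training sets from the annotations, trains the initiation and
#' termination classifiers with leave-one-chromosome-out folds, scores the
#' training genome on both strands, and estimates the symmetric HMM
#' parameters from the genome's 8-state transcript map.
#'
#' @param genome a [Genome()].
#' @param annotations ground-truth [transcript_annotations()].
#' @param motifs motif library.
#' @param config an [ensemble_config()].
#' @param stride genome-scoring stride (bp).
#' @param state_map optional precomputed [StateMap()] for parameter
#'   estimation. By default one is built from the annotations with TSS/CPA
#'   state widths of `train_tss_width`/`train_cpa_width` rather than the
#'   narrow annotation defaults: the classifier score peaks span roughly the
#'   feature-window resolution, and matching the emission states to that
#'   span keeps the score bleed around transcript ends out of the
#'   `Gene`/`IG` states (whose variances it would otherwise inflate,
#'   biasing decoding against transcript interiors).
#' @param train_tss_width,train_cpa_width TSS/CPA state widths (bp) used
#'   for the training state map.
#' @return a `UnifiedModel`: list with the two ensembles, their schemes and
#'   specs, the motif library, HMM `params`, and the training score tracks.
#' @export
train_unified_model <- function(genome, annotations,
                                motifs = default_motif_library(),
                                config = ensemble_config(),
                                stride = 10L, state_map = NULL,
                                train_tss_width = 70L,
                                train_cpa_width = 150L) {
  init_scheme <- default_initiation_scheme()
  term_scheme <- default_termination_scheme()
  init_specs <- default_initiation_specs()
  term_specs <- default_termination_specs()
  sets <- make_training_sets(genome, annotations, init_scheme, term_scheme)
  train_one <- function(anchors, scheme, specs) {
    fx <- extract_feature_matrix(genome, anchors, scheme, specs, motifs)
    train_ensemble(fx, anchors$label, anchors$chrom, config, specs = specs)
  }
  init_ens <- train_one(sets$initiation, init_scheme, init_specs)
  term_ens <- train_one(sets$termination, term_scheme, term_specs)
  init_track <- score_genome(genome, init_ens, init_scheme, init_specs,
                             motifs, stride)
  term_track <- score_genome(genome, term_ens, term_scheme, term_specs,
                             motifs, stride)
  obs <- um_observations(init_track, term_track)
  if (is.null(state_map)) {
    wide <- annotations
    wide$tss_start <- wide$tss_end <- wide$cpa_start <- wide$cpa_end <- NULL
    wide <- transcript_annotations(as.data.frame(wide), genome,
                                   tss_width = train_tss_width,
                                   cpa_width = train_cpa_width)
    state_map <- build_state_map(wide, genome)
  }
  params <- estimate_parameters(state_map, obs, variance_pool_floor = TRUE,
                                robust = TRUE)
  structure(list(init_ensemble = init_ens, term_ensemble = term_ens,
                 init_scheme = init_scheme, term_scheme = term_scheme,
                 init_specs = init_specs, term_specs = term_specs,
                 motifs = motifs, params = params, stride = stride,
                 train_tracks = list(init = init_track, term = term_track)),
            class = "UnifiedModel")
}

#' Refine called transcript ends against the classifier score tracks
#'
#' The posterior's boundary-state mass can sit slightly off the true site
#' (its spread reflects the HMM's state widths); the raw classifier peaks
#' are sharply centred at the sites they were trained on. Each TSS/CPA
#' anchor is moved to the maximum of the corresponding strand score track
#' within `radius` bp.
#'
#' @param transcripts a [transcript_annotations()] table of calls.
#' @param init_track,term_track `ScoreTrack`s from [score_genome()].
#' @param radius search radius in bp.
#' @return the calls with refined `tss_pos`/`cpa_pos`.
#' @export
refine_transcript_anchors <- function(transcripts, init_track, term_track,
                                      radius = 300L) {
  for (i in seq_len(nrow(transcripts))) {
    ch <- transcripts$chrom[i]; st <- transcripts$strand[i]
    it <- if (st == "+") init_track$plus[[ch]] else init_track$minus[[ch]]
    tt <- if (st == "+") term_track$plus[[ch]] else term_track$minus[[ch]]
    L <- length(it)
    win <- function(p) max(1L, p + 1L - radius):min(L, p + 1L + radius)
    wi <- win(transcripts$tss_pos[i])
    tss <- wi[which.max(it[wi])] - 1L
    wc <- win(transcripts$cpa_pos[i])
    cpa <- wc[which.max(tt[wc])] - 1L
    ok <- if (st == "+") tss < cpa else cpa < tss
    if (ok) {
      transcripts$tss_pos[i] <- tss
      transcripts$cpa_pos[i] <- cpa
      transcripts$tss_start[i] <- tss; transcripts$tss_end[i] <- tss + 1L
      transcripts$cpa_start[i] <- cpa; transcripts$cpa_end[i] <- cpa + 1L
      transcripts$start[i] <- min(transcripts$start[i], tss, cpa)
      transcripts$end[i] <- max(transcripts$end[i], tss + 1L, cpa + 1L)
    }
  }
  transcripts
}

#' Score and decode a genome with a trained unified model
#'
#' @param genome a [Genome()].
#' @param model a `UnifiedModel` from [train_unified_model()].
#' @param threshold posterior threshold for transcript calling.
#' @param refine refine called TSS/CPA anchors against the score tracks
#'   with [refine_transcript_anchors()].
#' @return list with `init_track`, `term_track`, `posterior` and
#'   `transcripts`.
#' @export
decode_genome <- function(genome, model, threshold = 0.45, refine = TRUE) {
  init_track <- score_genome(genome, model$init_ensemble, model$init_scheme,
                             model$init_specs, model$motifs, model$stride)
  term_track <- score_genome(genome, model$term_ensemble, model$term_scheme,
                             model$term_specs, model$motifs, model$stride)
  obs <- um_observations(init_track, term_track)
  posterior <- posterior_decode(model$params, obs)
  transcripts <- predict_transcripts(posterior, threshold)
  if (refine)
    transcripts <- refine_transcript_anchors(transcripts, init_track,
                                             term_track)
  list(init_track = init_track, term_track = term_track,
       posterior = posterior, transcripts = transcripts)
}
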