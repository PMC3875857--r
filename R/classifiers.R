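#' Configuration for a leave-one-chromosome-out Random-Forest ensemble
#'
#' The canonical design holds out each chromosome in turn and trains
#' replicate forests on the remainder: 8 folds x 4 replicates x 50 trees =
#' 1600 trees per classifier.
#'
#' @param replicates_per_fold replicate forests per held-out chromosome.
#' @param trees_per_forest trees per forest.
#' @param held_out_chromosomes chromosomes to hold out (default: every
#'   chromosome present in the training data).
#' @param seed RNG seed; training is reproducible given the seed.
#' @return an `EnsembleConfig` list.
#' @export
ensemble_config <- function(replicates_per_fold = 4L, trees_per_forest = 50L,
                            held_out_chromosomes = NULL, seed = 1L) {
  stopifnot(replicates_per_fold >= 1, trees_per_forest >= 1)
  structure(list(replicates_per_fold = as.integer(replicates_per_fold),
                 trees_per_forest = as.integer(trees_per_forest),
                 held_out_chromosomes = held_out_chromosomes,
                 seed = as.integer(seed)),
            class = "EnsembleConfig")
}

#' Train a leave-one-chromosome-out Random-Forest ensemble
#'
#' One group of replicate forests is trained per held-out chromosome, each
#' seeing only examples from the other chromosomes. Class imbalance is
#' handled by a balanced bootstrap per tree (each tree samples equally many
#' positives and negatives). Prediction averages the class-probability
#' output of every forest.
#'
#' @param features numeric matrix, one row per example.
#' @param labels character/factor vector in `{positive, negative}`.
#' @param chroms chromosome of each example (the cross-validation grouping).
#' @param config an [ensemble_config()].
#' @param specs optional feature-spec data.frame carried as metadata.
#' @return a `TrainedEnsemble`.
#' @export
train_ensemble <- function(features, labels, chroms, config = ensemble_config(),
                           specs = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty example set")
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (any(is.na(labels))) stop("labels must be 'positive'/'negative'")
  chroms <- as.character(chroms)
  folds <- config$held_out_chromosomes
  if (is.null(folds)) folds <- sort(unique(chroms))
  if (length(folds) < 2) stop("need at least 2 chromosomes for held-out folds")
  set.seed(config$seed)
  fold_models <- list()
  for (f in folds) {
    idx <- chroms != f
    y <- droplevels(labels[idx])
    if (nlevels(y) < 2)
      stop("training fold holding out '", f, "' has a single class")
    y <- labels[idx]
    nmin <- min(table(y))
    reps <- lapply(seq_len(config$replicates_per_fold), function(r) {
      randomForest::randomForest(
        x = features[idx, , drop = FALSE], y = y,
        ntree = config$trees_per_forest,
        strata = y, sampsize = c(nmin, nmin),
        importance = TRUE)
    })
    fold_models[[f]] <- list(held_out = f, forests = reps)
  }
  neg_median <- apply(features[labels == "negative", , drop = FALSE], 2,
                      stats::median)
  structure(list(folds = fold_models, config = config, specs = specs,
                 feature_names = colnames(features),
                 neg_median = neg_median,
                 n_trees = length(folds) * config$replicates_per_fold *
                   config$trees_per_forest),
            class = "TrainedEnsemble")
}

#' @export
print.TrainedEnsemble <- function(x, ...) {
  cat(sprintf("TrainedEnsemble: %d fold(s) x %d replicate(s) x %d trees = %d trees\n",
              length(x$folds), x$config$replicates_per_fold,
              x$config$trees_per_forest, x$n_trees))
  invisible(x)
}

#' Score examples with a trained ensemble
#'
#' The classification score is the mean positive-class probability over all
#' forests of all folds, in `[0, 1]`.
#'
#' @param object a `TrainedEnsemble`.
#' @param features numeric matrix (or single named vector) matching the
#'   ensemble's feature names.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.TrainedEnsemble <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, 1,
    dimnames = list(NULL, names(features)))
  features <- as.matrix(features)
  if (!identical(colnames(features), object$feature_names)) {
    if (is.null(colnames(features)) ||
        !all(object$feature_names %in% colnames(features)))
      stop("feature names do not match the ensemble's feature spec")
    features <- features[, object$feature_names, drop = FALSE]
  }
  acc <- numeric(nrow(features))
  n <- 0L
  for (fold in object$folds) for (rf in fold$forests) {
    acc <- acc + stats::predict(rf, features, type = "prob")[, "positive"]
    n <- n + 1L
  }
  acc / n
}

# held-out scores: each example scored only by the fold that held out its
# chromosome (examples from unseen chromosomes use the full ensemble)
predict_heldout <- function(ensemble, features, chroms) {
  features <- as.matrix(features)
  out <- rep(NA_real_, nrow(features))
  chroms <- as.character(chroms)
  for (f in names(ensemble$folds)) {
    sel <- chroms == f
    if (!any(sel)) next
    acc <- numeric(sum(sel))
    for (rf in ensemble$folds[[f]]$forests)
      acc <- acc + stats::predict(rf, features[sel, , drop = FALSE],
                                  type = "prob")[, "positive"]
    out[sel] <- acc / length(ensemble$folds[[f]]$forests)
  }
  rest <- is.na(out)
  if (any(rest))
    out[rest] <- predict(ensemble, features[rest, , drop = FALSE])
  out
}

#' Train a regularized logistic-regression classifier
#'
#' A ridge-penalized logistic fit on standardized features, exposing the
#' same scoring contract as the forest ensemble (scores in `[0, 1]`).
#' Constant features are dropped with a warning.
#'
#' @inheritParams train_ensemble
#' @param lambda ridge penalty.
#' @return a `LogisticClassifier`.
#' @export
train_logistic <- function(features, labels, lambda = 1e-3) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  keep <- apply(features, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(features)[!keep], collapse = ", "))
    features <- features[, keep, drop = FALSE]
  }
  if (ncol(features) == 0) stop("no non-constant features")
  fit <- glmnet::glmnet(features, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  structure(list(fit = fit, feature_names = colnames(features),
                 lambda = lambda),
            class = "LogisticClassifier")
}

#' @rdname train_logistic
#' @param object a `LogisticClassifier`.
#' @param ... unused.
#' @export
predict.LogisticClassifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, 1,
    dimnames = list(NULL, names(features)))
  features <- as.matrix(features)[, object$feature_names, drop = FALSE]
  as.numeric(stats::predict(object$fit, features, type = "response"))
}

#' Importance-ordered greedy feature reduction
#'
#' Features are ranked by the ensemble's impurity-based importance (averaged
#' over folds) and added one at a time; a feature is retained only if it
#' improves AUROC on held-aside refinement examples by at least
#' `improvement_threshold`. The refinement examples must be disjoint from
#' the training examples.
#'
#' @param ensemble a `TrainedEnsemble` (supplies the importance order).
#' @param train_features,train_labels,train_chroms the training examples
#'   used to rebuild candidate models.
#' @param refine_features,refine_labels refinement examples.
#' @param improvement_threshold minimum AUROC gain to retain a feature.
#' @param config ensemble configuration for candidate rebuilds (defaults to
#'   a lighter single-replicate version of the ensemble's own).
#' @return character vector: the retained features in the order considered.
#' @export
reduce_features <- function(ensemble, train_features, train_labels,
                            train_chroms, refine_features, refine_labels,
                            improvement_threshold = 0.002, config = NULL) {
  if (nrow(as.matrix(refine_features)) == 0) stop("empty refinement set")
  if (is.null(config)) {
    config <- ensemble$config
    config$replicates_per_fold <- 1L
  }
  imp <- Reduce(`+`, lapply(ensemble$folds, function(fold)
    Reduce(`+`, lapply(fold$forests, function(rf)
      randomForest::importance(rf)[, "MeanDecreaseGini"]))))
  ord <- names(sort(imp, decreasing = TRUE))
  refine_labels <- as.character(refine_labels)
  pos <- refine_labels == "positive"
  retained <- character(0)
  best_auc <- 0.5                       # no features: random scoring
  for (feat in ord) {
    cand <- c(retained, feat)
    m <- train_ensemble(train_features[, cand, drop = FALSE], train_labels,
                        train_chroms, config)
    sc <- predict(m, as.matrix(refine_features)[, cand, drop = FALSE])
    auc <- auroc(sc[pos], sc[!pos])
    if (auc - best_auc >= improvement_threshold) {
      retained <- cand
      best_auc <- auc
    }
  }
  retained
}

#' Per-base, per-strand classifier score tracks
#'
#' Scores every `stride`-th anchor base of every chromosome on both strands
#' and stores the score at the anchor; bases between anchors carry the last
#' anchor's score, and edge bases whose feature window leaves the
#' chromosome are masked to the track's minimum.
#'
#' @param genome a [Genome()].
#' @param ensemble a `TrainedEnsemble` (or `LogisticClassifier`).
#' @param scheme the [bin_scheme()] the ensemble was trained with.
#' @param specs the feature specs the ensemble was trained with.
#' @param motifs named list of [motif_model()]s.
#' @param stride anchor spacing in bp (1 = every base).
#' @return a `ScoreTrack`: list with `plus` and `minus`, each a named list
#'   of per-chromosome numeric vectors in `[0, 1]`.
#' @export
score_genome <- function(genome, ensemble, scheme, specs, motifs, stride = 10L) {
  stopifnot(stride >= 1)
  len <- seq_lengths(genome)
  plus <- minus <- list()
  for (nm in names(len)) {
    L <- len[[nm]]
    for (st in c("+", "-")) {
      if (st == "+") {
        first <- -scheme$window_start
        last <- L - scheme$window_end
      } else {
        first <- scheme$window_end - 1L
        last <- L - 1L + scheme$window_start
      }
      if (last < first) stop("chromosome '", nm, "' shorter than the feature window")
      anchors <- seq(first, last, by = stride)
      an <- data.frame(chrom = nm, pos = anchors, strand = st)
      fx <- extract_feature_matrix(genome, an, scheme, specs, motifs)
      sc <- predict(ensemble, fx)
      track <- rep(min(sc), L)           # edges masked to the track minimum
      fill <- rep(sc, each = stride)[seq_len(last - first + 1L)]
      track[(first + 1L):(last + 1L)] <- fill
      if (st == "+") plus[[nm]] <- track else minus[[nm]] <- track
    }
  }
  structure(list(plus = plus, minus = minus, stride = stride),
            class = "ScoreTrack")
}

#' Export a ScoreTrack as bedGraph (one file per strand)
#' @param track a `ScoreTrack`.
#' @param prefix output path prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @export
write_score_track <- function(track, prefix) {
  for (st in c("plus", "minus")) {
    grl <- lapply(names(track[[st]]), function(nm) {
      v <- track[[st]][[nm]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      GenomicRanges::GRanges(nm,
        IRanges::IRanges(ends - r$lengths + 1L, ends), score = r$values)
    })
    gr <- do.call(c, grl)
    rtracklayer::export(gr, sprintf("%s.%s.bedGraph", prefix, st),
                        format = "bedGraph")
  }
  invisible(prefix)
}

#' Does a score depend on a group of features?
#'
#' The group is neutralized to the negative-class median values seen in
#' training and the example re-scored; the example depends on the group if
#' the score drops by at least `threshold` (default 0.1).
#'
#' @param ensemble a `TrainedEnsemble`.
#' @param x named feature vector (or 1-row matrix).
#' @param group feature names to neutralize.
#' @param threshold minimum score drop to call dependence.
#' @return list with `dependent` (logical), `delta` (score drop), `score`
#'   and `neutralized_score`.
#' @export
feature_dependence <- function(ensemble, x, group, threshold = 0.1) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)[, ensemble$feature_names, drop = FALSE]
  if (!all(group %in% ensemble$feature_names))
    stop("unknown feature(s) in group: ",
         paste(setdiff(group, ensemble$feature_names), collapse = ", "))
  x0 <- x
  x0[, group] <- rep(ensemble$neg_median[group], each = nrow(x0))
  s <- predict(ensemble, x)
  s0 <- predict(ensemble, x0)
  delta <- s - s0
  list(dependent = delta >= threshold, delta = delta,
       score = s, neutralized_score = s0)
}

#' Persist / restore a trained ensemble
#'
#' The container embeds a format version and the feature spec so scoring
#' inputs can be validated on reload.
#'
#' @param ensemble a `TrainedEnsemble`.
#' @param path file path.
#' @return `load_ensemble` returns the `TrainedEnsemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(list(format = "txunify-ensemble-1", ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "txunify-ensemble-1"))
    stop("not a txunify ensemble container")
  obj$ensemble
}
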