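#' Area under the ROC curve by pair counting
#'
#' Fraction of (positive, negative) score pairs where the positive scores
#' higher, counting ties as one half; identical to the trapezoidal area
#' under the ROC curve.
#'
#' @param pos_scores,neg_scores score vectors for the two classes.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("both classes must be non-empty")
  r <- rank(c(pos_scores, neg_scores))    # midranks handle ties as 0.5
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#' @param scores numeric scores.
#' @param labels logical (or `positive`/`negative`) class labels.
#' @return data.frame of `threshold`, `tpr`, `fpr`, ordered for plotting.
#' @export
roc_curve <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.character(labels) == "positive"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    c(tpr = mean(scores[labels] >= t), fpr = mean(scores[!labels] >= t))
  }, numeric(2)))
  data.frame(threshold = thr, tpr = pts[, "tpr"], fpr = pts[, "fpr"])
}

# normalize a prediction/truth argument into list(plus=, minus=) of
# per-chromosome logical vectors
as_stranded_mask <- function(x) {
  if (is.list(x) && all(c("plus", "minus") %in% names(x))) return(x)
  if (inherits(x, "StateMap")) return(transcribed_mask(x))
  stop("expected a StateMap or list(plus = , minus = ) of logical vectors")
}

# per-base distance-to-nearest-TRUE dilation by `tol` bases
dilate_mask <- function(v, tol) {
  if (tol <= 0 || !any(v)) return(v)
  r <- IRanges::IRanges(v)          # ranges of TRUE runs
  r <- IRanges::restrict(r + tol, start = 1L, end = length(v))
  as.vector(IRanges::coverage(r, width = length(v)) > 0)
}

#' Per-base precision and recall with positional tolerance
#'
#' Recall is the fraction of truly transcribed bases predicted; precision
#' is the fraction of predicted bases lying within `tolerance_bp` of a true
#' transcript on the same strand (the tolerance can optionally be applied
#' to recall as well). With an empty prediction, precision is `NA` and
#' recall 0.
#'
#' @param predicted,truth [StateMap()]s or `list(plus=, minus=)` of
#'   per-chromosome logical vectors.
#' @param tolerance_bp positional tolerance in bp.
#' @param tolerance_on apply the tolerance to `"precision"` (default) or
#'   `"both"`.
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`.
#' @export
pr_per_base <- function(predicted, truth, tolerance_bp = 0L,
                        tolerance_on = c("precision", "both")) {
  tolerance_on <- match.arg(tolerance_on)
  predicted <- as_stranded_mask(predicted)
  truth <- as_stranded_mask(truth)
  tp_prec <- np <- tp_rec <- nt <- 0
  for (st in c("plus", "minus")) for (nm in names(truth[[st]])) {
    p <- predicted[[st]][[nm]]; t <- truth[[st]][[nm]]
    stopifnot(length(p) == length(t))
    tdil <- dilate_mask(t, tolerance_bp)
    tp_prec <- tp_prec + sum(p & tdil)
    np <- np + sum(p)
    pdil <- if (tolerance_on == "both") dilate_mask(p, tolerance_bp) else p
    tp_rec <- tp_rec + sum(t & pdil)
    nt <- nt + sum(t)
  }
  list(precision = if (np > 0) tp_prec / np else NA_real_,
       recall = if (nt > 0) tp_rec / nt else NA_real_,
       n_predicted = np, n_true = nt)
}

#' Expected precision/recall of independent random guessing
#'
#' Simulates predictions that label each base transcribed independently
#' with probability `p` against ground truth that is transcribed with
#' probability `truth_fraction`; when `p` equals the truth fraction both
#' precision and recall converge to that fraction.
#'
#' @param p prediction probability.
#' @param truth_fraction transcribed fraction of the ground truth.
#' @param n bases per replicate.
#' @param replicates number of replicates averaged.
#' @return list with mean `precision` and `recall` over replicates.
#' @export
random_baseline_pr <- function(p, truth_fraction = p, n = 1e6L,
                               replicates = 20L) {
  stopifnot(p > 0, p < 1)
  prec <- rec <- numeric(replicates)
  for (r in seq_len(replicates)) {
    truth <- stats::runif(n) < truth_fraction
    pred <- stats::runif(n) < p
    prec[r] <- sum(pred & truth) / sum(pred)
    rec[r] <- sum(pred & truth) / sum(truth)
  }
  list(precision = mean(prec), recall = mean(rec))
}

#' Transcript-level matching with end offsets
#'
#' Greedy one-to-one matching: a predicted and a true transcript match if
#' they share a strand and both `|delta TSS|` and `|delta CPA|` are within
#' `end_offset_bp`; candidate pairs are consumed in order of summed end
#' distance.
#'
#' @param predicted,truth [transcript_annotations()] tables.
#' @param end_offset_bp allowed offset for TSS and CPA positions.
#' @return list with `precision`, `recall`, and the `matching` data.frame.
#' @export
transcript_match <- function(predicted, truth, end_offset_bp = 200L) {
  pairs <- list()
  for (i in seq_len(nrow(predicted))) for (j in seq_len(nrow(truth))) {
    if (predicted$chrom[i] != truth$chrom[j] ||
        predicted$strand[i] != truth$strand[j]) next
    dt <- abs(predicted$tss_pos[i] - truth$tss_pos[j])
    dc <- abs(predicted$cpa_pos[i] - truth$cpa_pos[j])
    if (dt <= end_offset_bp && dc <= end_offset_bp)
      pairs[[length(pairs) + 1L]] <- c(i, j, dt + dc)
  }
  used_p <- logical(nrow(predicted)); used_t <- logical(nrow(truth))
  matching <- list()
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    m <- m[order(m[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1]; j <- m[r, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- used_t[j] <- TRUE
      matching[[length(matching) + 1L]] <- data.frame(
        predicted = predicted$id[i], true = truth$id[j], distance = m[r, 3])
    }
  }
  nm <- length(matching)
  list(precision = if (nrow(predicted)) nm / nrow(predicted) else NA_real_,
       recall = if (nrow(truth)) nm / nrow(truth) else NA_real_,
       matching = if (nm) do.call(rbind, matching)
                  else data.frame(predicted = character(), true = character(),
                                  distance = numeric()))
}

#' Cross-correlation between strand score tracks over an offset scan
#'
#' Pearson correlation of `track_plus[t]` with `track_minus[t + offset]`
#' over the overlapping span, for each offset in the scan range; returns
#' the full profile and the offset of maximal correlation.
#'
#' @param track_plus,track_minus equal-length numeric vectors.
#' @param offset_range integer offsets to scan (default -500:500).
#' @return list with `best_offset`, `best_correlation`, and the `profile`
#'   data.frame.
#' @export
strand_cross_correlation <- function(track_plus, track_minus,
                                     offset_range = -500:500) {
  L <- length(track_plus)
  stopifnot(length(track_minus) == L)
  cors <- vapply(offset_range, function(k) {
    lo <- max(1L, 1L - k); hi <- min(L, L - k)
    if (hi - lo < 1) return(NA_real_)
    i <- lo:hi
    suppressWarnings(stats::cor(track_plus[i], track_minus[i + k]))
  }, numeric(1))
  if (all(is.na(cors))) stop("no offset with an overlap of at least 2 bases")
  best <- which.max(cors)
  list(best_offset = offset_range[best], best_correlation = cors[best],
       profile = data.frame(offset = offset_range, correlation = cors))
}

#' True- and false-positive rates at a score threshold
#'
#' Predicts positive where `score >= threshold`.
#'
#' @param scores numeric scores.
#' @param labels logical or `positive`/`negative` labels.
#' @param score_threshold decision threshold.
#' @return list with `tpr` and `fpr`.
#' @export
threshold_rates <- function(scores, labels, score_threshold) {
  if (!is.logical(labels)) labels <- as.character(labels) == "positive"
  if (all(labels) || !any(labels)) stop("both classes required")
  list(tpr = mean(scores[labels] >= score_threshold),
       fpr = mean(scores[!labels] >= score_threshold))
}

#' Rank-sum test of expression changes between dependence groups
#'
#' Two-sided Wilcoxon rank-sum test on absolute expression changes of genes
#' whose promoters are predicted to depend on a factor versus those
#' predicted independent.
#'
#' @param dependent_changes,independent_changes expression changes of the
#'   two groups.
#' @return list with `statistic` and `p_value`.
#' @export
dependence_expression_test <- function(dependent_changes,
                                       independent_changes) {
  if (!length(dependent_changes) || !length(independent_changes))
    stop("both groups must be non-empty")
  w <- stats::wilcox.test(abs(dependent_changes), abs(independent_changes),
                          alternative = "two.sided", exact = FALSE)
  list(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Assemble a tabular evaluation report
#' @param metric metric name(s).
#' @param value metric value(s).
#' @param n problem size(s).
#' @param settings free-text settings description(s).
#' @return data.frame with one row per metric.
#' @export
evaluation_report <- function(metric, value, n = NA_integer_, settings = "") {
  data.frame(metric = metric, value = value, n = n, settings = settings,
             stringsAsFactors = FALSE)
}
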