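# Identification and verification metrics: correct classification rate,
# ROC (false-accept vs false-reject over a threshold sweep), equal error
# rate, and specificity/sensitivity sweeps for walking-vs-other screening.

#' Correct classification rate
#'
#' Fraction of probes whose predicted class equals the true class
#' (TP / (TP + FP) over the probe set); the misclassification rate is its
#' complement.
#'
#' @param predicted predicted labels, or a score-table data frame with
#'   columns `predicted_class` and `true_class` (e.g. from
#'   [predict.emsm()][emsm()] with `type = "table"`).
#' @param truth true labels (ignored for the data-frame form).
#' @return rate in \[0, 1\].
#' @export
ccr <- function(predicted, truth = NULL) {
  if (is.data.frame(predicted)) {
    truth <- predicted$true_class
    predicted <- predicted$predicted_class
  }
  if (length(predicted) == 0L) stop("empty score table", call. = FALSE)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  mean(predicted == truth)
}

roc_thresholds <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

#' ROC curve from genuine and impostor scores
#'
#' Thresholds sweep the midpoints between consecutive sorted unique scores
#' plus infinite endpoints. At each threshold the false-accept rate is the
#' fraction of impostor scores >= threshold and the false-reject rate the
#' fraction of genuine scores < threshold.
#'
#' @param genuine_scores scores of true-class (genuine) comparisons.
#' @param impostor_scores scores of cross-class (impostor) comparisons.
#' @return a data frame with columns `threshold`, `far`, `frr`, of class
#'   `"roc_curve"`.
#' @export
roc_curve <- function(genuine_scores, impostor_scores) {
  if (length(genuine_scores) == 0L || length(impostor_scores) == 0L)
    stop("genuine and impostor score lists must be non-empty", call. = FALSE)
  thr <- roc_thresholds(c(genuine_scores, impostor_scores))
  far <- vapply(thr, function(t) mean(impostor_scores >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine_scores < t), numeric(1))
  structure(data.frame(threshold = thr, far = far, frr = frr),
            class = c("roc_curve", "data.frame"))
}

#' Equal error rate of an ROC curve
#'
#' Linear interpolation, in (FAR, FRR) space, to the crossing FAR = FRR. The
#' interpolation is parameterized by the curve points rather than by the
#' threshold values, so the EER is exactly invariant under strictly monotone
#' transformations of the scores.
#'
#' @param curve a [roc_curve()] (or any data frame with `far` and `frr`
#'   columns), or genuine scores when `impostor` is supplied.
#' @param impostor optional impostor scores; when given, the curve is built
#'   internally.
#' @return the equal error rate in \[0, 1\].
#' @export
eer <- function(curve, impostor = NULL) {
  if (!is.null(impostor)) curve <- roc_curve(curve, impostor)
  d <- curve$far - curve$frr
  if (any(d == 0)) {
    i <- which(d == 0)[1]
    return(curve$far[i])
  }
  i <- which(d[-1] * d[-length(d)] < 0)[1]
  if (is.na(i)) return(min(pmax(curve$far, curve$frr)))
  df1 <- curve$far[i] - curve$frr[i]
  df2 <- curve$far[i + 1] - curve$frr[i + 1]
  t <- df1 / (df1 - df2)
  curve$far[i] + t * (curve$far[i + 1] - curve$far[i])
}

#' Specificity / sensitivity threshold sweep
#'
#' Screens "walking" (positive) against "not walking" (negative) scores: a
#' sample is accepted as walking when its score is at or above the threshold.
#' Reports, per threshold, the specificity `TN / (TN + FP)` together with
#' both the false-negative rate `FN / (FN + TP)` and the conventional
#' sensitivity `TP / (TP + FN)` (their sum is one), clearly labelled.
#'
#' @param walking_scores scores of true walking samples.
#' @param notwalking_scores scores of non-walking samples.
#' @return a data frame with columns `threshold`, `specificity`,
#'   `false_negative_rate`, `sensitivity`.
#' @export
spec_sens_sweep <- function(walking_scores, notwalking_scores) {
  if (length(walking_scores) == 0L || length(notwalking_scores) == 0L)
    stop("score lists must be non-empty", call. = FALSE)
  thr <- roc_thresholds(c(walking_scores, notwalking_scores))
  out <- lapply(thr, function(t) {
    tp <- sum(walking_scores >= t); fn <- sum(walking_scores < t)
    tn <- sum(notwalking_scores < t); fp <- sum(notwalking_scores >= t)
    data.frame(threshold = t,
               specificity = tn / (tn + fp),
               false_negative_rate = fn / (fn + tp),
               sensitivity = tp / (tp + fn))
  })
  do.call(rbind, out)
}

#' Build a verification score table from per-class scores
#'
#' One row per probe: the genuine score (score of the true class) and the
#' best impostor score (maximum over all other classes).
#'
#' @param scores probe x class score matrix (named columns).
#' @param truth true class per probe.
#' @param predicted predicted class per probe.
#' @param probe_id optional probe identifiers.
#' @return a data frame with columns `probe_id`, `true_class`,
#'   `predicted_class`, `genuine_score`, `best_impostor_score`.
#' @export
score_table <- function(scores, truth, predicted, probe_id = NULL) {
  stopifnot(nrow(scores) == length(truth), length(truth) == length(predicted))
  if (is.null(probe_id)) probe_id <- sprintf("P%03d", seq_along(truth))
  genuine <- vapply(seq_along(truth),
                    function(i) scores[i, truth[i]], numeric(1))
  best_imp <- vapply(seq_along(truth), function(i)
    max(scores[i, setdiff(colnames(scores), truth[i])]), numeric(1))
  data.frame(probe_id = probe_id, true_class = truth,
             predicted_class = predicted, genuine_score = genuine,
             best_impostor_score = best_imp, stringsAsFactors = FALSE)
}
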