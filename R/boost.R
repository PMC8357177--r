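# AdaBoost selection and fusion of the weak classifiers indexed by
# (canonical-angle order r, gallery dim d^G, probe dim d^P, rotation theta).
# Each boosting round picks the combination with the smallest weighted
# training error, weights it by its confidence alpha = 0.5*log((1-eps)/eps),
# and reweights the training probes multiplicatively.

#' Initial AdaBoost weights
#'
#' Uniform over the training probes, summing to one.
#' @param n number of training probes (>= 1).
#' @return numeric weight vector.
#' @export
init_weights <- function(n) {
  if (n < 1) stop("need at least one training probe", call. = FALSE)
  rep(1 / n, n)
}

#' Weighted training error of a weak classifier
#'
#' `eps = sum of the weights of misclassified probes`.
#' @param predictions,truth label vectors of equal length.
#' @param weights weight vector of the same length.
#' @return the weighted error in \[0, 1\].
#' @export
weighted_error <- function(predictions, truth, weights) {
  if (length(predictions) != length(truth) ||
      length(truth) != length(weights))
    stop("predictions, truth and weights must have equal length",
         call. = FALSE)
  sum(weights[predictions != truth])
}

#' AdaBoost confidence of a weak classifier
#'
#' `alpha = 0.5 * log((1 - eps) / eps)`. The formula diverges at eps = 0
#' (perfect weak classifiers do occur on separable data) and eps = 1, so eps
#' is clamped to `[1/(2*n_train), 1 - 1/(2*n_train)]` before the log; a
#' message notes when clamping fires.
#'
#' @param epsilon weighted error in \[0, 1\].
#' @param n_train number of training probes defining the clamp.
#' @return finite confidence alpha.
#' @export
confidence <- function(epsilon, n_train) {
  stopifnot(epsilon >= 0, epsilon <= 1, n_train >= 1)
  lo <- 1 / (2 * n_train)
  eps <- min(max(epsilon, lo), 1 - lo)
  if (eps != epsilon)
    message(sprintf("confidence: eps = %g clamped to %g", epsilon, eps))
  0.5 * log((1 - eps) / eps)
}

#' Multiplicative AdaBoost weight update
#'
#' `D(i) <- D(i) * exp(-alpha * h'(i)) / Z` with `h'(i) = +1` when probe i was
#' classified correctly and `-1` otherwise; `Z` renormalizes the weights to
#' sum to one.
#'
#' @param weights current weight vector.
#' @param alpha round confidence.
#' @param correct_flags logical vector, `TRUE` where the round's weak
#'   classifier was correct.
#' @return updated weight vector summing to one.
#' @export
update_weights <- function(weights, alpha, correct_flags) {
  if (length(weights) != length(correct_flags))
    stop("weights and correct_flags must have equal length", call. = FALSE)
  if (all(weights == 0)) stop("all-zero weights", call. = FALSE)
  w <- weights * exp(-alpha * ifelse(correct_flags, 1, -1))
  w / sum(w)
}

combo_grid <- function(grids) {
  # enumeration order fixes deterministic tie-breaking: r fastest, theta slowest
  expand.grid(r = grids$r, dg = grids$dg, dp = grids$dp, theta = grids$theta,
              KEEP.OUT.ATTRS = FALSE)
}

weak_prediction_matrix <- function(tensors) {
  # rows = parameter combinations (combo_grid order), cols = training probes
  g <- attr(tensors[[1]], "grids")
  classes <- g$classes
  vapply(tensors, function(tn) {
    m <- matrix(as.numeric(tn), nrow = length(classes))
    classes[max.col(t(m), ties.method = "first")]
  }, character(prod(vapply(g[c("r", "dg", "dp", "theta")], length, 1L))))
}

#' Fit the boosted strong classifier
#'
#' AdaBoost over the full Cartesian pool of weak classifiers
#' `(r, d_g, d_p, theta)`: every round evaluates the weighted error of every
#' combination, selects the minimum (ties broken by grid order), computes its
#' confidence and reweights the training probes. The same combination may be
#' selected in several rounds. Boosting stops early if no combination beats
#' chance (`min eps >= 0.5`).
#'
#' @param tensors list of [similarity_tensor()]s, one per training probe, all
#'   on the same parameter grid.
#' @param truth true class labels of the training probes.
#' @param T maximum number of boosting rounds.
#' @return an object of class `"strong_classifier"`: a data frame `rounds`
#'   with columns `t, r, dg, dp, theta, alpha, epsilon`, the `class_set`, and
#'   the training-CCR trajectory `train_ccr`.
#' @export
fit_boost <- function(tensors, truth, T = 30L) {
  stopifnot(is.list(tensors), length(tensors) == length(truth))
  if (length(unique(truth)) < 2L)
    stop("need >= 2 classes among the training labels", call. = FALSE)
  g <- attr(tensors[[1]], "grids")
  for (tn in tensors[-1])
    if (!identical(attr(tn, "grids"), g))
      stop("parameter grid mismatch across tensors", call. = FALSE)
  combos <- combo_grid(g)
  pred <- weak_prediction_matrix(tensors)     # ncombo x nprobe
  n <- length(truth)
  correct <- pred == matrix(truth, nrow(pred), n, byrow = TRUE)
  D <- init_weights(n)
  rounds <- NULL
  scores <- matrix(0, n, length(g$classes), dimnames = list(NULL, g$classes))
  train_ccr <- numeric(0)
  for (t in seq_len(T)) {
    eps_all <- as.numeric((!correct) %*% D)
    j <- which.min(eps_all)                   # first minimum = grid order
    if (eps_all[j] >= 0.5) {
      if (is.null(rounds))
        stop("no weak classifier beats chance on the training set",
             call. = FALSE)
      break
    }
    alpha <- suppressMessages(confidence(eps_all[j], n))
    rounds <- rbind(rounds, data.frame(
      t = t, r = combos$r[j], dg = combos$dg[j], dp = combos$dp[j],
      theta = combos$theta[j], alpha = alpha, epsilon = eps_all[j]))
    D <- update_weights(D, alpha, correct[j, ])
    for (i in seq_len(n)) scores[i, pred[j, i]] <- scores[i, pred[j, i]] + alpha
    H_pred <- g$classes[max.col(scores, ties.method = "first")]
    train_ccr <- c(train_ccr, mean(H_pred == truth))
  }
  structure(list(rounds = rounds, class_set = g$classes, grids = g,
                 train_ccr = train_ccr),
            class = "strong_classifier")
}

#' @export
print.strong_classifier <- function(x, ...) {
  cat(sprintf("Boosted strong classifier: %d rounds over %d classes; final training CCR %.3f\n",
              nrow(x$rounds), length(x$class_set),
              x$train_ccr[length(x$train_ccr)]))
  invisible(x)
}

#' Classify a probe with the strong classifier
#'
#' Alpha-weighted vote: `score_c = sum_t alpha_t * [h_t(probe) = c]`, decision
#' `argmax_c score_c`, ties broken towards the lowest class id.
#'
#' @param H a [fit_boost()] result.
#' @param tensor the probe's [similarity_tensor()] covering all selected
#'   parameter combinations.
#' @return a list with `label` and the per-class `scores` vector.
#' @export
strong_classify <- function(H, tensor) {
  stopifnot(inherits(H, "strong_classifier"))
  g <- attr(tensor, "grids")
  scores <- stats::setNames(numeric(length(g$classes)), g$classes)
  for (k in seq_len(nrow(H$rounds))) {
    p <- H$rounds[k, c("r", "dg", "dp", "theta")]
    lab <- suppressMessages(weak_classify(tensor, p))
    scores[lab] <- scores[lab] + H$rounds$alpha[k]
  }
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    best <- best[order(names(scores)[best])]
    message("strong_classify: tie broken towards class ",
            names(scores)[best[1]])
  }
  list(label = names(scores)[best[1]], scores = scores)
}

#' Save / load a strong classifier as JSON
#'
#' @param H a `"strong_classifier"`.
#' @param path file path.
#' @return `read_strong_classifier` returns the restored classifier.
#' @export
write_strong_classifier <- function(H, path) {
  stopifnot(inherits(H, "strong_classifier"))
  jsonlite::write_json(list(rounds = H$rounds, class_set = H$class_set,
                            train_ccr = H$train_ccr),
                       path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_strong_classifier
#' @export
read_strong_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(rounds = as.data.frame(x$rounds),
                 class_set = as.character(x$class_set),
                 train_ccr = as.numeric(x$train_ccr)),
            class = "strong_classifier")
}
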