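#' Control parameters for the enhanced MSM
#'
#' Bundles every tunable of the pipeline. Defaults follow the trained
#' operating point of the method: rotation bank of +/-20 degrees in 2-degree
#' steps, 2D-PCA dimension K = 16, subspace-dimensionality axes 10..50 in
#' steps of 10, and up to 18 canonical angles. Because the number of
#' canonical angles between d_g- and d_p-dimensional subspaces is at most
#' `min(d_g, d_p)`, the effective R is capped at the smallest axis value (a
#' message notes when the cap bites).
#'
#' @param theta_max,fine_step fine rotation range/step in degrees.
#' @param coarse_step,coarse_max optional coarse rotation wings.
#' @param K 2D-PCA dimension (`NULL` disables 2D-PCA: classic MSM features).
#' @param DG,DP maximal gallery/probe subspace dimensionalities.
#' @param dg_axis,dp_axis dimensionality axes of the similarity tensor.
#' @param R requested number of canonical angles.
#' @param T maximum boosting rounds.
#' @param canvas silhouette frame size `c(height, width)`.
#' @return a list of class `"emsm_control"`.
#' @export
emsm_control <- function(theta_max = 20, fine_step = 2, coarse_step = NULL,
                         coarse_max = NULL, K = 16L, DG = 50L, DP = 50L,
                         dg_axis = seq(10L, 50L, 10L),
                         dp_axis = seq(10L, 50L, 10L), R = 18L, T = 30L,
                         canvas = c(64L, 44L)) {
  r_eff <- min(R, min(dg_axis), min(dp_axis))
  if (r_eff < R)
    message(sprintf(
      "R = %d exceeds the smallest subspace axis; using R = %d", R, r_eff))
  structure(list(grid = build_rotation_grid(theta_max, fine_step,
                                            coarse_step, coarse_max),
                 K = K, DG = DG, DP = DP, dg_axis = dg_axis,
                 dp_axis = dp_axis, R = r_eff, T = T, canvas = canvas),
            class = "emsm_control")
}

#' Fit a boosted enhanced-MSM gait classifier
#'
#' Builds the per-(class, rotation-angle) gallery model (2D-PCA bases and
#' subspaces), computes the canonical-angle similarity tensor of every
#' training probe, and runs AdaBoost over the weak-classifier pool indexed by
#' (canonical-angle order, gallery dimension, probe dimension, rotation
#' angle).
#'
#' @param gallery named list mapping class id to a [gait_sequence()] (or a
#'   list of sequences per class, pooled).
#' @param probe list of training-probe [gait_sequence()]s. Training probes
#'   should differ from the enrolment condition (e.g. another walking speed)
#'   so boosting selects speed-robust parameter combinations.
#' @param labels true class of each training probe; defaults to the
#'   sequences' own `class_label`s.
#' @param control an [emsm_control()].
#' @return an object of class `"emsm"` with the gallery model, the boosted
#'   `"strong_classifier"`, the training tensors' score table, and the
#'   control. Supports `print`, `summary`, `coef`, `plot`, and `predict`.
#' @seealso [predict.emsm()], [plain_msm()]
#' @export
emsm <- function(gallery, probe, labels = NULL, control = emsm_control()) {
  stopifnot(inherits(control, "emsm_control"))
  if (inherits(probe, "gait_sequence")) probe <- list(probe)
  if (is.null(labels))
    labels <- vapply(probe, function(s) as.character(s$class_label),
                     character(1))
  model <- build_gallery_model(gallery, control$grid, K = control$K,
                               DG = control$DG)
  tensors <- lapply(seq_along(probe), function(i)
    similarity_tensor(probe = probe[[i]], model = model, DP = control$DP,
                      R = control$R, dg_axis = control$dg_axis,
                      dp_axis = control$dp_axis,
                      probe_id = sprintf("train%03d", i)))
  H <- fit_boost(tensors, labels, T = control$T)
  structure(list(model = model, classifier = H, control = control,
                 train_labels = labels, n_train = length(probe),
                 call = match.call()),
            class = "emsm")
}

#' @export
print.emsm <- function(x, ...) {
  cat("Boosted 2D-PCA rotated mutual subspace model\n")
  cat(sprintf("  classes: %d; training probes: %d\n",
              length(x$model$classes), x$n_train))
  cat(sprintf("  rotation bank: %d angles; K = %s; dims %s x %s; R = %d\n",
              length(x$model$grid$angles),
              if (is.null(x$control$K)) "identity" else x$control$K,
              paste(range(x$control$dg_axis), collapse = ".."),
              paste(range(x$control$dp_axis), collapse = ".."),
              x$control$R))
  cat(sprintf("  boosting: %d rounds, final training CCR %.3f\n",
              nrow(x$classifier$rounds),
              x$classifier$train_ccr[length(x$classifier$train_ccr)]))
  invisible(x)
}

#' @export
summary.emsm <- function(object, ...) {
  print(object)
  cat("\nSelected weak classifiers per round:\n")
  print(object$classifier$rounds, row.names = FALSE)
  invisible(object$classifier$rounds)
}

#' @export
coef.emsm <- function(object, ...) object$classifier$rounds

#' @export
plot.emsm <- function(x, ...) {
  r <- x$classifier$rounds
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(r$t, r$epsilon, type = "b", xlab = "boosting round",
                 ylab = expression(epsilon[t]),
                 main = "Weighted error of selected weak classifier", ...)
  graphics::plot(r$t, x$classifier$train_ccr, type = "b",
                 xlab = "boosting round", ylab = "training CCR", ylim = c(0, 1),
                 main = "Training CCR of the strong classifier", ...)
  invisible(x)
}

#' Classify probes with a fitted enhanced-MSM model
#'
#' @param object an [emsm()] fit.
#' @param newdata a [gait_sequence()] or list of them.
#' @param type `"class"` (labels), `"scores"` (per-class alpha-vote matrix),
#'   `"table"` (verification score table, see [score_table()]), or
#'   `"tensor"` (the raw similarity tensors).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.emsm <- function(object, newdata,
                         type = c("class", "scores", "table", "tensor"),
                         ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gait_sequence")) newdata <- list(newdata)
  ctl <- object$control
  tensors <- lapply(seq_along(newdata), function(i)
    similarity_tensor(probe = newdata[[i]], model = object$model,
                      DP = ctl$DP, R = ctl$R, dg_axis = ctl$dg_axis,
                      dp_axis = ctl$dp_axis, probe_id = i))
  if (type == "tensor") return(tensors)
  res <- lapply(tensors, function(tn)
    suppressMessages(strong_classify(object$classifier, tn)))
  labels <- vapply(res, `[[`, character(1), "label")
  scores <- do.call(rbind, lapply(res, `[[`, "scores"))
  if (type == "class") return(labels)
  if (type == "scores") return(scores)
  truth <- vapply(newdata, function(s)
    if (is.null(s$class_label)) NA_character_ else as.character(s$class_label),
    character(1))
  score_table(scores, truth, labels,
              probe_id = names(newdata) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
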