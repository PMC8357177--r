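# Rotated-image bank and the end-to-end similarity tensor
# s_c(r, d^G, d^P, theta): for every rotation angle the frames are rotated,
# a per-gallery-class 2D-PCA basis is fitted on the rotated gallery frames,
# gallery and probe frames are projected with it, flattened, modelled as
# subspaces, and compared through canonical angles. Rotating the image is
# equivalent to scanning it with rotated parallel lines, so each angle yields
# a genuinely different 2D-PCA feature set.

#' Rotate a silhouette frame about its centre
#'
#' The frame is zero-padded to the square of side `ceiling(sqrt(A^2 + B^2))`
#' (so no rotation can push foreground off the canvas and all angles share an
#' output size) and rotated in-plane with nearest-neighbour interpolation,
#' which preserves binarity; background fill is 0.
#'
#' @param frame a binary matrix.
#' @param theta rotation angle in degrees (counter-clockwise).
#' @param interpolation `"nearest"` (default, binary-preserving) or
#'   `"bilinear"` followed by a 0.5 threshold.
#' @return a binary S x S matrix, S independent of `theta`.
#' @export
rotate_frame <- function(frame, theta,
                         interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  A <- nrow(frame); B <- ncol(frame)
  S <- ceiling(sqrt(A^2 + B^2))
  padded <- matrix(0, S, S)
  r0 <- (S - A) %/% 2L; c0 <- (S - B) %/% 2L
  padded[(r0 + 1L):(r0 + A), (c0 + 1L):(c0 + B)] <- frame
  if (theta %% 360 == 0) return(padded)
  ctr <- (S + 1) / 2
  th <- theta * pi / 180
  # inverse map output (row, col) back to source coordinates
  rows <- matrix(seq_len(S), S, S) - ctr
  cols <- matrix(seq_len(S), S, S, byrow = TRUE) - ctr
  # image row axis points down, so a CCW rotation of content corresponds to
  # the standard rotation matrix applied in (col, -row) coordinates
  src_c <- cos(th) * cols + sin(th) * (-rows)
  src_r <- -(-sin(th) * cols + cos(th) * (-rows))
  if (interpolation == "nearest") {
    si <- round(src_r + ctr); sj <- round(src_c + ctr)
    ok <- si >= 1 & si <= S & sj >= 1 & sj <= S
    out <- matrix(0, S, S)
    out[ok] <- padded[cbind(si[ok], sj[ok])]
  } else {
    fi <- src_r + ctr; fj <- src_c + ctr
    i0 <- floor(fi); j0 <- floor(fj)
    wi <- fi - i0; wj <- fj - j0
    val <- matrix(0, S, S)
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      ok <- ii >= 1 & ii <= S & jj >= 1 & jj <= S
      w <- (if (di == 0) 1 - wi else wi) * (if (dj == 0) 1 - wj else wj)
      add <- matrix(0, S, S)
      add[ok] <- padded[cbind(ii[ok], jj[ok])] * w[ok]
      val <- val + add
    }
    out <- (val >= 0.5) * 1
  }
  out
}

#' Build the bank of rotation angles
#'
#' A fine grid `-theta_max ... theta_max` in steps of `fine_step`, optionally
#' extended by coarse wings `(theta_max, coarse_max]` (and mirrored) in steps
#' of `coarse_step`. Always contains 0, sorted ascending, no duplicates.
#'
#' @param theta_max fine-range half-width in degrees.
#' @param fine_step fine step in degrees (must divide `theta_max`).
#' @param coarse_step,coarse_max optional coarse wings (step must divide
#'   `coarse_max - theta_max`).
#' @return an object of class `"rotation_grid"` with field `angles`.
#' @export
build_rotation_grid <- function(theta_max = 20, fine_step = 2,
                                coarse_step = NULL, coarse_max = NULL) {
  if (theta_max < 0) stop("theta_max must be >= 0", call. = FALSE)
  if (theta_max == 0) {
    angles <- 0
  } else {
    if (theta_max %% fine_step != 0)
      stop("fine_step does not divide theta_max", call. = FALSE)
    angles <- seq(-theta_max, theta_max, by = fine_step)
  }
  if (!is.null(coarse_step) && !is.null(coarse_max)) {
    if ((coarse_max - theta_max) %% coarse_step != 0)
      stop("coarse_step does not divide the coarse range", call. = FALSE)
    if (coarse_max > theta_max) {
      wing <- seq(theta_max + coarse_step, coarse_max, by = coarse_step)
      angles <- c(-rev(wing), angles, wing)
    }
  }
  structure(list(angles = sort(unique(angles)), theta_max = theta_max,
                 fine_step = fine_step), class = "rotation_grid")
}

#' @export
print.rotation_grid <- function(x, ...) {
  cat(sprintf("Rotation grid: %d angles in [%g, %g] degrees\n",
              length(x$angles), min(x$angles), max(x$angles)))
  invisible(x)
}

sequence_frames <- function(x) {
  # accept a gait_sequence, a list of gait_sequences, or a list of frames
  if (inherits(x, "gait_sequence")) return(x$frames)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "gait_sequence")))
    return(do.call(c, lapply(x, `[[`, "frames")))
  x
}

class_feature_matrix <- function(rframes, basis) {
  # flattened feature vectors (identity projection when basis is NULL);
  # all frames are projected in one stacked matrix product
  if (is.null(basis))
    return(vapply(rframes, as.numeric, numeric(length(rframes[[1]]))))
  A <- nrow(rframes[[1]]); K <- basis$K; N <- length(rframes)
  P <- do.call(rbind, rframes) %*% basis$eigvecs
  X <- matrix(0, A * K, N)
  for (i in seq_len(N)) X[, i] <- P[((i - 1L) * A + 1L):(i * A), ]
  X
}

#' Precompute per-(class, angle) gallery bases and subspaces
#'
#' The gallery side of the pipeline does not depend on the probe, so its
#' 2D-PCA bases and subspaces are computed once and reused across probes.
#' Results are identical whether or not a prebuilt model is supplied to
#' [similarity_tensor()].
#'
#' @param gallery named list mapping class id to a [gait_sequence()] (or list
#'   of sequences, pooled).
#' @param grid a [build_rotation_grid()].
#' @param K 2D-PCA dimension; `NULL` disables the 2D-PCA step (identity
#'   projection on vectorized frames, i.e. classic MSM features).
#' @param DG gallery subspace dimensionality (capped at the sample count).
#' @return an object of class `"gallery_model"`.
#' @export
build_gallery_model <- function(gallery, grid, K = 16L, DG = 50L) {
  stopifnot(inherits(grid, "rotation_grid"), length(gallery) >= 1,
            !is.null(names(gallery)))
  classes <- names(gallery)
  entries <- list()
  for (th in grid$angles) {
    key <- format(th)
    entries[[key]] <- list()
    for (cl in classes) {
      frames <- sequence_frames(gallery[[cl]])
      rframes <- lapply(frames, rotate_frame, theta = th)
      basis <- if (is.null(K)) NULL else {
        b <- fit_image_basis(rframes, K)
        attr(b, "class_id") <- cl
        b
      }
      X <- class_feature_matrix(rframes, basis)
      sub <- fit_subspace(X, min(DG, ncol(X)))
      entries[[key]][[cl]] <- list(basis = basis, subspace = sub)
    }
  }
  structure(list(entries = entries, grid = grid, K = K, DG = DG,
                 classes = classes), class = "gallery_model")
}

#' @export
print.gallery_model <- function(x, ...) {
  cat(sprintf("Gallery model: %d classes x %d rotation angles (K = %s, DG = %d)\n",
              length(x$classes), length(x$grid$angles),
              if (is.null(x$K)) "identity" else x$K, x$DG))
  invisible(x)
}

#' Canonical-angle similarity tensor of one probe against all classes
#'
#' For every rotation angle the gallery and probe frames are rotated; per
#' gallery class a 2D-PCA basis is fitted on the rotated gallery frames and
#' used to project BOTH the gallery and the probe frames (the probe is
#' re-projected per class); flattened projections are modelled as subspaces
#' and compared through the top `R` canonical-angle similarities at every
#' `(d_g, d_p)` on the axes.
#'
#' @param gallery named list of class sequences (or a prebuilt
#'   [build_gallery_model()] via `model`).
#' @param probe a [gait_sequence()].
#' @param grid a [build_rotation_grid()].
#' @param K 2D-PCA dimension (`NULL` = identity projection / classic MSM).
#' @param DG,DP maximal gallery/probe subspace dimensionalities.
#' @param R number of canonical angles, at most `min(dg_axis, dp_axis)`.
#' @param dg_axis,dp_axis dimensionality axes of the tensor.
#' @param model optional prebuilt [build_gallery_model()]; when supplied,
#'   `gallery`, `grid`, `K`, `DG` are taken from it.
#' @param probe_id identifier stored with the tensor.
#' @return an object of class `"similarity_tensor"`: a 5-D array with
#'   dimensions (class, r, d_g, d_p, theta) and the axis grids as attributes.
#' @export
similarity_tensor <- function(gallery = NULL, probe, grid = NULL, K = 16L,
                              DG = 50L, DP = 50L, R = 10L,
                              dg_axis = seq(10L, 50L, 10L),
                              dp_axis = seq(10L, 50L, 10L),
                              model = NULL, probe_id = NULL) {
  if (is.null(model)) {
    model <- build_gallery_model(gallery, grid, K = K, DG = DG)
  } else {
    stopifnot(inherits(model, "gallery_model"))
    grid <- model$grid; K <- model$K; DG <- model$DG
  }
  stopifnot(inherits(probe, "gait_sequence"))
  if (any(dg_axis > DG) || any(dp_axis > DP))
    stop("dimension axes exceed DG/DP", call. = FALSE)
  if (R > min(dg_axis, dp_axis))
    stop(sprintf("R = %d exceeds the smallest axis dimensionality %d",
                 R, min(dg_axis, dp_axis)), call. = FALSE)
  classes <- model$classes
  angles <- grid$angles
  tens <- array(NA_real_,
                dim = c(length(classes), R, length(dg_axis), length(dp_axis),
                        length(angles)),
                dimnames = list(class = classes, r = seq_len(R),
                                dg = dg_axis, dp = dp_axis,
                                theta = angles))
  for (ti in seq_along(angles)) {
    th <- angles[ti]
    rprobe <- lapply(probe$frames, rotate_frame, theta = th)
    ent <- model$entries[[format(th)]]
    for (ci in seq_along(classes)) {
      e <- ent[[classes[ci]]]
      Xp <- class_feature_matrix(rprobe, e$basis)
      psub <- suppressWarnings(fit_subspace(Xp, min(DP, ncol(Xp))))
      gdim <- ncol(e$subspace$basis); pdim <- ncol(psub$basis)
      for (gi in seq_along(dg_axis)) for (pi in seq_along(dp_axis)) {
        dg <- min(dg_axis[gi], gdim); dp <- min(dp_axis[pi], pdim)
        Re <- min(R, dg, dp)
        cp <- canonical_similarities(e$subspace, psub, dg, dp, Re)
        s <- cp$similarities
        # canonical angles beyond the attainable rank do not exist; report
        # them as orthogonal (similarity 0) so the tensor stays complete
        if (Re < R) s <- c(s, rep(0, R - Re))
        tens[ci, , gi, pi, ti] <- s
      }
    }
  }
  structure(tens, class = "similarity_tensor", probe_id = probe_id,
            grids = list(classes = classes, r = seq_len(R), dg = dg_axis,
                         dp = dp_axis, theta = angles))
}

#' @export
print.similarity_tensor <- function(x, ...) {
  g <- attr(x, "grids")
  cat(sprintf("Similarity tensor%s: %d classes x %d canonical angles x %d x %d dims x %d rotations\n",
              if (!is.null(attr(x, "probe_id")))
                paste0(" (probe ", attr(x, "probe_id"), ")") else "",
              length(g$classes), length(g$r), length(g$dg), length(g$dp),
              length(g$theta)))
  invisible(x)
}

tensor_slice <- function(tensor, r, dg, dp, theta) {
  g <- attr(tensor, "grids")
  ri <- match(r, g$r); gi <- match(dg, g$dg)
  pi <- match(dp, g$dp); ti <- match(theta, g$theta)
  if (anyNA(c(ri, gi, pi, ti)))
    stop("parameter combination off the tensor grid", call. = FALSE)
  s <- tensor[, ri, gi, pi, ti]
  names(s) <- g$classes
  s
}

#' Weak classifier at one parameter combination
#'
#' `h(r, d_g, d_p, theta) = argmax_c s_c(r, d_g, d_p, theta)`. Ties are broken
#' deterministically by the lowest class identifier (a message is emitted).
#'
#' @param tensor a [similarity_tensor()].
#' @param p parameter combination: a list or named vector with `r`, `dg`,
#'   `dp`, `theta`, all on the tensor grid.
#' @return the winning class label (character).
#' @export
weak_classify <- function(tensor, p) {
  p <- as.list(p)
  s <- tensor_slice(tensor, p$r, p$dg, p$dp, p$theta)
  best <- which(s >= max(s) - 0)
  if (length(best) > 1L) {
    best <- best[order(names(s)[best])]
    message("weak_classify: tie broken towards class ", names(s)[best[1]])
  }
  names(s)[best[1]]
}

#' Classic MSM classification (vectorized frames, no rotation bank)
#'
#' The plain mutual subspace method baseline: frames are vectorized, each
#' class and the probe are modelled as subspaces via autocorrelation PCA, and
#' the probe is assigned to the class with the largest first canonical-angle
#' similarity.
#'
#' @param gallery named list of class sequences.
#' @param probes list of probe [gait_sequence()]s.
#' @param DG,DP subspace dimensionalities (capped at sample counts).
#' @param r canonical-angle order used for the decision (default 1).
#' @return a list with `predicted` labels and the `similarity` matrix
#'   (probe x class, at canonical order `r`).
#' @export
plain_msm <- function(gallery, probes, DG = 50L, DP = 50L, r = 1L) {
  classes <- names(gallery)
  subs <- lapply(gallery, function(g) {
    X <- vapply(sequence_frames(g), as.numeric,
                numeric(length(sequence_frames(g)[[1]])))
    suppressWarnings(fit_subspace(X, min(DG, ncol(X))))
  })
  if (inherits(probes, "gait_sequence")) probes <- list(probes)
  sim <- matrix(NA_real_, length(probes), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_along(probes)) {
    X <- vapply(probes[[i]]$frames, as.numeric,
                numeric(length(probes[[i]]$frames[[1]])))
    psub <- suppressWarnings(fit_subspace(X, min(DP, ncol(X))))
    for (cl in classes) {
      d_g <- min(DG, ncol(subs[[cl]]$basis))
      d_p <- min(DP, ncol(psub$basis))
      cp <- canonical_similarities(subs[[cl]], psub, d_g, d_p,
                                   min(r, d_g, d_p))
      sim[i, cl] <- cp$similarities[min(r, d_g, d_p)]
    }
  }
  list(predicted = classes[max.col(sim, ties.method = "first")],
       similarity = sim)
}
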