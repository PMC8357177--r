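# Two-dimensional PCA on image matrices: the covariance is the B x B matrix
# S = (1/N) sum_n (I_n - mu)^T (I_n - mu), so it is estimated far more
# accurately from short sequences than the (A*B) x (A*B) covariance of
# vectorized frames.

#' Fit a 2D-PCA image basis
#'
#' @param frames list of at least two A x B image matrices.
#' @param K number of leading eigenvectors retained (1 <= K <= B).
#' @return an object of class `"image_basis"` with the mean image `mu`, the
#'   B x K orthonormal eigenvector matrix `eigvecs`, the descending `eigvals`,
#'   and `K`.
#' @export
fit_image_basis <- function(frames, K) {
  stopifnot(is.list(frames))
  if (length(frames) < 2L) stop("covariance undefined: need >= 2 frames",
                                call. = FALSE)
  B <- ncol(frames[[1]])
  if (K < 1 || K > B) stop("K must lie in [1, image width]", call. = FALSE)
  mu <- Reduce(`+`, frames) / length(frames)
  S <- matrix(0, B, B)
  for (f in frames) {
    d <- f - mu
    S <- S + crossprod(d)
  }
  S <- S / length(frames)
  eg <- eigen(S, symmetric = TRUE)
  if (max(eg$values) <= 1e-12)
    stop("degenerate: zero image covariance (identical frames)", call. = FALSE)
  structure(list(mu = mu,
                 eigvecs = fix_sign(eg$vectors[, seq_len(K), drop = FALSE]),
                 eigvals = eg$values[seq_len(K)],
                 K = as.integer(K)),
            class = "image_basis")
}

#' @export
print.image_basis <- function(x, ...) {
  cat(sprintf("2D-PCA image basis: K = %d eigenvectors of length %d; leading eigenvalue %.4g\n",
              x$K, nrow(x$eigvecs), x$eigvals[1]))
  invisible(x)
}

#' Project a frame onto a 2D-PCA basis
#'
#' The projected matrix has columns `xi_k = I %*% eta_k`. Probe frames are
#' projected with the basis of the gallery class they are being compared to;
#' no mean subtraction is applied at projection time (the raw frame `I` is
#' projected, not `I - mu`).
#'
#' @param frame an A x B matrix whose width matches the basis.
#' @param basis an [fit_image_basis()] result.
#' @return an object of class `"projected_matrix"`: the A x K matrix `Xi` plus
#'   a `source_class` attribute naming the basis owner (if set).
#' @export
project_image <- function(frame, basis) {
  stopifnot(inherits(basis, "image_basis"))
  if (ncol(frame) != nrow(basis$eigvecs))
    stop(sprintf("frame width %d does not match basis vector length %d",
                 ncol(frame), nrow(basis$eigvecs)), call. = FALSE)
  structure(list(Xi = frame %*% basis$eigvecs,
                 source_class = attr(basis, "class_id")),
            class = "projected_matrix")
}

#' Reconstruct an image from its projected matrix
#'
#' `I_tilde = sum_k xi_k %*% t(eta_k)`; exact when `K = B` (complete
#' orthonormal basis), a low-rank approximation otherwise. Reconstructions may
#' contain values outside \[0, 1\].
#'
#' @param pm a [project_image()] result produced with `basis`.
#' @param basis the same [fit_image_basis()] object.
#' @return an A x B real matrix.
#' @export
reconstruct_image <- function(pm, basis) {
  stopifnot(inherits(pm, "projected_matrix"), inherits(basis, "image_basis"))
  if (ncol(pm$Xi) != basis$K)
    stop("projected matrix/basis mismatch: column count differs from K",
         call. = FALSE)
  if (!is.null(pm$source_class) && !is.null(attr(basis, "class_id")) &&
      !identical(pm$source_class, attr(basis, "class_id")))
    stop("projected matrix was produced with a different basis", call. = FALSE)
  tcrossprod(pm$Xi, basis$eigvecs)
}

#' Flatten a projected matrix to a vector
#'
#' Column-major flattening (R's native layout): column k of `Xi` occupies
#' positions `(k-1)*A + 1 ... k*A`. Inner products of flattened vectors equal
#' Frobenius inner products of the matrices, so subspaces fitted on flattened
#' projected matrices see exactly the Frobenius geometry.
#'
#' @param pm a [project_image()] result (or a plain matrix).
#' @return a numeric vector of length `A * K`.
#' @export
flatten_projected <- function(pm) {
  m <- if (inherits(pm, "projected_matrix")) pm$Xi else pm
  as.numeric(m)
}

#' Save / load an image basis as JSON
#'
#' Portable plain-text serialization of a [fit_image_basis()] result.
#' @param basis an `"image_basis"`.
#' @param path file path.
#' @return `read_image_basis` returns the restored `"image_basis"`.
#' @export
write_image_basis <- function(basis, path) {
  stopifnot(inherits(basis, "image_basis"))
  jsonlite::write_json(
    list(mu = as.numeric(basis$mu), eigvecs = as.numeric(basis$eigvecs),
         eigvals = basis$eigvals, K = basis$K, shape = dim(basis$mu)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_basis
#' @export
read_image_basis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = matrix(x$mu, x$shape[1], x$shape[2]),
                 eigvecs = matrix(x$eigvecs, ncol = x$K),
                 eigvals = as.numeric(x$eigvals), K = as.integer(x$K)),
            class = "image_basis")
}
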