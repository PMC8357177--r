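# Linear-subspace modelling of image sets and canonical angles between
# subspaces -- the algebraic core of the mutual subspace method (MSM).

fix_sign <- function(basis) {
  # deterministic sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  basis
}

as_vector_matrix <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(cbind, lapply(vectors, as.numeric))
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 1)
  vectors
}

#' Fit a class subspace by autocorrelation PCA
#'
#' The class subspace is spanned by the leading eigenvectors of the class
#' autocorrelation matrix `Gamma = (1/N) * sum_n x_n x_n^T` (no mean
#' subtraction). Computed via the thin SVD of the sample matrix, which is
#' algebraically identical and numerically safer than forming `Gamma`.
#'
#' @param vectors an M x N matrix of sample columns, or a list of M-vectors.
#' @param max_dim requested subspace dimensionality; silently capped at the
#'   numerical rank (singular values below `1e-10` of the largest), with a
#'   warning when capping occurs.
#' @param printed_double_sum if `TRUE`, use the rank-one double-sum form
#'   `(1/N) * sum_n sum_l x_n x_l^T` instead of the autocorrelation. This
#'   variant exists for auditability only; it collapses the model to a single
#'   direction (the mean) and is not used anywhere in the pipeline.
#' @return an object of class `"subspace"` with fields `basis` (orthonormal
#'   M x D matrix), `eigenvalues` (descending, the spectrum of `Gamma`), and
#'   `ambient_dim`.
#' @export
fit_subspace <- function(vectors, max_dim, printed_double_sum = FALSE) {
  X <- as_vector_matrix(vectors)
  stopifnot(max_dim >= 1)
  n <- ncol(X)
  if (all(X == 0)) stop("degenerate input: all-zero vectors", call. = FALSE)
  if (printed_double_sum) {
    s <- rowSums(X)
    gamma <- tcrossprod(s) / n
    eg <- eigen(gamma, symmetric = TRUE)
    keep <- which(eg$values > 1e-10 * eg$values[1])
    d <- min(max_dim, length(keep))
    return(structure(list(basis = fix_sign(eg$vectors[, seq_len(d), drop = FALSE]),
                          eigenvalues = eg$values[seq_len(d)],
                          ambient_dim = nrow(X)), class = "subspace"))
  }
  sv <- svd(X)
  rank <- sum(sv$d >= 1e-10 * sv$d[1])
  d <- min(max_dim, rank, nrow(X), n)
  if (d < max_dim)
    warning(sprintf("requested dimension %d capped at numerical rank %d",
                    max_dim, d), call. = FALSE)
  structure(list(basis = fix_sign(sv$u[, seq_len(d), drop = FALSE]),
                 eigenvalues = sv$d[seq_len(d)]^2 / n,
                 ambient_dim = nrow(X)),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("Subspace: dim %d in ambient dim %d; leading eigenvalue %.4g\n",
              ncol(x$basis), x$ambient_dim, x$eigenvalues[1]))
  invisible(x)
}

#' @export
dim.subspace <- function(x) c(x$ambient_dim, ncol(x$basis))

#' Canonical-angle similarities between two subspaces
#'
#' Similarities are the squared cosines of the canonical (principal) angles
#' between the leading `d_g`-dimensional gallery and `d_p`-dimensional probe
#' subspaces: the top `R` squared singular values of the cross-Gram matrix
#' `M = Phi^T Psi`, equivalently the eigenvalues of `Z = M M^T`.
#'
#' @param gallery,probe `"subspace"` objects with equal `ambient_dim`.
#' @param d_g,d_p numbers of leading basis vectors used on each side.
#' @param R number of canonical angles returned, at most `min(d_g, d_p)`.
#' @return an object of class `"canonical_pair"` with `similarities`
#'   (descending, in \[0, 1\]), and `gallery_coeffs` / `probe_coeffs`
#'   (R x d_g and R x d_p coefficient rows; row r combined with the basis
#'   yields the r-th canonical vector, see [canonical_vector()]).
#' @export
canonical_similarities <- function(gallery, probe, d_g = NULL, d_p = NULL,
                                   R = 1L) {
  stopifnot(inherits(gallery, "subspace"), inherits(probe, "subspace"))
  if (gallery$ambient_dim != probe$ambient_dim)
    stop(sprintf("ambient dimension mismatch: gallery %d vs probe %d",
                 gallery$ambient_dim, probe$ambient_dim), call. = FALSE)
  if (is.null(d_g)) d_g <- ncol(gallery$basis)
  if (is.null(d_p)) d_p <- ncol(probe$basis)
  if (d_g > ncol(gallery$basis))
    stop(sprintf("d_g = %d exceeds gallery subspace dimension %d",
                 d_g, ncol(gallery$basis)), call. = FALSE)
  if (d_p > ncol(probe$basis))
    stop(sprintf("d_p = %d exceeds probe subspace dimension %d",
                 d_p, ncol(probe$basis)), call. = FALSE)
  if (R > min(d_g, d_p))
    stop(sprintf("R = %d exceeds min(d_g, d_p) = %d", R, min(d_g, d_p)),
         call. = FALSE)
  M <- crossprod(gallery$basis[, seq_len(d_g), drop = FALSE],
                 probe$basis[, seq_len(d_p), drop = FALSE])
  sv <- svd(M)
  sims <- pmin(pmax(sv$d[seq_len(R)]^2, 0), 1)
  structure(list(similarities = sims,
                 gallery_coeffs = t(sv$u[, seq_len(R), drop = FALSE]),
                 probe_coeffs = t(sv$v[, seq_len(R), drop = FALSE])),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat("Canonical-angle similarities (cos^2):",
      paste(sprintf("%.4f", x$similarities), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical vector from a coefficient row
#'
#' The r-th canonical vector of a subspace is the unit-norm combination
#' `v_r = sum_d w(r, d) * basis_d` of its first `d` basis vectors, where the
#' coefficient rows come from [canonical_similarities()]. The gallery and
#' probe canonical vectors of the same canonical angle satisfy
#' `<v_r^G, v_r^P>^2 = s(r)`.
#'
#' @param subspace a `"subspace"`.
#' @param coeffs coefficient row of length `d`.
#' @param d number of basis vectors used (defaults to `length(coeffs)`).
#' @return an M-vector of unit norm.
#' @export
canonical_vector <- function(subspace, coeffs, d = length(coeffs)) {
  stopifnot(inherits(subspace, "subspace"))
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != d)
    stop("coefficient length does not match d", call. = FALSE)
  if (d > ncol(subspace$basis))
    stop("d exceeds subspace dimension", call. = FALSE)
  drop(subspace$basis[, seq_len(d), drop = FALSE] %*% coeffs)
}
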