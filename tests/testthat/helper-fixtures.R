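# Shared fixtures, generated in code (no stored data). Heavier fixtures are
# memoized so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# 4 subjects, equal speed, no noise: the smallest benchmark on which
# identity separability should be perfect
small_bench <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- suppressWarnings(
      make_benchmark(4, gallery_speed = 1.0, probe_speeds = 1.0,
                     frames_per_seq = 40, seed = 11))
  .fixtures$small
}

# one walker frame, already normalized to 64 x 44
walker_frame <- function(seed = 5, phase = 0.7) {
  render_sequence(walker_subject(seed),
                  gait_style(1.0, phase0 = phase), 1)$frames[[1]]
}

random_subspace <- function(m, d) {
  basis <- qr.Q(qr(matrix(rnorm(m * d), m, d)))
  structure(list(basis = basis, eigenvalues = rep(1, d), ambient_dim = m),
            class = "subspace")
}

random_orthogonal <- function(d) qr.Q(qr(matrix(rnorm(d * d), d, d)))

# eigenvalues of the Z-matrix assembled elementwise from the two bases:
# zeta_ij = sum_d (phi_i . psi_d)(psi_d . phi_j)
z_matrix_similarities <- function(gallery, probe, d_g, d_p, R) {
  Phi <- gallery$basis[, seq_len(d_g), drop = FALSE]
  Psi <- probe$basis[, seq_len(d_p), drop = FALSE]
  Z <- matrix(0, d_g, d_g)
  for (i in seq_len(d_g)) for (j in seq_len(d_g)) for (d in seq_len(d_p))
    Z[i, j] <- Z[i, j] + sum(Phi[, i] * Psi[, d]) * sum(Psi[, d] * Phi[, j])
  sort(eigen(Z, symmetric = TRUE)$values, decreasing = TRUE)[seq_len(R)]
}

# hand-built similarity tensor for boosting tests: grids with classes,
# r = 1, dg = 1, dp = 1, and one theta per weak classifier; `sims` is a
# classes x n_theta matrix of similarities
toy_tensor <- function(sims, classes = rownames(sims),
                       thetas = seq_len(ncol(sims)) * 10 - 10) {
  tens <- array(sims, dim = c(length(classes), 1, 1, 1, ncol(sims)),
                dimnames = list(class = classes, r = 1, dg = 1, dp = 1,
                                theta = thetas))
  structure(tens, class = "similarity_tensor",
            grids = list(classes = classes, r = 1L, dg = 1L, dp = 1L,
                         theta = thetas))
}
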