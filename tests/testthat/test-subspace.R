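test_that("fit_subspace reproduces the autocorrelation eigenproblem", {
  e1 <- c(1, rep(0, 4))
  s <- fit_subspace(list(e1, e1, e1), 1)
  expect_equal(abs(s$basis[, 1]), e1)
  expect_equal(s$eigenvalues[1], 1)

  e2 <- c(0, 1, 0, 0, 0)
  s2 <- fit_subspace(cbind(e1, e2), 2)
  expect_equal(s2$eigenvalues, c(0.5, 0.5))
  proj <- s2$basis %*% t(s2$basis)
  expect_equal(as.numeric(proj %*% e1), e1)
  expect_equal(as.numeric(proj %*% e2), e2)

  # brute-force Gamma assembly oracle
  set.seed(1)
  X <- matrix(rnorm(50 * 20), 50, 20)
  gamma <- matrix(0, 50, 50)
  for (n in 1:20) gamma <- gamma + X[, n] %*% t(X[, n])
  gamma <- gamma / 20
  ev <- eigen(gamma, symmetric = TRUE)$values
  s3 <- fit_subspace(X, 20)
  expect_equal(s3$eigenvalues, ev[seq_along(s3$eigenvalues)],
               tolerance = 1e-8)
  expect_equal(crossprod(s3$basis), diag(ncol(s3$basis)), tolerance = 1e-8)

  expect_error(fit_subspace(matrix(0, 5, 3), 2), "degenerate")
})

test_that("the printed rank-one double-sum variant is available but inert", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  s <- fit_subspace(X, 3, printed_double_sum = TRUE)
  expect_equal(ncol(s$basis), 1)  # the double sum collapses to rank one
  m <- rowSums(X)
  expect_equal(abs(sum(s$basis[, 1] * m / sqrt(sum(m^2)))), 1,
               tolerance = 1e-10)
})

test_that("canonical similarities match their geometric definition", {
  set.seed(3)
  sub <- random_subspace(10, 3)
  cp <- canonical_similarities(sub, sub, 3, 3, 3)
  expect_equal(cp$similarities, rep(1, 3), tolerance = 1e-12)

  e <- diag(4)
  s1 <- fit_subspace(cbind(e[, 1], e[, 1]), 1)
  s2 <- fit_subspace(cbind(e[, 2], e[, 2]), 1)
  expect_equal(canonical_similarities(s1, s2, 1, 1, 1)$similarities, 0)

  diag45 <- fit_subspace(cbind((e[, 1] + e[, 2]) / sqrt(2)), 1)
  expect_equal(canonical_similarities(s1, diag45, 1, 1, 1)$similarities, 0.5)

  sub2 <- random_subspace(8, 2)
  expect_error(canonical_similarities(random_subspace(10, 2), sub2),
               "ambient dimension mismatch")
  expect_error(canonical_similarities(sub, sub, 5, 2, 1), "d_g")
  expect_error(canonical_similarities(sub, sub, 2, 2, 3), "R = 3")
})

test_that("similarities are basis-invariant, bounded, and monotone in d_p", {
  set.seed(4)
  for (rep in 1:5) {
    g <- random_subspace(20, 4); p <- random_subspace(20, 5)
    cp <- canonical_similarities(g, p, 4, 5, 4)
    expect_true(all(cp$similarities >= 0 & cp$similarities <= 1))
    expect_true(all(diff(cp$similarities) <= 1e-12))

    # rotate the probe basis by a random orthogonal matrix: same subspace
    q <- random_orthogonal(5)
    p2 <- p; p2$basis <- p$basis %*% q
    cp2 <- canonical_similarities(g, p2, 4, 5, 4)
    expect_equal(cp2$similarities, cp$similarities, tolerance = 1e-8)

    # enlarging the probe subspace cannot decrease s(1)
    s1 <- vapply(1:5, function(dp)
      canonical_similarities(g, p, 4, dp, 1)$similarities, numeric(1))
    expect_true(all(diff(s1) >= -1e-12))
  }
})

test_that("s(1) matches a dense grid search over unit vectors in M = 3", {
  set.seed(5)
  g <- random_subspace(3, 2); p <- random_subspace(3, 2)
  s1 <- canonical_similarities(g, p, 2, 2, 1)$similarities
  ang <- seq(0, pi, by = pi / 180)
  best <- 0
  for (a in ang) {
    u <- g$basis %*% c(cos(a), sin(a))
    for (b in ang) {
      v <- p$basis %*% c(cos(b), sin(b))
      best <- max(best, sum(u * v)^2)
    }
  }
  expect_equal(s1, best, tolerance = 1e-3)
})

test_that("canonical vectors reproduce the similarities", {
  set.seed(6)
  for (rep in 1:5) {
    g <- random_subspace(15, 4); p <- random_subspace(15, 3)
    cp <- canonical_similarities(g, p, 4, 3, 3)
    for (r in 1:3) {
      vg <- canonical_vector(g, cp$gallery_coeffs[r, ])
      vp <- canonical_vector(p, cp$probe_coeffs[r, ])
      expect_equal(sqrt(sum(vg^2)), 1, tolerance = 1e-8)
      expect_equal(sum(vg * vp)^2, cp$similarities[r], tolerance = 1e-8)
    }
  }
  sub <- random_subspace(6, 3)
  expect_equal(canonical_vector(sub, c(1, 0, 0)), sub$basis[, 1])
  expect_error(canonical_vector(sub, c(1, 0), d = 3), "length")
})
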