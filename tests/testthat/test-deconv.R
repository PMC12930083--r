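# Regularized-SVD deconvolution.

test_that("an impulse AIF makes deconvolution the identity up to the dt scale", {
  nt <- 16; dt <- 2
  aif <- c(1, rep(0, nt - 1))
  curve <- c(0, 0, 1, 4, 9, 6, 3, 2, 1, rep(0.5, 7))
  k <- deconvolve_matrix(matrix(curve, ncol = 1), aif, dt, lambda_rel = 0,
    circulant = TRUE, quadrature = "rect")
  expect_equal(as.vector(k[1:nt]) * dt, curve, tolerance = 1e-10)
})

test_that("SVD-filtered solution matches the direct Tikhonov normal-equations solve", {
  set.seed(3)
  for (nt in c(12, 20)) for (circ in c(TRUE, FALSE)) {
    t <- seq(0, by = 2, length.out = nt)
    aif <- make_aif(list(amplitude = 200, t0 = 4, alpha = 2, beta = 2), t)
    curves <- matrix(rnorm(nt * 5, sd = 5), nt, 5)
    lam_rel <- 0.15
    k_svd <- deconvolve_matrix(curves, aif, 2, lam_rel, circulant = circ,
      quadrature = "rect")
    # independent oracle: (A'A + lambda^2 I) k = A'c solved directly
    L <- nrow(k_svd)
    a_pad <- c(aif, rep(0, L - nt))
    S <- outer(seq_len(L), seq_len(L), `-`)
    A <- if (circ) 2 * matrix(a_pad[(S %% L) + 1], L, L) else {
      M <- matrix(0, L, L); M[S >= 0] <- 2 * a_pad[S[S >= 0] + 1]; M
    }
    lam <- lam_rel * svd(A)$d[1]
    C <- rbind(curves, matrix(0, L - nt, 5))
    k_direct <- solve(crossprod(A) + lam^2 * diag(L), crossprod(A, C))
    expect_lt(max(abs(k_svd - k_direct)) / max(abs(k_direct)), 1e-8)
  }
})

test_that("increasing regularization never increases the residue norm", {
  set.seed(8)
  t <- seq(0, 48, by = 2)
  aif <- make_aif(default_aif_params(), t)
  curve <- matrix(perfstab:::tissue_enhancement(t, default_aif_params(),
    50, 5, 2, 0) + rnorm(length(t), sd = 1), ncol = 1)
  norms <- sapply(c(0, 0.01, 0.05, 0.1, 0.2, 0.5), function(l) {
    sqrt(sum(deconvolve_matrix(curve, aif, 2, l)^2))
  })
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("a pure delay appears at the right residue sample in circulant mode", {
  nt <- 24; dt <- 2
  t <- seq(0, by = dt, length.out = nt)
  aif <- make_aif(list(amplitude = 200, t0 = 4, alpha = 2, beta = 2), t)
  for (m in c(2L, 5L)) {
    curve <- c(rep(0, m), aif[1:(nt - m)])  # delayed unit-scale copy
    k <- deconvolve_matrix(matrix(dt * curve, ncol = 1), aif, dt,
      lambda_rel = 0.001, circulant = TRUE, quadrature = "rect")
    expect_lte(abs(which.max(k[1:nt]) - 1L - m), 1L)
  }
})

test_that("discrete-model curves recover CBF within 5% at small lambda", {
  nt <- 26; dt <- 2
  t <- seq(0, by = dt, length.out = nt)
  aif <- make_aif(default_aif_params(), t)
  a_pad <- c(aif, rep(0, nt))
  S <- outer(seq_len(2 * nt), seq_len(2 * nt), `-`)
  A <- dt * matrix(a_pad[(S %% (2 * nt)) + 1], 2 * nt, 2 * nt)
  cbf <- 60 / 6000
  k_true <- c(cbf * exp(-t / 4), rep(0, nt))
  curve <- (A %*% k_true)[1:nt]
  k <- deconvolve_matrix(matrix(curve, ncol = 1), aif, dt, lambda_rel = 0.005,
    circulant = TRUE, quadrature = "rect")
  expect_equal(max(k), cbf, tolerance = 0.05)
})

test_that("deconvolution is linear in the tissue curves", {
  t <- seq(0, 48, by = 2)
  aif <- make_aif(default_aif_params(), t)
  curve <- matrix(perfstab:::tissue_enhancement(t, default_aif_params(),
    40, 6, 1, 0), ncol = 1)
  k1 <- deconvolve_matrix(curve, aif, 2, 0.1)
  k3 <- deconvolve_matrix(3 * curve, aif, 2, 0.1)
  expect_equal(k3, 3 * k1, tolerance = 1e-12)
})

test_that("invalid regularization and degenerate AIFs are rejected", {
  t <- seq(0, 30, by = 2)
  expect_error(deconvolve_matrix(matrix(0, 16, 1), rep(0, 16), 2), "all-zero")
  expect_error(deconvolve_matrix(matrix(0, 16, 1), rep(1, 16), 2,
    lambda_rel = -0.1), "lambda_rel")
})
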