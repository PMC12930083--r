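# Map computation and relative normalization.

# single-voxel series through deconvolution + maps, for focused checks
one_voxel_maps <- function(curve, aif_curve, t, baseline = 0, lambda = 0.05,
                           cbf_bias_correction = TRUE, quadrature = "linear") {
  arr <- array(baseline + curve, c(1, 1, 1, length(t)))
  ser <- suppressWarnings(dynamic_series(arr, t, c(3, 3, 4)))
  mask <- array(TRUE, c(1, 1, 1))
  res <- deconvolve_voxelwise(ser, list(curve = aif_curve), mask,
    array(baseline, c(1, 1, 1)), lambda_rel = lambda, quadrature = quadrature)
  compute_maps(res, ser, list(curve = aif_curve), array(baseline, c(1, 1, 1)),
    cbf_bias_correction = cbf_bias_correction, map_filter = "none")
}

test_that("Tmax is the time of the residue maximum, first on ties", {
  t <- seq(0, 30, by = 2)
  nt <- length(t)
  impulse <- c(1, rep(0, nt - 1))
  curve <- numeric(nt); curve[4] <- 5  # residue peak at t = 6 s
  m <- one_voxel_maps(curve, impulse, t, lambda = 0,
    cbf_bias_correction = FALSE, quadrature = "rect")
  expect_equal(m$tmax[1, 1, 1], 6)
  tie <- numeric(nt); tie[c(4, 6)] <- 5  # equal maxima at samples 4 and 6
  m2 <- one_voxel_maps(tie, impulse, t, lambda = 0,
    cbf_bias_correction = FALSE, quadrature = "rect")
  expect_equal(m2$tmax[1, 1, 1], 6)  # first maximum (sample 4, t = 6)
})

test_that("recovered CBV/CBF reproduces the true MTT within 10%", {
  p <- default_aif_params()
  t <- seq(0, 54, by = 2)
  aif <- make_aif(p, t)
  for (mtt in c(4, 8)) {
    curve <- perfstab:::tissue_enhancement(t, p, 50, mtt, 1, 0)
    m <- one_voxel_maps(curve, aif, t, lambda = 0.03)
    expect_equal(m$mtt[1, 1, 1], mtt, tolerance = 0.1)
  }
})

test_that("maps scale linearly with the tissue curves, Tmax unchanged", {
  p <- default_aif_params()
  t <- seq(0, 50, by = 2)
  aif <- make_aif(p, t)
  curve <- perfstab:::tissue_enhancement(t, p, 45, 6, 2, 0)
  m1 <- one_voxel_maps(curve, aif, t)
  m2 <- one_voxel_maps(2 * curve, aif, t)
  expect_equal(m2$cbf[1, 1, 1], 2 * m1$cbf[1, 1, 1], tolerance = 1e-8)
  expect_equal(m2$cbv[1, 1, 1], 2 * m1$cbv[1, 1, 1], tolerance = 1e-12)
  expect_identical(m2$tmax[1, 1, 1], m1$tmax[1, 1, 1])
})

test_that("relative normalization references normal tissue", {
  cbf <- array(10, c(6, 6, 6))
  tmax <- array(1, c(6, 6, 6))
  maps <- fake_maps(cbf, tmax)
  norm <- normalize_relative(maps, erode_reference = 0)
  expect_true(all(norm$rcbf == 100))
  # doubling absolute CBF leaves rCBF unchanged
  norm2 <- normalize_relative(fake_maps(2 * cbf, tmax), erode_reference = 0)
  expect_equal(norm2$rcbf, norm$rcbf)
  # mtt = cbv / cbf wherever cbf > 0
  expect_equal(norm$mtt[cbf > 0], (norm$cbv / norm$cbf)[cbf > 0])
})

test_that("normalization fails without normally perfused reference tissue", {
  maps <- fake_maps(array(10, c(4, 4, 4)), array(8, c(4, 4, 4)))
  expect_error(normalize_relative(maps), "no normally perfused")
})
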