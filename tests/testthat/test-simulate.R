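# Forward model: indicator-dilution simulation and NCCT generation.

spec <- phantom_spec(seed = 3)
truth <- build_phantom(spec)

test_that("zero flow and zero noise give constant baseline curves", {
  sp <- phantom_spec(
    tissue_params = list(gm = list(cbf = 0, mtt = 4, baseline_hu = 35),
      wm = list(cbf = 0, mtt = 5, baseline_hu = 28)),
    lesion = NULL, noise_sd = 0
  )
  tr <- build_phantom(sp)
  ser <- simulate_ctp_series(tr, sp, seed = 1)
  tis <- tr$brain_mask & !tr$artery_mask & !tr$vein_mask
  flat <- matrix(ser$data, ncol = length(ser$time_axis_s))
  rng <- apply(flat[which(tis), ], 1, function(x) diff(range(x)))
  expect_equal(max(rng), 0)
})

test_that("central volume theorem holds for the noise-free simulation", {
  # integral of enhancement equals kappa*CBF*MTT*integral(AIF) for every
  # voxel; oracle integrals by fine-grid quadrature
  sp <- phantom_spec(duration_s = 55, noise_sd = 0, lesion = NULL,
    normal_delay_s = 0)
  tr <- build_phantom(sp)
  ser <- simulate_ctp_series(tr, sp, seed = 1)
  tf <- seq(0, 55, by = 0.01)
  aif_area <- pracma::trapz(tf, make_aif(sp$aif_params, tf))
  w <- perfstab:::trapz_weights(ser$time_axis_s)
  flat <- matrix(ser$data, ncol = length(w))
  for (cls in c("gm_mask", "wm_mask")) {
    vox <- which(tr[[cls]])[1]
    enh_area <- sum(w * (flat[vox, ] - tr$baseline_hu[vox]))
    expected <- (1 / 6000) * tr$true_cbf[vox] * tr$true_mtt[vox] * aif_area
    expect_equal(enh_area, expected, tolerance = 0.02)
  }
})

test_that("two noise seeds differ by the folded-normal expectation", {
  s1 <- simulate_ctp_series(truth, spec, seed = 21)
  s2 <- simulate_ctp_series(truth, spec, seed = 22)
  d <- s1$data - s2$data
  # |N(0, 2 sigma^2)| has mean 2 sigma / sqrt(pi)
  expect_equal(mean(abs(d)), 2 * spec$noise_sd / sqrt(pi), tolerance = 0.05)
})

test_that("simulation is bit-identical for identical seeds", {
  s1 <- simulate_ctp_series(truth, spec, seed = 77)
  s2 <- simulate_ctp_series(truth, spec, seed = 77)
  expect_identical(s1$data, s2$data)
  n1 <- simulate_ncct(truth, spec, seed = 77)
  n2 <- simulate_ncct(truth, spec, seed = 77)
  expect_identical(as.vector(n1), as.vector(n2))
})

test_that("lesion-free hemispheres are balanced within the noise bound", {
  sp <- phantom_spec(lesion = NULL, seed = 5)
  tr <- build_phantom(sp)
  ncct <- simulate_ncct(tr, sp, seed = 41)
  left <- tr$brain_mask
  left[(dim(left)[1] / 2 + 1):dim(left)[1], , ] <- FALSE
  right <- tr$brain_mask & !left
  n <- sum(left)
  expect_lt(abs(mean(ncct[left]) - mean(ncct[right])),
    3 * sp$ncct_noise_sd / sqrt(n))
})

test_that("NCCT core hypodensity is applied exactly without noise", {
  n0 <- simulate_ncct(truth, spec, seed = 1, core_hypodensity_hu = 5,
    noise_sd = 0)
  expect_equal(unique(truth$baseline_hu[truth$core_mask] -
    n0[truth$core_mask]), 5)
  out <- !truth$core_mask
  expect_equal(max(abs(truth$baseline_hu[out] - n0[out])), 0)
})

test_that("affected regions count atlas regions majority-covered by the core", {
  tr <- truth
  tr$core_mask <- tr$atlas$labels %in% c(1L, 2L, 3L)
  dim(tr$core_mask) <- dim(tr$atlas$labels)
  aff <- perfstab:::affected_atlas_regions(tr$atlas, tr$core_mask)
  expect_length(aff, 3)
  expect_true(all(startsWith(aff, "L:")))
})
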