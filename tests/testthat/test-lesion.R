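# Brain masking, threshold segmentation, volumetry.

test_that("mask volume arithmetic is exact", {
  m <- array(FALSE, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mask_volume_ml(m, c(1, 1, 1)), 1)
  expect_equal(mask_volume_ml(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  m2 <- array(FALSE, c(10, 10, 10)); m2[1:5, 1:5, 1:5] <- TRUE
  expect_equal(mask_volume_ml(m2, c(2, 2, 2)), 1)  # 125 voxels at 8 mm^3
})

test_that("an all-air volume yields an explicit empty-mask error", {
  expect_error(compute_brain_mask(array(-1000, c(10, 10, 5))), "empty brain mask")
})

test_that("the noise-free phantom brain mask matches the construction labels", {
  spec <- phantom_spec(seed = 1)
  truth <- build_phantom(spec)
  mask <- compute_brain_mask(truth$baseline_hu, voxel_size_mm = spec$voxel_size_mm)
  expect_identical(as.vector(mask), as.vector(truth$brain_mask))
  # voxelized volume close to the analytic ellipsoid volume
  analytic_ml <- 4 / 3 * pi * prod(spec$brain_radii_mm) / 1000
  expect_equal(mask_volume_ml(mask, spec$voxel_size_mm), analytic_ml,
    tolerance = 0.02)
})

test_that("segmentation applies strict thresholds and nests core in hypoperfusion", {
  dims <- c(10, 10, 4)
  tmax <- array(2, dims)
  tmax[1:5, , ] <- 8
  tmax[6, 1, 1] <- 6  # exactly at threshold: excluded
  cbf <- array(50, dims)
  cbf[1:3, , ] <- 10
  maps <- fake_maps(cbf, tmax)
  maps <- normalize_relative(maps, erode_reference = 0)
  maps$rcbf[2, 1, 1] <- 30  # exactly at threshold: excluded
  les <- segment_lesions(maps, min_cluster_ml = 0)
  expect_false(les$hypoperfusion_mask[6, 1, 1])
  expect_false(les$core_mask[2, 1, 1])
  expect_true(all(les$hypoperfusion_mask[les$core_mask]))
  expect_equal(les$mismatch_ml, les$hypoperfusion_ml - les$core_ml)
})

test_that("thresholds act monotonically on the volumes", {
  set.seed(21)
  dims <- c(12, 12, 6)
  tmax <- array(runif(prod(dims), 0, 12), dims)
  cbf <- array(runif(prod(dims), 5, 60), dims)
  maps <- normalize_relative(fake_maps(cbf, tmax), erode_reference = 0)
  hypo_v <- sapply(c(4, 6, 8), function(th) {
    segment_lesions(maps, tmax_threshold_s = th, min_cluster_ml = 0)$hypoperfusion_ml
  })
  expect_true(all(diff(hypo_v) <= 0))
  core_v <- sapply(c(20, 30, 40), function(th) {
    segment_lesions(maps, rcbf_threshold_pct = th, min_cluster_ml = 0)$core_ml
  })
  expect_true(all(diff(core_v) >= 0))
})

test_that("missing normalization is reported, not silently ignored", {
  maps <- fake_maps(array(30, c(6, 6, 3)), array(2, c(6, 6, 3)))
  expect_error(segment_lesions(maps), "rcbf")
})

test_that("noise-free phantom hypoperfusion is recovered almost exactly", {
  spec <- phantom_spec(noise_sd = 0, seed = 1)
  truth <- build_phantom(spec)
  ctp <- simulate_ctp_series(truth, spec, seed = 1)
  res <- run_scan_analysis(ctp, config = perfstab_config())
  expect_gte(dice_coefficient(res$lesions$hypoperfusion_mask,
    truth$hypoperfusion_mask), 0.95)
  expect_true(all(res$lesions$hypoperfusion_mask[res$lesions$core_mask]))
})
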