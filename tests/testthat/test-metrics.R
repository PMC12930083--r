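# Contralateral mirroring, intensity metrics, scan intervals.

test_that("mirroring reflects across the midline and is an involution", {
  m <- array(FALSE, c(8, 6, 4))
  m[1:3, 2, 2] <- TRUE  # strictly left-sided
  mm <- mirror_contralateral(m)
  expect_equal(sum(mm), sum(m))
  expect_true(all(which(mm, arr.ind = TRUE)[, 1] >= 6))
  expect_identical(mirror_contralateral(mm), m)
  expect_error(mirror_contralateral(m, lr_axis = NA), "ambiguous")
})

test_that("the mirrored phantom core lies in contralateral normal tissue", {
  truth <- build_phantom(phantom_spec(seed = 4))
  mirrored <- mirror_contralateral(truth$core_mask)
  expect_equal(sum(mirrored & truth$hypoperfusion_mask), 0)
  expect_true(all(truth$brain_mask[mirrored]))
})

test_that("intensity metrics compute medians and contralateral ratios", {
  dims <- c(10, 6, 4)
  tmax <- array(1, dims)
  cbf <- array(40, dims)
  hypo <- array(FALSE, dims)
  hypo[2, 2:4, 2] <- TRUE
  hypo[3, 2:3, 2] <- TRUE
  tmax[hypo] <- c(7, 8, 9, 10, 11)
  core <- array(FALSE, dims)
  core[2, 2:4, 2] <- TRUE
  maps <- fake_maps(cbf, tmax)
  lesions <- fake_lesions(hypo, core)
  ncct <- array(30, dims)
  out <- lesion_intensity_metrics(maps, ncct, lesions)
  expect_equal(out$median_tmax_hypo_s, 9)
  expect_equal(out$rel_cbf_core_pct, 100)  # core CBF equals contralateral
  expect_equal(out$rel_hu_core_pct, 100)
})

test_that("empty masks yield undefined metrics, never zero", {
  dims <- c(6, 6, 2)
  maps <- fake_maps(array(40, dims), array(1, dims))
  lesions <- fake_lesions(array(FALSE, dims), array(FALSE, dims))
  out <- lesion_intensity_metrics(maps, array(30, dims), lesions)
  expect_true(is.na(out$median_tmax_hypo_s))
  expect_true(is.na(out$rel_cbf_core_pct))
  expect_true(is.na(out$rel_hu_core_pct))
})

test_that("the noise-free phantom core measures about 15% relative CBF", {
  spec <- phantom_spec(noise_sd = 0, seed = 2)
  truth <- build_phantom(spec)
  ctp <- simulate_ctp_series(truth, spec, seed = 3)
  cfg <- perfstab_config(lambda_rel = 0.01, cbf_lambda_rel = 0.01,
    smoothing_fwhm_mm = 0, cbf_smoothing_fwhm_mm = 0, map_filter = "none")
  res <- run_scan_analysis(ctp, config = cfg)
  expect_equal(res$metrics$rel_cbf_core_pct, 15, tolerance = 3 / 15)
})

test_that("scan intervals parse acquisition times and wrap midnight", {
  expect_equal(scan_interval_hours("120000", "150000"), 3)
  expect_equal(scan_interval_hours("233000", "003000"), 1)
  expect_equal(scan_interval_hours("080000", "083600"), 0.6)
  expect_equal(scan_interval_hours("080000.250000", "080001.750000"),
    1.5 / 3600)
  expect_error(scan_interval_hours("12:00:00", "130000"), "unparseable")
  expect_error(scan_interval_hours("250000", "120000"), "invalid")
})
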