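# Ground-truth construction: masks, maps, atlas geometry.

spec_default <- phantom_spec(seed = 7)
truth_default <- build_phantom(spec_default)

test_that("lesion-free phantom has empty lesion masks", {
  truth <- build_phantom(phantom_spec(lesion = NULL))
  expect_equal(sum(truth$hypoperfusion_mask), 0)
  expect_equal(sum(truth$core_mask), 0)
})

test_that("truth masks nest and follow the thresholds by construction", {
  truth <- truth_default
  expect_true(all(truth$core_mask[truth$core_mask] %in% TRUE))
  expect_true(all(truth$hypoperfusion_mask[truth$core_mask]))
  expect_true(all(truth$brain_mask[truth$hypoperfusion_mask]))
  # core voxels: true rCBF 15% of the normal reference, below 30%
  expect_equal(unique(truth$rcbf_true[truth$core_mask]), 15)
  expect_true(all(truth$rcbf_true[truth$core_mask] < 30))
  # hypoperfused voxels all exceed 6 s true Tmax; normal tissue is < 4 s
  expect_true(all(truth$true_tmax[truth$hypoperfusion_mask] > 6))
  normal <- truth$brain_mask & !truth$hypoperfusion_mask &
    !truth$artery_mask & !truth$vein_mask
  expect_true(all(truth$true_tmax[normal] < 4, na.rm = TRUE))
})

test_that("penumbra delay places true Tmax as designed", {
  les4 <- lesion_component(penumbra_delay_s = 4, penumbra_dispersion_s = 1,
    include_core = FALSE)
  t4 <- build_phantom(phantom_spec(lesion = les4))
  pen <- !is.na(t4$true_delay) & t4$true_delay == 4
  expect_true(all(t4$true_tmax[pen] > 4))
  les7 <- lesion_component(penumbra_delay_s = 7, include_core = FALSE)
  t7 <- build_phantom(phantom_spec(lesion = les7))
  expect_gt(sum(t7$hypoperfusion_mask), 0)
  expect_true(all(t7$true_tmax[t7$hypoperfusion_mask] == 7))
})

test_that("dispersed residue shifts true Tmax by the residue peak offset", {
  # closed-form argmax of exp(-t/m) convolved with exp(-t/tau)/tau
  m <- 8; tau <- 2
  expected <- log(m / tau) * m * tau / (m - tau)
  expect_equal(perfstab:::residue_peak_offset(m, tau), expected, tolerance = 0.02)
  les <- lesion_component(penumbra_delay_s = 8, penumbra_dispersion_s = 2,
    include_core = FALSE)
  tr <- build_phantom(phantom_spec(lesion = les))
  mtt_pen <- unique(tr$true_mtt[tr$hypoperfusion_mask])
  off <- perfstab:::residue_peak_offset(mtt_pen, 2)
  expect_equal(unique(tr$true_tmax[tr$hypoperfusion_mask]), 8 + off,
    tolerance = 0.02)
})

test_that("atlas has 20 mirror-symmetric nonempty regions", {
  atlas <- truth_default$atlas
  labs <- atlas$labels
  counts <- table(labs[labs > 0])
  expect_equal(sort(as.integer(names(counts))), 1:20)
  expect_true(all(counts > 0))
  # mirroring the label volume and swapping sides reproduces it exactly
  flipped <- labs[rev(seq_len(dim(labs)[1])), , ]
  swapped <- flipped
  swapped[flipped > 0] <- ifelse(flipped[flipped > 0] > 10,
    flipped[flipped > 0] - 10L, flipped[flipped > 0] + 10L)
  expect_identical(swapped, labs)
})

test_that("a lesion outside the brain is rejected", {
  les <- lesion_component(center_mm = c(-200, 0, 0))
  expect_error(build_phantom(phantom_spec(lesion = les)), "outside brain")
})

test_that("phantom construction is deterministic", {
  t1 <- build_phantom(spec_default)
  t2 <- build_phantom(spec_default)
  expect_identical(t1$true_cbf, t2$true_cbf)
  expect_identical(t1$atlas$labels, t2$atlas$labels)
})

test_that("volume-targeted lesions hit their volume to within one voxel", {
  vml <- prod(spec_default$voxel_size_mm) / 1000
  for (target in c(10, 30, 60)) {
    les <- lesion_component(penumbra_target_ml = target, include_core = FALSE)
    tr <- build_phantom(phantom_spec(lesion = les))
    expect_lte(abs(sum(tr$hypoperfusion_mask) * vml - target), vml)
  }
})
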