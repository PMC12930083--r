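# Automated ASPECTS scoring.

spec <- phantom_spec(seed = 5)
truth <- build_phantom(spec)
atlas <- truth$atlas
ncct0 <- truth$baseline_hu  # noise-free, symmetric NCCT

test_that("identity mapping returns exactly the atlas label sets", {
  regions <- map_atlas_regions(ncct0, atlas, alignment_mode = "identity")
  expect_length(regions, 20)
  for (i in seq_len(20)) {
    expect_equal(length(regions[[i]]), sum(atlas$labels == atlas$names$label[i]))
  }
})

test_that("an atlas without all 20 regions fails validation", {
  broken <- atlas
  broken$labels[broken$labels %in% c(19L, 20L)] <- 0L
  expect_error(map_atlas_regions(ncct0, broken), "20 paired region labels")
})

test_that("affine alignment recovers a pure translation within half a voxel", {
  shifted <- ncct0[c(62:64, 1:61), , ]  # translate 3 voxels along x (circular)
  reg_orig <- map_atlas_regions(ncct0, atlas, "identity")
  reg_aff <- map_atlas_regions(shifted, atlas, "affine",
    hu_window = c(10, 60))
  centroid <- function(idx) colMeans(arrayInd(idx, dim(ncct0)))
  for (nm in c("L:C", "R:M5", "L:M1")) {
    d <- centroid(reg_aff[[nm]]) - centroid(reg_orig[[nm]])
    expect_lt(abs(d[1] - 3), 0.5)
    expect_lt(max(abs(d[2:3])), 0.5)
  }
})

test_that("identical hemispheres score 10 on both sides", {
  res <- score_aspects(ncct0, atlas = atlas)
  expect_equal(res$score, 10L)
  expect_equal(res$score_left, 10L)
  expect_equal(res$score_right, 10L)
  expect_equal(res$affected_side, "none")
})

test_that("k hypodense regions cost exactly k points", {
  for (k in c(1, 3, 6)) {
    ncct <- ncct0
    for (lab in seq_len(k)) {
      ncct[atlas$labels == lab] <- ncct[atlas$labels == lab] - 5
    }
    res <- score_aspects(ncct, atlas = atlas)
    expect_equal(res$score, 10L - k)
    expect_equal(res$affected_side, "L")
    expect_equal(res$score_right, 10L)
  }
})

test_that("a difference of exactly 2.25 HU is not flagged", {
  ncct <- ncct0
  ncct[atlas$labels == 1L] <- ncct[atlas$labels == 1L] - 2.25
  res <- score_aspects(ncct, atlas = atlas)
  expect_equal(res$score, 10L)
  ncct[atlas$labels == 1L] <- ncct[atlas$labels == 1L] - 0.01
  expect_equal(score_aspects(ncct, atlas = atlas)$score, 9L)
})

test_that("swapping hemispheres mirrors flags and scores", {
  ncct <- ncct0
  ncct[atlas$labels %in% c(2L, 5L)] <- ncct[atlas$labels %in% c(2L, 5L)] - 6
  res <- score_aspects(ncct, atlas = atlas)
  flipped <- ncct[rev(seq_len(dim(ncct)[1])), , ]
  res_f <- score_aspects(flipped, atlas = atlas)
  expect_equal(res_f$affected_side, "R")
  expect_equal(res_f$score, res$score)
  expect_equal(res_f$table$flag_right, res$table$flag_left)
})

test_that("deepening a hypodensity never raises the score", {
  scores <- sapply(c(3, 5, 8, 12), function(dhu) {
    ncct <- ncct0
    ncct[atlas$labels == 4L] <- ncct[atlas$labels == 4L] - dhu
    score_aspects(ncct, atlas = atlas)$score
  })
  expect_true(all(diff(scores) <= 0))
})

test_that("region medians are robust to moderate NCCT noise", {
  flags <- sapply(1:10, function(s) {
    ncct <- simulate_ncct(truth, spec, seed = 7000 + s, core_hypodensity_hu = 0,
      noise_sd = 1.5)
    res <- score_aspects(ncct, atlas = atlas)
    sum(res$table$flag_left) + sum(res$table$flag_right)
  })
  expect_equal(sum(flags), 0)
})
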