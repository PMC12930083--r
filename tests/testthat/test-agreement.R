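# Bland-Altman, paired tests, cohort aggregation.

test_that("Bland-Altman matches hand-computed values", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))

  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
  ba3 <- bland_altman(c(0, 0, 0, NA), c(1, 3, 2, 5))
  expect_equal(ba3$n_used, 3)
  expect_equal(ba3$n_dropped, 1)
})

test_that("limits of agreement equal bias +/- 1.96 sd on the {1,3} example", {
  ba <- bland_altman(c(0, 0, 0), c(1, 3, 2))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 1)
  d <- c(1, 3)
  # the two-difference case, computed directly against the closed form
  bias <- mean(d); s <- sd(d)
  expect_equal(bias, 2)
  expect_equal(s, sqrt(2))
  expect_equal(bias + 1.96 * s, 2 + 1.96 * sqrt(2))
  expect_equal(bias - 1.96 * s, 2 - 1.96 * sqrt(2))
})

test_that("adding constants shifts the bias exactly as expected", {
  set.seed(12)
  v1 <- rnorm(10); v2 <- rnorm(10)
  ba <- bland_altman(v1, v2)
  expect_equal(bland_altman(v1 + 5, v2 + 5)$bias, ba$bias, tolerance = 1e-12)
  expect_equal(bland_altman(v1, v2 + 5)$bias, ba$bias + 5, tolerance = 1e-12)
})

test_that("swapping scan order negates bias and interval association only", {
  set.seed(13)
  v1 <- rnorm(12); v2 <- rnorm(12); iv <- runif(12, 1, 8)
  a <- agreement_tests(v1, v2, iv)
  b <- agreement_tests(v2, v1, iv)
  expect_equal(bland_altman(v2, v1)$bias, -bland_altman(v1, v2)$bias)
  expect_equal(bland_altman(v2, v1)$sd, bland_altman(v1, v2)$sd)
  expect_equal(b$r, a$r)
  expect_equal(b$interval_r, -a$interval_r, tolerance = 1e-12)
  expect_equal(b$t_p, a$t_p, tolerance = 1e-12)
})

test_that("p-values match the reference implementations to 1e-9", {
  set.seed(14)
  for (i in 1:5) {
    v1 <- rnorm(8 + i, mean = 2)
    v2 <- v1 + rnorm(8 + i, sd = 0.7)
    iv <- runif(8 + i, 0.7, 8.9)
    at <- agreement_tests(v1, v2, iv)
    expect_equal(at$r_p, cor.test(v1, v2)$p.value, tolerance = 1e-9)
    expect_equal(at$t_p, t.test(v2 - v1, mu = 0)$p.value, tolerance = 1e-9)
    expect_equal(at$interval_p, cor.test(v2 - v1, iv)$p.value, tolerance = 1e-9)
  }
})

test_that("identical and anticorrelated scans give the textbook statistics", {
  v <- c(1, 2, 3, 5)
  at <- agreement_tests(v, v)
  expect_equal(at$r, 1)
  expect_equal(at$t, 0)
  expect_equal(at$t_p, 1)
  expect_equal(agreement_tests(c(1, 2, 3), c(3, 2, 1))$r, -1)
})

test_that("zero-variance correlates yield NA statistics, not errors", {
  at <- agreement_tests(rep(2, 5), c(1, 2, 3, 4, 5), runif(5, 1, 5))
  expect_true(is.na(at$r))
  at2 <- agreement_tests(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), rep(3, 5))
  expect_true(is.na(at2$interval_p))
})

test_that("cohort reports exclude disruptive pairs and track per-metric n", {
  set.seed(15)
  n <- 32
  tab <- data.frame(pair_id = 1:n,
    scenario = c(rep("stable", 29), "new_occlusion", "new_occlusion",
      "thrombus_migration"),
    interval_h = runif(n, 0.7, 8.9))
  for (m in c("core_ml", "hypoperfusion_ml", "aspects", "median_tmax_hypo_s",
    "rel_cbf_core_pct", "rel_hu_core_pct")) {
    tab[[paste0(m, "_1")]] <- rnorm(n, 20, 5)
    tab[[paste0(m, "_2")]] <- tab[[paste0(m, "_1")]] + rnorm(n, 0, 2)
  }
  tab$core_ml_1[4] <- NA  # one pair with an undefined core metric
  rep <- cohort_report(tab)
  expect_equal(rep$n_pairs, 32)
  expect_equal(rep$n_excluded, 3)
  expect_equal(nrow(rep$excluded), 3)
  got <- rep$table
  expect_equal(got$n_used[got$metric == "hypoperfusion_ml"], 29)
  expect_equal(got$n_used[got$metric == "core_ml"], 28)
  expect_equal(got$loa_low, got$bias - 1.96 * got$sd)
  expect_equal(got$loa_high, got$bias + 1.96 * got$sd)
})

test_that("a cohort with no usable pairs reports its status explicitly", {
  tab <- data.frame(pair_id = 1:4, scenario = "new_occlusion",
    interval_h = 2, core_ml_1 = 1, core_ml_2 = 2)
  rep <- cohort_report(tab)
  expect_equal(rep$status, "no usable pairs")
  expect_null(rep$table)
})
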