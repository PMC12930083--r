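# Forward model: per voxel, attenuation(t) = baseline_HU +
# kappa * CBF * (AIF (*) R)(t - delay) + Gaussian noise, with residue
# R(t) = exp(-t/MTT) optionally dispersed by an exponential kernel.
# kappa converts CBF from mL/100g/min to a per-second fractional flow
# (unit tissue density assumed): kappa = 1/6000 s^-1 per (mL/100g/min).
KAPPA_CBF <- 1 / 6000

#' Dynamic series container
#'
#' A 4-D attenuation volume (HU) with its time axis and geometry. Fewer
#' than 8 frames is an error; fewer than 15 triggers a warning since
#' deconvolution becomes unreliable.
#'
#' @param data 4-D numeric array, axes x, y, z, t.
#' @param time_axis_s strictly increasing frame times in seconds.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param acquisition_time acquisition timestamp string, `"HHMMSS.ffffff"`.
#' @param z_origin_mm z position of the first slice relative to the nominal
#'   phantom grid (non-zero after a coverage shift).
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, time_axis_s, voxel_size_mm,
                           acquisition_time = "080000.000000",
                           z_origin_mm = 0) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(time_axis_s))
  if (any(diff(time_axis_s) <= 0)) stop("time axis must be strictly increasing")
  nt <- length(time_axis_s)
  if (nt < 8L) stop("dynamic series needs at least 8 time points")
  if (nt < 15L) warning("fewer than 15 time points: deconvolution may be unreliable")
  dts <- diff(time_axis_s)
  if ((max(dts) - min(dts)) > 0.25 * stats::median(dts)) {
    warning("temporal sampling jitter exceeds 25% of the median frame interval")
  }
  structure(list(
    data = data,
    time_axis_s = as.numeric(time_axis_s),
    voxel_size_mm = as.numeric(voxel_size_mm),
    acquisition_time = acquisition_time,
    z_origin_mm = z_origin_mm
  ), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf(
    "<dynamic_series> %s voxels x %d frames, dt %.2g s, t = [%.4g, %.4g] s\n",
    paste(dim(x$data)[1:3], collapse = "x"), length(x$time_axis_s),
    stats::median(diff(x$time_axis_s)), min(x$time_axis_s), max(x$time_axis_s)
  ))
  invisible(x)
}

# Noise-free tissue enhancement curve on the scan time axis, computed by
# fine-grid convolution of the AIF with the (dispersed) residue and shifted
# by the bolus delay.  cbf in mL/100g/min.
#' @noRd
tissue_enhancement <- function(time_axis, aif_params, cbf, mtt, delay, dispersion,
                               allow_truncation = FALSE, dt_fine = 0.05) {
  tf <- seq(0, max(time_axis), by = dt_fine)
  aif_f <- make_aif(aif_params, tf, allow_truncation = allow_truncation)
  r_f <- residue_curve(tf, mtt, dispersion)
  conv <- dt_fine * stats::convolve(aif_f, rev(r_f), type = "open")[seq_along(tf)]
  KAPPA_CBF * cbf * stats::approx(tf, conv, xout = time_axis - delay,
    yleft = 0, rule = 2)$y
}

#' Simulate a dynamic CTP acquisition of the phantom
#'
#' Generates the 4-D attenuation series implied by the ground-truth maps:
#' tissue voxels follow the indicator-dilution forward model, the arterial
#' cluster carries the undelayed input function and the venous cluster a
#' delayed, amplified copy; i.i.d. Gaussian noise is added everywhere.
#' Identical seeds give bit-identical output.
#'
#' @param truth a [build_phantom()] result.
#' @param spec the generating [phantom_spec()] (defaults to the one stored
#'   in `truth`).
#' @param seed random seed for the noise realization.
#' @param noise_sd noise standard deviation in HU (default from the spec).
#' @param duration_s scan duration override, s.
#' @param aif_params input-function override (used by bolus-truncation
#'   scenarios).
#' @param z_shift integer slice shift of the acquisition window along z.
#' @param allow_truncation passed to [make_aif()].
#' @param acquisition_time timestamp string recorded in the series.
#' @return A [dynamic_series()].
#' @export
simulate_ctp_series <- function(truth, spec = truth$spec, seed = spec$seed,
                                noise_sd = spec$noise_sd,
                                duration_s = spec$duration_s,
                                aif_params = spec$aif_params,
                                z_shift = 0L,
                                allow_truncation = FALSE,
                                acquisition_time = "080000.000000") {
  stopifnot(inherits(truth, "phantom_truth"))
  if (any(truth$true_cbf < 0, na.rm = TRUE)) stop("negative CBF in ground truth")
  if (any(truth$true_mtt <= 0, na.rm = TRUE)) stop("non-positive MTT in ground truth")
  time_axis <- seq(0, duration_s, by = spec$dt_s)
  dim3 <- truth$dim
  nvox <- prod(dim3)
  nt <- length(time_axis)

  flat <- matrix(rep(as.vector(truth$baseline_hu), nt), nrow = nvox)

  tissue <- truth$brain_mask & !(truth$artery_mask | truth$vein_mask) &
    !is.na(truth$true_cbf)
  key <- paste(truth$true_cbf, truth$true_mtt, truth$true_delay,
    truth$true_dispersion)[tissue]
  vox_idx <- which(tissue)
  for (k in unique(key)) {
    sel <- vox_idx[key == k]
    p <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
    if (p[1] > 0) {
      curve <- tissue_enhancement(time_axis, aif_params,
        cbf = p[1], mtt = p[2], delay = p[3], dispersion = p[4],
        allow_truncation = allow_truncation)
      flat[sel, ] <- flat[sel, ] + rep(curve, each = length(sel))
    }
  }

  vs <- spec$vessel
  art_curve <- make_aif(aif_params, time_axis, allow_truncation = allow_truncation)
  vein_curve <- vs$vein_scale *
    make_aif(modifyList(aif_params, list(t0 = aif_params$t0 + vs$vein_delay_s)),
      time_axis, allow_truncation = TRUE)
  flat[which(truth$artery_mask), ] <-
    flat[which(truth$artery_mask), , drop = FALSE] +
    rep(art_curve, each = sum(truth$artery_mask))
  flat[which(truth$vein_mask), ] <-
    flat[which(truth$vein_mask), , drop = FALSE] +
    rep(vein_curve, each = sum(truth$vein_mask))

  arr <- array(flat, dim = c(dim3, nt))
  if (z_shift != 0L) arr <- shift_z(arr, z_shift, fill = 0)
  if (noise_sd > 0) {
    arr <- arr + with_seed(seed, array(stats::rnorm(length(arr), sd = noise_sd),
      dim = dim(arr)))
  }
  dynamic_series(arr, time_axis, truth$voxel_size_mm,
    acquisition_time = acquisition_time,
    z_origin_mm = z_shift * truth$voxel_size_mm[3])
}

#' Simulate a non-contrast CT of the phantom
#'
#' Baseline tissue HU with infarct-core voxels lowered by
#' `core_hypodensity_hu`, plus Gaussian noise.
#'
#' @inheritParams simulate_ctp_series
#' @param core_hypodensity_hu HU decrease inside the true core (>= 0).
#' @param noise_sd NCCT noise standard deviation, HU.
#' @return A 3-D HU array with attributes `voxel_size_mm`, `z_origin_mm`
#'   and `affected_regions` (atlas regions majority-covered by the core).
#' @export
simulate_ncct <- function(truth, spec = truth$spec, seed = spec$seed + 1L,
                          core_hypodensity_hu = spec$core_hypodensity_hu,
                          noise_sd = spec$ncct_noise_sd,
                          z_shift = 0L) {
  stopifnot(inherits(truth, "phantom_truth"), core_hypodensity_hu >= 0)
  vol <- truth$baseline_hu
  vol[truth$core_mask] <- vol[truth$core_mask] - core_hypodensity_hu
  if (z_shift != 0L) vol <- shift_z(vol, z_shift, fill = 0)
  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(stats::rnorm(length(vol), sd = noise_sd),
      dim = dim(vol)))
  }
  attr(vol, "voxel_size_mm") <- truth$voxel_size_mm
  attr(vol, "z_origin_mm") <- z_shift * truth$voxel_size_mm[3]
  attr(vol, "affected_regions") <- affected_atlas_regions(truth$atlas, truth$core_mask)
  vol
}

#' Scan-pair scenarios
#'
#' Names of the supported repeated-scan scenarios: `stable` (identical
#' ground truth, fresh noise), the disruptive events `new_occlusion`
#' (additional 20 mL hypoperfused territory) and `thrombus_migration`
#' (lesion relocated), and the technical failure modes `bolus_truncation`
#' (second scan ends while the input function is still far above baseline),
#' `coverage_shift` (acquisition window moved along z) and `high_noise`
#' (noise standard deviation multiplied).
#' @export
SCAN_SCENARIOS <- c("stable", "new_occlusion", "thrombus_migration",
  "bolus_truncation", "coverage_shift", "high_noise")

#' Scenarios treated as disruptive cerebrovascular events
#' @export
DISRUPTIVE_SCENARIOS <- c("new_occlusion", "thrombus_migration")

#' @noRd
format_hhmmss <- function(hours) {
  hours <- hours %% 24
  h <- floor(hours)
  m <- floor((hours - h) * 60)
  s <- (hours - h) * 3600 - m * 60
  sprintf("%02d%02d%09.6f", h, m, s)
}

#' Generate a repeated-scan pair
#'
#' Builds two CTP + NCCT acquisitions of the same synthetic patient under a
#' named scenario. Both scans share the hemodynamic ground truth (scenario
#' permitting) but have independent noise realizations; acquisition
#' timestamps are `interval_h` hours apart.
#'
#' Scenario specifics: `new_occlusion` adds a second, disjoint hypoperfused
#' territory whose voxelized volume matches `growth_ml` to within one
#' voxel; `thrombus_migration` moves the lesion 15 mm posteriorly;
#' `bolus_truncation` delays the bolus of scan 2 by 20 s and shortens the
#' scan to 38 s, so the input function is still at roughly 30 % of its peak
#' at the last frame; `coverage_shift` moves the scan-2 acquisition window
#' by `shift_slices` slices along z; `high_noise` multiplies the scan-2
#' noise SD by `noise_factor`.
#'
#' @param spec a [phantom_spec()].
#' @param scenario one of [SCAN_SCENARIOS].
#' @param interval_h inter-scan interval in hours, in (0.6, 9); drawn
#'   uniformly from (0.7, 8.9) when `NULL`.
#' @param seed integer seed controlling all randomness of the pair.
#' @param growth_ml added hypoperfusion volume for `new_occlusion`, mL.
#' @param shift_slices z shift for `coverage_shift`, slices.
#' @param noise_factor multiplier for `high_noise`.
#' @param truth optional pre-built [build_phantom()] result for `spec`
#'   (avoids rebuilding the same ground truth for every pair of a
#'   cohort).
#' @return A list of class `scan_pair` with elements `scan1`, `scan2`
#'   (each `ctp`, `ncct`, `acquisition_time`), `truth1`, `truth2`,
#'   `scenario`, `interval_h`, `seed`.
#' @examples
#' pair <- make_scan_pair(phantom_spec(), "stable", interval_h = 3, seed = 1)
#' identical(pair$truth1$hypoperfusion_mask, pair$truth2$hypoperfusion_mask)
#' @export
make_scan_pair <- function(spec, scenario = "stable", interval_h = NULL,
                           seed = spec$seed, growth_ml = 20,
                           shift_slices = 4L, noise_factor = 2.5,
                           truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!scenario %in% SCAN_SCENARIOS) {
    stop("unknown scenario '", scenario, "'; expected one of: ",
      paste(SCAN_SCENARIOS, collapse = ", "))
  }
  if (is.null(interval_h)) {
    interval_h <- with_seed(seed * 8L + 5L, stats::runif(1, 0.7, 8.9))
  }
  if (interval_h <= 0.6 || interval_h >= 9) {
    stop("interval_h must lie in (0.6, 9) hours")
  }

  truth1 <- truth %||% build_phantom(spec)
  spec2 <- spec
  z_shift2 <- 0L
  noise_sd2 <- spec$noise_sd
  duration2 <- spec$duration_s
  aif2 <- spec$aif_params
  allow_trunc <- FALSE

  if (scenario == "new_occlusion") {
    extra <- lesion_component(
      center_mm = c(-27, -48, 0),
      penumbra_radii_mm = c(17, 17, 17),
      penumbra_target_ml = growth_ml,
      include_core = FALSE
    )
    spec2$lesion <- c(spec$lesion %||% list(), list(extra))
  } else if (scenario == "thrombus_migration") {
    spec2$lesion <- lapply(spec$lesion %||% list(), function(comp) {
      comp$center_mm <- comp$center_mm + c(0, -15, 0)
      comp
    })
  } else if (scenario == "bolus_truncation") {
    aif2$t0 <- aif2$t0 + 20
    duration2 <- 38
    allow_trunc <- TRUE
  } else if (scenario == "coverage_shift") {
    z_shift2 <- as.integer(shift_slices)
  } else if (scenario == "high_noise") {
    noise_sd2 <- spec$noise_sd * noise_factor
  }

  truth2 <- if (scenario %in% DISRUPTIVE_SCENARIOS) build_phantom(spec2) else truth1

  t1 <- 8  # first acquisition nominally at 08:00
  t2 <- t1 + interval_h
  scan1 <- list(
    ctp = simulate_ctp_series(truth1, spec, seed = seed * 8L + 1L,
      acquisition_time = format_hhmmss(t1)),
    ncct = simulate_ncct(truth1, spec, seed = seed * 8L + 2L),
    acquisition_time = format_hhmmss(t1)
  )
  scan2 <- list(
    ctp = simulate_ctp_series(truth2, spec2, seed = seed * 8L + 3L,
      noise_sd = noise_sd2, duration_s = duration2, aif_params = aif2,
      z_shift = z_shift2, allow_truncation = allow_trunc,
      acquisition_time = format_hhmmss(t2)),
    ncct = simulate_ncct(truth2, spec2, seed = seed * 8L + 4L,
      z_shift = z_shift2),
    acquisition_time = format_hhmmss(t2)
  )

  structure(list(
    scan1 = scan1, scan2 = scan2,
    truth1 = truth1, truth2 = truth2,
    scenario = scenario, interval_h = interval_h, seed = seed
  ), class = "scan_pair")
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("<scan_pair> scenario '%s', interval %.2f h, seed %d\n",
    x$scenario, x$interval_h, x$seed))
  invisible(x)
}
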