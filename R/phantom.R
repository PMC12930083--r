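#' Gamma-variate arterial input function
#'
#' Evaluates a gamma-variate bolus curve on a time axis. The curve is zero
#' up to the onset `t0` and follows `(t - t0)^alpha * exp(-(t - t0)/beta)`
#' afterwards, scaled so that its analytic peak (at `t0 + alpha * beta`)
#' equals `amplitude` HU.
#'
#' @param aif_params list with `amplitude` (peak enhancement, HU), `t0`
#'   (onset, s), `alpha` (shape, > 0) and `beta` (scale, s, > 0).
#' @param t strictly increasing time axis in seconds.
#' @param allow_truncation if `FALSE` (default) a curve whose analytic peak
#'   falls after the last sample is rejected, since such a scan cannot
#'   capture the bolus; scenario generators that deliberately truncate the
#'   bolus set this to `TRUE`.
#' @return Numeric vector of enhancement values (HU), same length as `t`.
#' @examples
#' t <- seq(0, 50, by = 2)
#' aif <- make_aif(list(amplitude = 200, t0 = 8, alpha = 3, beta = 1.5), t)
#' t[which.max(aif)]  # close to 8 + 3 * 1.5
#' @export
make_aif <- function(aif_params, t, allow_truncation = FALSE) {
  p <- aif_params
  stopifnot(
    is_scalar_number(p$amplitude), is_scalar_number(p$t0),
    is_scalar_number(p$alpha), is_scalar_number(p$beta)
  )
  if (p$alpha <= 0 || p$beta <= 0) stop("gamma-variate requires alpha > 0 and beta > 0")
  if (length(t) < 2L || any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  t_peak <- p$t0 + p$alpha * p$beta
  if (t_peak > max(t) && !allow_truncation) {
    stop("AIF peak (", round(t_peak, 2), " s) falls after the last sample: bolus truncated")
  }
  tau <- t - p$t0
  y <- numeric(length(t))
  pos <- tau > 0
  # normalized so the analytic maximum equals `amplitude`
  y[pos] <- p$amplitude * (tau[pos] / (p$alpha * p$beta))^p$alpha *
    exp(p$alpha - tau[pos] / p$beta)
  y
}

# Tissue residue (optionally dispersed): R(t) = exp(-t/mtt), convolved with
# a normalized exponential kernel exp(-t/tau)/tau when tau > 0.  Evaluated
# on an arbitrary non-negative time axis by fine-grid quadrature.
#' @noRd
residue_curve <- function(t, mtt, dispersion = 0) {
  stopifnot(mtt > 0, dispersion >= 0)
  if (dispersion == 0) return(exp(-pmax(t, 0) / mtt) * (t >= 0))
  if (abs(dispersion - mtt) < 1e-9) {
    # confluent case: (t/mtt^2) * exp(-t/mtt) ... normalized kernel convolution
    return(ifelse(t >= 0, (t / mtt^2) * exp(-t / mtt) * mtt, 0))
  }
  # closed form of exp(-t/mtt) * exp(-t/tau)/tau
  a <- 1 / mtt; b <- 1 / dispersion
  ifelse(t >= 0, (b / (b - a)) * (exp(-a * t) - exp(-b * t)), 0)
}

# Time offset of the residue peak relative to bolus delay; zero for the
# undispersed mono-exponential residue (which peaks at t = 0).
#' @noRd
residue_peak_offset <- function(mtt, dispersion = 0) {
  if (dispersion <= 0) return(0)
  tf <- seq(0, 6 * (mtt + dispersion), by = 0.01)
  tf[which.max(residue_curve(tf, mtt, dispersion))]
}

#' Describe one ischemic lesion of the phantom
#'
#' A lesion is an ellipsoidal hypoperfused region (the penumbra in mismatch
#' terminology) optionally containing a concentric infarct-core ellipsoid.
#' Perfusion inside a lesion is uniform: CBF is the stated fraction of the
#' grey-matter reference value and MTT is prolonged reciprocally (capped),
#' with the bolus delayed by `*_delay_s` and optionally dispersed.
#'
#' When a `*_target_ml` volume is given the region is built as exactly the
#' voxels closest to the centre in the ellipsoid metric, with the count
#' chosen to match the target volume to within one voxel; the core then
#' reuses the penumbra metric so that nesting is guaranteed.
#'
#' @param center_mm lesion centre in mm relative to the grid centre
#'   (x = left-right with the midline at 0, y = anterior-posterior,
#'   z = axial).
#' @param penumbra_radii_mm,core_radii_mm ellipsoid semi-axes in mm.
#' @param penumbra_delay_s,core_delay_s bolus delay in seconds.
#' @param penumbra_dispersion_s,core_dispersion_s exponential dispersion
#'   time constant in seconds (0 = off).
#' @param penumbra_cbf_fraction,core_cbf_fraction CBF as a fraction of the
#'   grey-matter reference, in (0, 1].
#' @param penumbra_target_ml,core_target_ml optional exact target volumes.
#' @param include_core logical; `FALSE` builds a pure hypoperfusion lesion.
#' @param mtt_cap_s upper bound for the prolonged lesion MTT.
#' @return A list of class `lesion_component`.
#' @export
lesion_component <- function(center_mm = c(-52, 0, 0),
                             penumbra_radii_mm = c(21, 24, 18),
                             penumbra_delay_s = 8,
                             penumbra_dispersion_s = 0,
                             penumbra_cbf_fraction = 0.65,
                             penumbra_target_ml = NULL,
                             core_radii_mm = c(17, 19, 13),
                             core_delay_s = 10,
                             core_dispersion_s = 0,
                             core_cbf_fraction = 0.15,
                             core_target_ml = NULL,
                             include_core = TRUE,
                             mtt_cap_s = 12) {
  comp <- list(
    center_mm = center_mm,
    penumbra = list(
      radii_mm = penumbra_radii_mm, delay_s = penumbra_delay_s,
      dispersion_s = penumbra_dispersion_s,
      cbf_fraction = penumbra_cbf_fraction, target_ml = penumbra_target_ml
    ),
    core = if (include_core) list(
      radii_mm = core_radii_mm, delay_s = core_delay_s,
      dispersion_s = core_dispersion_s,
      cbf_fraction = core_cbf_fraction, target_ml = core_target_ml
    ),
    mtt_cap_s = mtt_cap_s
  )
  for (part in c("penumbra", "core")) {
    p <- comp[[part]]
    if (is.null(p)) next
    if (p$cbf_fraction <= 0 || p$cbf_fraction > 1) {
      stop("CBF fractions must lie in (0, 1]")
    }
    if (p$delay_s < 0 || p$dispersion_s < 0) stop("delay and dispersion must be >= 0")
  }
  class(comp) <- "lesion_component"
  comp
}

#' Phantom specification
#'
#' Defines the geometry, hemodynamics and acquisition parameters of the
#' digital CTP/NCCT head phantom: a two-hemisphere ellipsoidal brain with a
#' grey-matter shell around a white-matter centre, small arterial and venous
#' voxel clusters carrying the (scaled/delayed) input function, and zero or
#' more ischemic lesions.  Acquisition timing is constrained to the
#' clinically typical envelope (temporal sampling 1.5-3.5 s, scan duration
#' 38-55 s).
#'
#' @param grid_shape integer triple of voxels (x, y, z).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param dt_s temporal sampling in seconds, within \[1.5, 3.5\].
#' @param duration_s scan duration in seconds, within \[38, 55\].
#' @param aif_params gamma-variate parameters, see [make_aif()].
#' @param tissue_params per-class hemodynamics: lists `gm` and `wm` with
#'   `cbf` (mL/100g/min), `mtt` (s) and `baseline_hu`.
#' @param lesion a `lesion_component`, a list of them, or `NULL` for a
#'   lesion-free phantom.
#' @param noise_sd additive Gaussian CTP noise, HU.
#' @param ncct_noise_sd additive Gaussian NCCT noise, HU.
#' @param core_hypodensity_hu HU decrease of infarct-core tissue on NCCT.
#' @param brain_radii_mm semi-axes of the brain ellipsoid, mm.
#' @param wm_scale linear scale of the white-matter ellipsoid relative to
#'   the brain ellipsoid.
#' @param normal_delay_s bolus delay of normally perfused tissue, s.
#' @param seed default random seed for simulations from this spec.
#' @return A validated list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(seed = 7)
#' truth <- build_phantom(spec)
#' sum(truth$core_mask) <= sum(truth$hypoperfusion_mask)
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         voxel_size_mm = c(3, 3, 4),
                         dt_s = 2,
                         duration_s = 50,
                         aif_params = list(amplitude = 350, t0 = 8, alpha = 3, beta = 1.5),
                         tissue_params = list(
                           gm = list(cbf = 60, mtt = 4, baseline_hu = 35),
                           wm = list(cbf = 25, mtt = 5, baseline_hu = 28)
                         ),
                         lesion = lesion_component(),
                         noise_sd = 2,
                         ncct_noise_sd = 1.5,
                         core_hypodensity_hu = 5,
                         brain_radii_mm = c(81, 87, 42),
                         wm_scale = 0.62,
                         normal_delay_s = 0.5,
                         seed = 1L) {
  if (dt_s < 1.5 || dt_s > 3.5) stop("dt_s must lie in [1.5, 3.5] s")
  if (duration_s < 38 || duration_s > 55) stop("duration_s must lie in [38, 55] s")
  if (noise_sd < 0 || ncct_noise_sd < 0) stop("noise standard deviations must be >= 0")
  if (core_hypodensity_hu < 0) stop("core_hypodensity_hu must be >= 0")
  if (inherits(lesion, "lesion_component")) lesion <- list(lesion)
  if (!is.null(lesion)) {
    stopifnot(all(vapply(lesion, inherits, logical(1), "lesion_component")))
  }
  spec <- list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    dt_s = dt_s,
    duration_s = duration_s,
    aif_params = aif_params,
    tissue_params = tissue_params,
    lesion = lesion,
    noise_sd = noise_sd,
    ncct_noise_sd = ncct_noise_sd,
    core_hypodensity_hu = core_hypodensity_hu,
    brain_radii_mm = brain_radii_mm,
    wm_scale = wm_scale,
    normal_delay_s = normal_delay_s,
    # fixed vessel plumbing: a small arterial cluster carrying the undelayed
    # AIF and a venous cluster with a delayed, amplified curve
    vessel = list(
      artery_offset_mm = c(0, -60, -20),
      vein_offset_mm = c(0, 63, -16),
      block_voxels = c(4L, 3L, 2L),
      artery_baseline_hu = 45,
      vein_baseline_hu = 45,
      vein_scale = 1.3,
      vein_delay_s = 3.5
    ),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

# Rectangular cluster of voxels centred at a mm offset from the grid centre.
#' @noRd
block_mask <- function(dim, voxel_size, center_mm, block_voxels) {
  ctr <- (dim + 1) / 2 + center_mm / voxel_size
  out <- array(FALSE, dim)
  rng <- lapply(1:3, function(a) {
    i <- seq(round(ctr[a] - (block_voxels[a] - 1) / 2), length.out = block_voxels[a])
    i[i >= 1 & i <= dim[a]]
  })
  out[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  out
}

# Region mask for one lesion part (penumbra or core).
#' @noRd
lesion_part_mask <- function(dim, voxel_size, center_mm, part, metric_radii = NULL) {
  radii <- metric_radii %||% part$radii_mm
  if (!is.null(part$target_ml)) {
    n <- max(1L, round(part$target_ml * 1000 / prod(voxel_size)))
    nearest_n_mask(dim, voxel_size, center_mm, radii, n)
  } else {
    ellipsoid_mask(dim, voxel_size, center_mm, part$radii_mm)
  }
}

#' Build the phantom ground truth
#'
#' Voxelizes a [phantom_spec()] into ground-truth maps and masks: true CBF,
#' MTT, bolus delay and dispersion, the true Tmax (delay plus the peak
#' offset of the possibly dispersed residue, evaluated numerically), the
#' hypoperfusion and core truth masks obtained by applying the standard
#' thresholds (Tmax > 6 s, rCBF < 30 % of the normal-tissue median) to the
#' true maps, a 10-region-per-hemisphere ASPECTS-style atlas that is
#' mirror-symmetric across the midsagittal plane, and the set of atlas
#' regions whose voxels are majority-covered by the core.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_truth`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dim <- spec$grid_shape
  vox <- spec$voxel_size_mm

  brain <- ellipsoid_mask(dim, vox, c(0, 0, 0), spec$brain_radii_mm)
  wm <- ellipsoid_mask(dim, vox, c(0, 0, 0), spec$brain_radii_mm * spec$wm_scale)
  gm <- brain & !wm

  vs <- spec$vessel
  artery <- block_mask(dim, vox, vs$artery_offset_mm, vs$block_voxels) & brain
  vein <- block_mask(dim, vox, vs$vein_offset_mm, vs$block_voxels) & brain
  if (!any(artery) || !any(vein)) stop("vessel clusters fall outside the brain")
  vessel <- artery | vein
  tissue <- brain & !vessel

  tp <- spec$tissue_params
  true_cbf <- array(NA_real_, dim)
  true_mtt <- array(NA_real_, dim)
  true_delay <- array(NA_real_, dim)
  true_disp <- array(NA_real_, dim)
  baseline_hu <- array(0, dim)
  true_cbf[gm & tissue] <- tp$gm$cbf
  true_cbf[wm & tissue] <- tp$wm$cbf
  true_mtt[gm & tissue] <- tp$gm$mtt
  true_mtt[wm & tissue] <- tp$wm$mtt
  true_delay[tissue] <- spec$normal_delay_s
  true_disp[tissue] <- 0
  baseline_hu[gm] <- tp$gm$baseline_hu
  baseline_hu[wm] <- tp$wm$baseline_hu
  baseline_hu[artery] <- vs$artery_baseline_hu
  baseline_hu[vein] <- vs$vein_baseline_hu

  hypo_truth <- array(FALSE, dim)
  core_truth <- array(FALSE, dim)
  ref_cbf <- tp$gm$cbf
  for (comp in spec$lesion %||% list()) {
    pen <- lesion_part_mask(dim, vox, comp$center_mm, comp$penumbra)
    if (!any(pen) || any(pen & !tissue)) {
      stop("lesion outside brain (or overlapping a vessel cluster)")
    }
    core <- NULL
    if (!is.null(comp$core)) {
      core <- lesion_part_mask(dim, vox, comp$center_mm, comp$core,
        metric_radii = if (!is.null(comp$core$target_ml)) comp$penumbra$radii_mm
      )
      core <- core & pen
      if (!any(core)) stop("lesion core region is empty after nesting inside the penumbra")
    }
    for (part_name in c("penumbra", "core")) {
      part <- comp[[part_name]]
      if (is.null(part)) next
      m <- if (part_name == "penumbra") pen else core
      true_cbf[m] <- part$cbf_fraction * ref_cbf
      true_mtt[m] <- min(tp$gm$mtt / part$cbf_fraction, comp$mtt_cap_s)
      true_delay[m] <- part$delay_s
      true_disp[m] <- part$dispersion_s
    }
    hypo_truth <- hypo_truth | pen
    if (!is.null(core)) core_truth <- core_truth | core
  }

  # true Tmax per unique (mtt, dispersion) combination
  true_tmax <- array(NA_real_, dim)
  combos <- unique(data.frame(
    mtt = true_mtt[tissue], disp = true_disp[tissue], delay = true_delay[tissue]
  ))
  for (i in seq_len(nrow(combos))) {
    sel <- tissue & !is.na(true_mtt) &
      true_mtt == combos$mtt[i] & true_disp == combos$disp[i] &
      true_delay == combos$delay[i]
    true_tmax[sel] <- combos$delay[i] + residue_peak_offset(combos$mtt[i], combos$disp[i])
  }

  normal_set <- tissue & !is.na(true_tmax) & true_tmax < 4
  ref_median <- stats::median(true_cbf[normal_set])
  rcbf_true <- 100 * true_cbf / ref_median

  hypoperfusion_mask <- tissue & !is.na(true_tmax) & true_tmax > 6
  core_mask <- hypoperfusion_mask & !is.na(rcbf_true) & rcbf_true < 30

  atlas <- build_aspects_atlas(brain, vessel, dim, vox)
  affected <- affected_atlas_regions(atlas, core_mask)

  structure(list(
    spec = spec,
    dim = dim,
    voxel_size_mm = vox,
    brain_mask = brain,
    gm_mask = gm & tissue,
    wm_mask = wm & tissue,
    artery_mask = artery,
    vein_mask = vein,
    baseline_hu = baseline_hu,
    true_cbf = true_cbf,
    true_mtt = true_mtt,
    true_delay = true_delay,
    true_dispersion = true_disp,
    true_tmax = true_tmax,
    rcbf_true = rcbf_true,
    normal_reference_cbf = ref_median,
    hypoperfusion_mask = hypoperfusion_mask,
    core_mask = core_mask,
    atlas = atlas,
    affected_regions = affected
  ), class = "phantom_truth")
}

# Geometric 10-region-per-hemisphere surrogate of the ASPECTS atlas:
# ganglionic (lower) slab split into a medial strip (y-quartiles -> I, IC,
# L, C from posterior to anterior) and a lateral strip (y-terciles -> M3,
# M2, M1); supraganglionic slab split into y-terciles (M6, M5, M4).
# Left labels 1..10, right labels 11..20; mirror-symmetric by construction
# because every rule depends only on |x|, y and z.
#' @noRd
build_aspects_atlas <- function(brain, vessel, dim, vox) {
  co <- coord_arrays(dim, vox)
  tissue <- brain & !vessel
  labels <- array(0L, dim)
  region_names <- c("C", "L", "IC", "I", "M1", "M2", "M3", "M4", "M5", "M6")

  gang <- co$z < 0
  absx <- abs(co$x)
  left_gang <- tissue & gang & co$x < 0
  d_med <- stats::median(absx[left_gang])
  medial <- absx <= d_med

  assign_band <- function(sel, cuts_probs, names_order) {
    # y-band cuts computed on the left hemisphere, applied to both sides
    ys <- co$y[sel & co$x < 0]
    cuts <- stats::quantile(ys, probs = cuts_probs, names = FALSE)
    band <- findInterval(co$y, cuts, rightmost.closed = FALSE) + 1L
    list(band = band, names = names_order)
  }

  region_of <- array(NA_integer_, dim)
  med_sel <- tissue & gang & medial
  b <- assign_band(med_sel, c(0.25, 0.5, 0.75), c("I", "IC", "L", "C"))
  region_of[med_sel] <- match(b$names, region_names)[b$band[med_sel]]
  lat_sel <- tissue & gang & !medial
  b <- assign_band(lat_sel, c(1 / 3, 2 / 3), c("M3", "M2", "M1"))
  region_of[lat_sel] <- match(b$names, region_names)[b$band[lat_sel]]
  sup_sel <- tissue & !gang
  b <- assign_band(sup_sel, c(1 / 3, 2 / 3), c("M6", "M5", "M4"))
  region_of[sup_sel] <- match(b$names, region_names)[b$band[sup_sel]]

  left <- co$x < 0
  labels[!is.na(region_of)] <- region_of[!is.na(region_of)] +
    ifelse(left[!is.na(region_of)], 0L, 10L)

  name_table <- data.frame(
    label = 1:20,
    side = rep(c("L", "R"), each = 10),
    region = rep(region_names, 2),
    stringsAsFactors = FALSE
  )
  list(labels = labels, names = name_table, region_names = region_names)
}

# Atlas regions whose voxels are majority-covered (> overlap_frac) by the
# core; median-based region statistics only shift once most of a region is
# involved, hence the 0.5 default.
#' @noRd
affected_atlas_regions <- function(atlas, core_mask, overlap_frac = 0.5) {
  out <- character(0)
  for (i in seq_len(nrow(atlas$names))) {
    lab <- atlas$names$label[i]
    sel <- atlas$labels == lab
    n <- sum(sel)
    if (n > 0 && sum(core_mask[sel]) / n > overlap_frac) {
      out <- c(out, paste0(atlas$names$side[i], ":", atlas$names$region[i]))
    }
  }
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  vml <- prod(x$voxel_size_mm) / 1000
  cat("<phantom_truth>\n")
  cat(sprintf("  grid             %s voxels at %s mm\n",
    paste(x$dim, collapse = "x"), paste(x$voxel_size_mm, collapse = "x")))
  cat(sprintf("  brain            %.0f mL\n", sum(x$brain_mask) * vml))
  cat(sprintf("  hypoperfusion    %.1f mL (truth)\n", sum(x$hypoperfusion_mask) * vml))
  cat(sprintf("  infarct core     %.1f mL (truth)\n", sum(x$core_mask) * vml))
  cat(sprintf("  affected regions %s\n",
    if (length(x$affected_regions)) paste(x$affected_regions, collapse = ", ") else "none"))
  invisible(x)
}
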