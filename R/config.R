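#' Analysis configuration
#'
#' Collects every tunable of the quantification pipeline in one object.
#' Defaults follow the field-standard values where such values exist
#' (hypoperfusion at Tmax > 6 s, infarct core at rCBF < 30 %, normal tissue
#' at Tmax < 4 s, ASPECTS flag at an inter-hemispheric difference
#' > 2.25 HU); the remaining knobs are documented package choices.
#' A serialized copy of the configuration (plus an MD5 hash and the package
#' version) is embedded in every report for provenance.
#'
#' @param tmax_hypoperfusion_s Tmax threshold (s) above which tissue counts
#'   as hypoperfused (strict inequality).
#' @param rcbf_core_pct relative-CBF threshold (percent of normal tissue)
#'   below which hypoperfused tissue counts as infarct core (strict).
#' @param tmax_normal_s Tmax (s) below which tissue defines the normally
#'   perfused reference used for CBF/CBV normalization.
#' @param aspects_delta_hu inter-hemispheric HU difference above which an
#'   ASPECTS region is flagged abnormal (strict).
#' @param lambda_rel Tikhonov regularization expressed as a fraction of the
#'   largest singular value of the convolution matrix. The 0.12 default was
#'   calibrated once on the phantom's parameter-recovery behaviour (see the
#'   methods vignette); heavier regularization biases CBF down and Tmax up.
#' @param circulant use the delay-insensitive block-circulant formulation
#'   (default) rather than the plain lower-triangular Toeplitz one.
#' @param quadrature convolution-matrix discretization, see
#'   [deconvolve_matrix()].
#' @param smoothing_fwhm_mm spatial Gaussian smoothing FWHM per frame, in
#'   mm (0 disables), for the timing path (Tmax). Kept light so that the
#'   Tmax lesion boundary is not displaced by partial-volume mixing. The
#'   AIF is always selected from the unsmoothed series to avoid
#'   partial-volume dilution of the arterial peak.
#' @param cbf_smoothing_fwhm_mm smoothing FWHM in mm for the flow path
#'   (CBF/CBV). Heavier than the timing path: flow ratios against the
#'   30 % core threshold need low voxel noise, while their boundaries are
#'   constrained to the hypoperfused region anyway.
#' @param cbf_lambda_rel regularization for the flow path; smaller than
#'   `lambda_rel` because its input is strongly denoised, which keeps the
#'   CBF amplitude bias low.
#' @param map_filter denoising applied to the computed maps:
#'   `"median"` (default; masked 26-neighbourhood median filter, an
#'   edge-preserving way to suppress voxelwise deconvolution noise) or
#'   `"none"`.
#' @param cbf_bias_correction logical, see [compute_maps()].
#' @param motion_correction logical; rigid (translation) frame-to-first
#'   registration. Off by default: the phantom does not move.
#' @param arrival_z bolus-arrival rule: first frame whose whole-brain mean
#'   enhancement exceeds `arrival_z` times the pre-bolus standard deviation.
#' @param aif_top_frac fraction of brain voxels (ranked by peak enhancement)
#'   admitted as AIF candidates.
#' @param aif_amplitude_floor_hu minimum peak enhancement (HU) for an AIF
#'   candidate; separates vessel from tissue curves.
#' @param aif_top_k number of top-ranked arterial candidates averaged into
#'   the returned AIF.
#' @param min_cluster_ml minimum lesion cluster size retained after
#'   thresholding, in mL (0 disables the filter).
#' @param restrict_core_to_hypoperfusion logical; require the core to lie
#'   inside the hypoperfused region (standard mismatch-software practice).
#' @param hu_window two HU values bounding brain parenchyma for brain-mask
#'   extraction.
#' @param aspects_stat region summary statistic, `"median"` (default) or
#'   `"trimmed_mean"`.
#' @param aspects_trim trim fraction when `aspects_stat = "trimmed_mean"`.
#' @param alignment_mode atlas alignment, `"identity"` (phantom-space
#'   labels) or `"affine"` (moment-based alignment).
#' @param interval_assoc association between paired differences and
#'   inter-scan interval, `"pearson"` (default) or `"spearman"`.
#' @param bolus_residual_warn_frac flag a scan's bolus coverage as
#'   suboptimal when the last AIF sample exceeds this fraction of its peak.
#'
#' @return An object of class `perfstab_config` (a validated list).
#' @examples
#' cfg <- perfstab_config(lambda_rel = 0.1)
#' cfg$tmax_hypoperfusion_s
#' @export
perfstab_config <- function(tmax_hypoperfusion_s = 6,
                            rcbf_core_pct = 30,
                            tmax_normal_s = 4,
                            aspects_delta_hu = 2.25,
                            lambda_rel = 0.12,
                            circulant = TRUE,
                            quadrature = c("linear", "rect", "simpson"),
                            smoothing_fwhm_mm = 4,
                            cbf_smoothing_fwhm_mm = 9,
                            cbf_lambda_rel = 0.065,
                            map_filter = c("median", "none"),
                            cbf_bias_correction = TRUE,
                            motion_correction = FALSE,
                            arrival_z = 3,
                            aif_top_frac = 0.02,
                            aif_amplitude_floor_hu = 20,
                            aif_top_k = 5,
                            min_cluster_ml = 1,
                            restrict_core_to_hypoperfusion = TRUE,
                            hu_window = c(10, 60),
                            aspects_stat = c("median", "trimmed_mean"),
                            aspects_trim = 0.1,
                            alignment_mode = c("identity", "affine"),
                            interval_assoc = c("pearson", "spearman"),
                            bolus_residual_warn_frac = 0.1) {
  cfg <- list(
    tmax_hypoperfusion_s = tmax_hypoperfusion_s,
    rcbf_core_pct = rcbf_core_pct,
    tmax_normal_s = tmax_normal_s,
    aspects_delta_hu = aspects_delta_hu,
    lambda_rel = lambda_rel,
    circulant = isTRUE(circulant),
    quadrature = match.arg(quadrature),
    smoothing_fwhm_mm = smoothing_fwhm_mm,
    cbf_smoothing_fwhm_mm = cbf_smoothing_fwhm_mm,
    cbf_lambda_rel = cbf_lambda_rel,
    map_filter = match.arg(map_filter),
    cbf_bias_correction = isTRUE(cbf_bias_correction),
    motion_correction = isTRUE(motion_correction),
    arrival_z = arrival_z,
    aif_top_frac = aif_top_frac,
    aif_amplitude_floor_hu = aif_amplitude_floor_hu,
    aif_top_k = as.integer(aif_top_k),
    min_cluster_ml = min_cluster_ml,
    restrict_core_to_hypoperfusion = isTRUE(restrict_core_to_hypoperfusion),
    hu_window = hu_window,
    aspects_stat = match.arg(aspects_stat),
    aspects_trim = aspects_trim,
    alignment_mode = match.arg(alignment_mode),
    interval_assoc = match.arg(interval_assoc),
    bolus_residual_warn_frac = bolus_residual_warn_frac
  )
  stopifnot(
    is_scalar_number(cfg$tmax_hypoperfusion_s), cfg$tmax_hypoperfusion_s > 0,
    is_scalar_number(cfg$rcbf_core_pct), cfg$rcbf_core_pct > 0,
    is_scalar_number(cfg$tmax_normal_s), cfg$tmax_normal_s > 0,
    is_scalar_number(cfg$lambda_rel), cfg$lambda_rel >= 0,
    is_scalar_number(cfg$smoothing_fwhm_mm), cfg$smoothing_fwhm_mm >= 0,
    is_scalar_number(cfg$cbf_smoothing_fwhm_mm), cfg$cbf_smoothing_fwhm_mm >= 0,
    is_scalar_number(cfg$min_cluster_ml), cfg$min_cluster_ml >= 0,
    length(cfg$hu_window) == 2L, cfg$hu_window[1] < cfg$hu_window[2],
    cfg$aif_top_k >= 1L
  )
  class(cfg) <- "perfstab_config"
  cfg
}

#' @export
print.perfstab_config <- function(x, ...) {
  cat("<perfstab_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file whose keys match [perfstab_config()]
#'   arguments.
#' @return A `perfstab_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(perfstab_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(perfstab_config, vals)
}

# Provenance stamp attached to every report.
#' @noRd
config_stamp <- function(config) {
  list(
    config = unclass(config),
    config_md5 = object_md5(unclass(config)),
    package_version = as.character(utils::packageVersion("perfstab"))
  )
}
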