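# Threshold-based segmentation of hypoperfused tissue and infarct core,
# with volumetry in mL.

#' Extract a brain mask from an HU-calibrated volume
#'
#' Voxels inside a parenchymal HU window, reduced to the largest
#' 6-connected component with internal cavities filled. Deterministic.
#'
#' @param volume 3-D HU volume.
#' @param hu_window two HU bounds (default 10-60) enclosing brain
#'   parenchyma and intracranial vessels while excluding air and bone.
#' @param voxel_size_mm voxel size (stored on the result).
#' @return Logical volume.
#' @export
compute_brain_mask <- function(volume, hu_window = c(10, 60),
                               voxel_size_mm = attr(volume, "voxel_size_mm")) {
  m <- volume >= hu_window[1] & volume <= hu_window[2]
  if (!any(m)) stop("empty brain mask: no voxels inside the HU window")
  m <- largest_component3d(m)
  m <- fill_holes3d(m)
  attr(m, "voxel_size_mm") <- voxel_size_mm
  m
}

#' Volume of a binary mask in mL
#'
#' @param mask logical (or 0/1) volume.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return Volume in mL (`count * voxel volume / 1000`).
#' @examples
#' mask_volume_ml(array(TRUE, c(10, 10, 10)), c(1, 1, 1))  # 1 mL
#' @export
mask_volume_ml <- function(mask, voxel_size_mm) {
  sum(mask != 0) * prod(voxel_size_mm) / 1000
}

# Remove 6-connected clusters smaller than min_ml.
#' @noRd
remove_small_clusters <- function(mask, voxel_size_mm, min_ml) {
  if (min_ml <= 0 || !any(mask)) return(mask)
  min_vox <- ceiling(min_ml * 1000 / prod(voxel_size_mm))
  out <- array(FALSE, dim(mask))
  remaining <- mask
  while (any(remaining)) {
    comp <- flood_fill3d(remaining, which(remaining)[1L])
    if (sum(comp) >= min_vox) out <- out | comp
    remaining <- remaining & !comp
  }
  out
}

#' Segment hypoperfusion and infarct core
#'
#' Hypoperfusion is brain tissue with Tmax strictly above
#' `tmax_threshold_s`; infarct core is hypoperfused tissue with rCBF
#' strictly below `rcbf_threshold_pct` (the restriction of core to the
#' hypoperfused region is standard mismatch practice and can be turned
#' off). Clusters smaller than `min_cluster_ml` are removed from both
#' masks after thresholding to suppress salt-and-pepper noise.
#'
#' @param maps a normalized [compute_maps()] result (`rcbf` filled).
#' @param brain_mask logical volume.
#' @param tmax_threshold_s hypoperfusion Tmax threshold, s (default 6).
#' @param rcbf_threshold_pct core rCBF threshold, percent (default 30).
#' @param min_cluster_ml minimum retained cluster size, mL (0 disables).
#' @param restrict_core_to_hypoperfusion logical.
#' @return List of class `lesion_masks`: `hypoperfusion_mask`,
#'   `core_mask`, `hypoperfusion_ml`, `core_ml`, `mismatch_ml`,
#'   `thresholds`.
#' @export
segment_lesions <- function(maps, brain_mask = maps$brain_mask,
                            tmax_threshold_s = 6, rcbf_threshold_pct = 30,
                            min_cluster_ml = 1,
                            restrict_core_to_hypoperfusion = TRUE) {
  stopifnot(inherits(maps, "perfusion_maps"))
  if (all(is.na(maps$rcbf))) {
    stop("rcbf map missing: run normalize_relative() before segmentation")
  }
  vox <- maps$voxel_size_mm
  hypo <- brain_mask & !is.na(maps$tmax) & maps$tmax > tmax_threshold_s
  core_domain <- if (restrict_core_to_hypoperfusion) hypo else brain_mask
  core <- core_domain & !is.na(maps$rcbf) & maps$rcbf < rcbf_threshold_pct

  hypo <- remove_small_clusters(hypo, vox, min_cluster_ml)
  core <- remove_small_clusters(core, vox, min_cluster_ml)
  if (restrict_core_to_hypoperfusion) core <- core & hypo

  structure(list(
    hypoperfusion_mask = hypo,
    core_mask = core,
    hypoperfusion_ml = mask_volume_ml(hypo, vox),
    core_ml = mask_volume_ml(core, vox),
    mismatch_ml = mask_volume_ml(hypo, vox) - mask_volume_ml(core, vox),
    thresholds = list(tmax_s = tmax_threshold_s, rcbf_pct = rcbf_threshold_pct,
      min_cluster_ml = min_cluster_ml)
  ), class = "lesion_masks")
}

#' @export
print.lesion_masks <- function(x, ...) {
  cat(sprintf(
    "<lesion_masks> hypoperfusion %.1f mL, core %.1f mL, mismatch %.1f mL (Tmax > %g s, rCBF < %g %%)\n",
    x$hypoperfusion_ml, x$core_ml, x$mismatch_ml,
    x$thresholds$tmax_s, x$thresholds$rcbf_pct
  ))
  invisible(x)
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical volumes of identical dimension.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
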