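# NIfTI + JSON-sidecar I/O for scan pairs and maps.

#' @noRd
as_nifti_vol <- function(arr, voxel_size_mm, dt_s = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (is.null(dt_s)) voxel_size_mm else c(voxel_size_mm, dt_s)
  RNifti::pixdim(img) <- pd
  img
}

#' Write a scan pair to disk
#'
#' Writes the 4-D CTP series and 3-D NCCT of both scans as NIfTI files
#' plus a JSON sidecar (acquisition timestamps, voxel geometry, scenario,
#' seed) and the ground-truth masks (hypoperfusion, core, brain, atlas
#' labels) as NIfTI with a truth sidecar.
#'
#' @param pair a [make_scan_pair()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "scan_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in 1:2) {
    scan <- pair[[paste0("scan", i)]]
    truth <- pair[[paste0("truth", i)]]
    ctp <- scan$ctp
    RNifti::writeNifti(as_nifti_vol(ctp$data, ctp$voxel_size_mm,
      stats::median(diff(ctp$time_axis_s))),
      file.path(dir, sprintf("scan%d_ctp.nii.gz", i)))
    RNifti::writeNifti(as_nifti_vol(unclass(scan$ncct), ctp$voxel_size_mm),
      file.path(dir, sprintf("scan%d_ncct.nii.gz", i)))
    for (nm in c("hypoperfusion_mask", "core_mask", "brain_mask")) {
      RNifti::writeNifti(as_nifti_vol(truth[[nm]] * 1L, ctp$voxel_size_mm),
        file.path(dir, sprintf("scan%d_truth_%s.nii.gz", i, nm)))
    }
    RNifti::writeNifti(as_nifti_vol(truth$atlas$labels, ctp$voxel_size_mm),
      file.path(dir, sprintf("scan%d_atlas.nii.gz", i)))
    sidecar <- list(
      acquisition_time = scan$acquisition_time,
      time_axis_s = ctp$time_axis_s,
      voxel_size_mm = ctp$voxel_size_mm,
      z_origin_mm = ctp$z_origin_mm,
      scenario = pair$scenario,
      seed = pair$seed,
      atlas_names = truth$atlas$names,
      affected_regions = truth$affected_regions
    )
    jsonlite::write_json(sidecar, file.path(dir, sprintf("scan%d.json", i)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a scan pair written by [write_scan_pair()]
#'
#' @param dir directory containing the pair files.
#' @return A list of class `scan_pair` (truths reduced to the stored
#'   masks and atlas).
#' @export
read_scan_pair <- function(dir) {
  out <- list()
  for (i in 1:2) {
    side <- jsonlite::read_json(file.path(dir, sprintf("scan%d.json", i)),
      simplifyVector = TRUE)
    ctp_arr <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("scan%d_ctp.nii.gz", i))))
    ctp <- dynamic_series(ctp_arr, side$time_axis_s, side$voxel_size_mm,
      acquisition_time = side$acquisition_time,
      z_origin_mm = side$z_origin_mm %||% 0)
    ncct <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("scan%d_ncct.nii.gz", i))))
    attr(ncct, "voxel_size_mm") <- side$voxel_size_mm
    truth <- list(
      hypoperfusion_mask = as.array(RNifti::readNifti(
        file.path(dir, sprintf("scan%d_truth_hypoperfusion_mask.nii.gz", i)))) > 0,
      core_mask = as.array(RNifti::readNifti(
        file.path(dir, sprintf("scan%d_truth_core_mask.nii.gz", i)))) > 0,
      brain_mask = as.array(RNifti::readNifti(
        file.path(dir, sprintf("scan%d_truth_brain_mask.nii.gz", i)))) > 0,
      atlas = list(
        labels = as.array(RNifti::readNifti(
          file.path(dir, sprintf("scan%d_atlas.nii.gz", i)))),
        names = as.data.frame(side$atlas_names)
      ),
      affected_regions = side$affected_regions
    )
    out[[paste0("scan", i)]] <- list(ctp = ctp, ncct = ncct,
      acquisition_time = side$acquisition_time)
    out[[paste0("truth", i)]] <- truth
    if (i == 1) {
      out$scenario <- side$scenario
      out$seed <- side$seed
    }
  }
  out$interval_h <- scan_interval_hours(out$scan1$acquisition_time,
    out$scan2$acquisition_time)
  class(out) <- "scan_pair"
  out
}

#' Write perfusion maps as NIfTI volumes
#'
#' Writes `cbf`, `rcbf`, `cbv`, `rcbv`, `mtt`, `tmax` as float NIfTI files
#' named `<prefix>_<map>.nii.gz`.
#'
#' @param maps a [compute_maps()] result.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Written paths, invisibly.
#' @export
write_perfusion_maps <- function(maps, dir, prefix = "maps") {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("cbf", "rcbf", "cbv", "rcbv", "mtt", "tmax")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(as_nifti_vol(maps[[nm]], maps$voxel_size_mm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
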