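# Per-scan intensity metrics: Tmax measured natively (seconds) inside the
# hypoperfusion volume; CBF and NCCT HU inside the core, normalized to the
# median of the contralateral homologous region.

#' Mirror a mask across the midsagittal plane
#'
#' Reflects a mask voxel-for-voxel across the left-right midline of the
#' grid, which the phantom guarantees to coincide with the grid centre.
#' The left-right axis must be stated explicitly (`NA` errors rather than
#' guessing an orientation).
#'
#' @param mask logical 3-D volume.
#' @param lr_axis integer axis index of the left-right direction (1 on the
#'   phantom grid).
#' @return Mirrored logical volume.
#' @examples
#' m <- array(FALSE, c(4, 3, 2)); m[1, 1, 1] <- TRUE
#' which(mirror_contralateral(m))  # voxel (4, 1, 1)
#' @export
mirror_contralateral <- function(mask, lr_axis = 1L) {
  if (is.na(lr_axis)) {
    stop("left-right axis is ambiguous: set lr_axis explicitly")
  }
  stopifnot(length(dim(mask)) == 3L, lr_axis %in% 1:3)
  flip_lr(mask, lr_axis)
}

#' Intensity metrics inside the segmented lesions
#'
#' Computes the three intensity-based metrics: the median Tmax (s) inside
#' the hypoperfusion volume, and median CBF / median NCCT HU inside the
#' core expressed as a percentage of the median over the mirrored
#' (contralateral homologous) core region. Metrics over empty masks are
#' `NA` (explicitly undefined, never zero).
#'
#' @param maps a normalized [compute_maps()] result.
#' @param ncct 3-D NCCT HU volume (or `NULL`; then `rel_hu_core_pct` is
#'   `NA`).
#' @param lesions a [segment_lesions()] result.
#' @param brain_mask logical volume.
#' @param lr_axis left-right axis passed to [mirror_contralateral()].
#' @return List: `median_tmax_hypo_s`, `rel_cbf_core_pct`,
#'   `rel_hu_core_pct`, each `NA` when undefined.
#' @export
lesion_intensity_metrics <- function(maps, ncct, lesions,
                                     brain_mask = maps$brain_mask,
                                     lr_axis = 1L) {
  stopifnot(inherits(lesions, "lesion_masks"))
  hypo <- lesions$hypoperfusion_mask
  core <- lesions$core_mask

  median_tmax <- if (any(hypo)) stats::median(maps$tmax[hypo], na.rm = TRUE) else NA_real_

  rel_cbf <- NA_real_
  rel_hu <- NA_real_
  if (any(core)) {
    mirror <- mirror_contralateral(core, lr_axis)
    mirror_in <- mirror & brain_mask
    if (!any(mirror_in)) {
      stop("mirrored core region falls outside the brain; cannot normalize")
    }
    ref_cbf <- stats::median(maps$cbf[mirror_in], na.rm = TRUE)
    if (is.finite(ref_cbf) && ref_cbf > 0) {
      rel_cbf <- 100 * stats::median(maps$cbf[core], na.rm = TRUE) / ref_cbf
    }
    if (!is.null(ncct)) {
      ref_hu <- stats::median(ncct[mirror_in])
      if (is.finite(ref_hu) && ref_hu > 0) {
        rel_hu <- 100 * stats::median(ncct[core]) / ref_hu
      }
    }
  }
  list(
    median_tmax_hypo_s = median_tmax,
    rel_cbf_core_pct = rel_cbf,
    rel_hu_core_pct = rel_hu
  )
}

#' Interval between two acquisition timestamps in hours
#'
#' Timestamps follow the DICOM AcquisitionTime convention
#' `"HHMMSS"` or `"HHMMSS.ffffff"`. A negative raw difference is assumed
#' to wrap across midnight and 24 h is added.
#'
#' @param time1,time2 timestamp strings.
#' @return Non-negative interval in hours.
#' @examples
#' scan_interval_hours("120000", "150000")    # 3
#' scan_interval_hours("233000", "003000")    # 1 (midnight wrap)
#' @export
scan_interval_hours <- function(time1, time2) {
  parse_one <- function(s) {
    if (!grepl("^\\d{6}(\\.\\d+)?$", s)) {
      stop("unparseable acquisition time: '", s, "' (expected HHMMSS[.ffffff])")
    }
    h <- as.numeric(substr(s, 1, 2))
    m <- as.numeric(substr(s, 3, 4))
    sec <- as.numeric(substr(s, 5, nchar(s)))
    if (h >= 24 || m >= 60 || sec >= 60) {
      stop("invalid acquisition time: '", s, "'")
    }
    h + m / 60 + sec / 3600
  }
  d <- parse_one(time2) - parse_one(time1)
  if (d < 0) d <- d + 24
  d
}
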