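# Automated ASPECTS on non-contrast CT: atlas region labels are overlaid
# on the NCCT, per-region HU summary statistics are compared between
# hemispheres, and one point is deducted per abnormal region.

#' Map atlas regions onto an NCCT volume
#'
#' With `alignment_mode = "identity"` the provided label volume is used as
#' is (the phantom supplies exact labels on its own grid). With
#' `"affine"`, a per-axis affine transform (scale and translation from the
#' centroid and axis standard deviations of the brain masks — a simplified
#' stand-in for full non-rigid template registration) maps NCCT
#' coordinates into atlas space before nearest-neighbour label sampling.
#'
#' @param ncct 3-D HU volume.
#' @param atlas list with `labels` (integer volume, 10 paired regions per
#'   hemisphere, left 1-10 and right 11-20) and `names` (label/side/region
#'   table), as produced by [build_phantom()].
#' @param alignment_mode `"identity"` or `"affine"`.
#' @param hu_window passed to [compute_brain_mask()] in affine mode.
#' @return Named list of linear voxel index vectors, one per region
#'   (names `"L:C"`, ..., `"R:M6"`). Errors if a region ends up empty.
#' @export
map_atlas_regions <- function(ncct, atlas, alignment_mode = c("identity", "affine"),
                              hu_window = c(10, 60)) {
  alignment_mode <- match.arg(alignment_mode)
  labs <- atlas$labels
  present <- sort(unique(labs[labs > 0]))
  if (!identical(as.integer(present), 1:20)) {
    stop("atlas must contain exactly the 20 paired region labels 1-20; found ",
      length(present))
  }
  stopifnot(identical(dim(ncct), dim(labs)))

  if (alignment_mode == "affine") {
    ncct_mask <- compute_brain_mask(ncct, hu_window = hu_window)
    tmpl_mask <- labs > 0
    moments <- function(m) {
      pos <- arrayInd(which(m), dim(m))
      list(center = colMeans(pos), sd = apply(pos, 2, stats::sd))
    }
    mn <- moments(ncct_mask)
    mt <- moments(tmpl_mask)
    scale <- mt$sd / pmax(mn$sd, 1e-6)
    dims <- dim(ncct)
    co <- coord_arrays(dims, c(1, 1, 1))
    # voxel indices (1-based) of every NCCT voxel mapped into atlas space
    xi <- round((co$x + (dims[1] + 1) / 2 - mn$center[1]) * scale[1] + mt$center[1])
    yi <- round((co$y + (dims[2] + 1) / 2 - mn$center[2]) * scale[2] + mt$center[2])
    zi <- round((co$z + (dims[3] + 1) / 2 - mn$center[3]) * scale[3] + mt$center[3])
    ok <- xi >= 1 & xi <= dims[1] & yi >= 1 & yi <= dims[2] & zi >= 1 & zi <= dims[3]
    mapped <- array(0L, dims)
    mapped[ok] <- labs[cbind(xi[ok], yi[ok], zi[ok])]
    labs <- mapped
  }

  region_key <- paste0(atlas$names$side, ":", atlas$names$region)
  out <- lapply(atlas$names$label, function(l) which(labs == l))
  names(out) <- region_key
  empty <- region_key[vapply(out, length, integer(1)) == 0L]
  if (length(empty)) {
    stop("atlas region(s) empty after alignment: ", paste(empty, collapse = ", "))
  }
  out
}

# Per-region HU summary statistics.
#' @noRd
region_hu_stats <- function(ncct, regions, stat = "median", trim = 0.1) {
  vals <- vapply(regions, function(idx) {
    v <- ncct[idx]
    if (stat == "median") stats::median(v) else mean(v, trim = trim)
  }, numeric(1))
  parts <- strsplit(names(regions), ":", fixed = TRUE)
  data.frame(
    side = vapply(parts, `[`, character(1), 1),
    region = vapply(parts, `[`, character(1), 2),
    hu = unname(vals),
    n = vapply(regions, length, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Score ASPECTS from per-region HU statistics
#'
#' For each region and side, the inter-hemispheric difference is the
#' contralateral homologue's summary HU minus the region's own; a region
#' is flagged abnormal when that difference strictly exceeds
#' `delta_threshold_hu` (default 2.25 HU, an empirically established
#' operating point). The affected side is the one with more flags (a tie,
#' including zero flags on both sides, yields `"none"` and a score of 10);
#' the score is 10 minus the number of flagged regions on the affected
#' side.
#'
#' @param ncct 3-D HU volume.
#' @param regions region index list from [map_atlas_regions()], or `NULL`
#'   to derive it from `atlas`.
#' @param atlas atlas list (used when `regions` is `NULL`).
#' @param delta_threshold_hu flag threshold, HU (strict inequality).
#' @param stat `"median"` (default) or `"trimmed_mean"`.
#' @param trim trim fraction for the trimmed mean.
#' @return List of class `aspects_result`: `table` (region, HU per side,
#'   signed deltas, flags), `score_left`, `score_right`, `affected_side`,
#'   `score`, `threshold_hu`.
#' @export
score_aspects <- function(ncct, regions = NULL, atlas = NULL,
                          delta_threshold_hu = 2.25,
                          stat = c("median", "trimmed_mean"), trim = 0.1) {
  stat <- match.arg(stat)
  stat_name <- if (stat == "median") "median" else "trimmed_mean"
  if (is.null(regions)) {
    if (is.null(atlas)) stop("provide either `regions` or `atlas`")
    regions <- map_atlas_regions(ncct, atlas)
  }
  st <- region_hu_stats(ncct, regions,
    stat = if (stat == "median") "median" else "trimmed", trim = trim)
  regs <- unique(st$region)
  hu_l <- st$hu[match(paste0("L:", regs), paste0(st$side, ":", st$region))]
  hu_r <- st$hu[match(paste0("R:", regs), paste0(st$side, ":", st$region))]
  delta_l <- hu_r - hu_l   # positive when the left region is hypodense
  delta_r <- hu_l - hu_r
  flag_l <- delta_l > delta_threshold_hu
  flag_r <- delta_r > delta_threshold_hu
  n_l <- sum(flag_l)
  n_r <- sum(flag_r)
  affected <- if (n_l == n_r) "none" else if (n_l > n_r) "L" else "R"
  score <- if (affected == "none") 10L else 10L - max(n_l, n_r)

  structure(list(
    table = data.frame(
      region = regs, hu_left = hu_l, hu_right = hu_r,
      delta_left = delta_l, delta_right = delta_r,
      flag_left = flag_l, flag_right = flag_r,
      stringsAsFactors = FALSE
    ),
    score_left = 10L - n_l,
    score_right = 10L - n_r,
    affected_side = affected,
    score = score,
    threshold_hu = delta_threshold_hu,
    stat = stat_name
  ), class = "aspects_result")
}

#' @export
print.aspects_result <- function(x, ...) {
  cat(sprintf(
    "<aspects_result> score %d (L %d / R %d, affected side %s, threshold %.2f HU)\n",
    x$score, x$score_left, x$score_right, x$affected_side, x$threshold_hu
  ))
  flagged <- x$table$region[x$table$flag_left | x$table$flag_right]
  if (length(flagged)) cat("  flagged:", paste(flagged, collapse = ", "), "\n")
  invisible(x)
}
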