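# Automatic arterial input function selection: high-enhancement voxels are
# clustered on (time-to-peak, peak amplitude) into arterial and venous
# pools; the arterial pool is the earlier-peaking cluster, candidates are
# ranked by a quality score and the top-k curves averaged.

# Time-to-peak, peak and FWHM (linear interpolation at half maximum) of
# baseline-subtracted curves; `curves` has one row per voxel.
#' @noRd
curve_features <- function(curves, time_axis) {
  n <- nrow(curves)
  ttp <- peak <- fwhm <- numeric(n)
  for (i in seq_len(n)) {
    y <- curves[i, ]
    j <- which.max(y)
    p <- y[j]
    peak[i] <- p
    ttp[i] <- time_axis[j]
    half <- p / 2
    # left crossing
    tl <- time_axis[1]
    if (j > 1) {
      below <- which(y[1:(j - 1)] < half)
      if (length(below)) {
        a <- max(below)
        tl <- time_axis[a] + (half - y[a]) / (y[a + 1] - y[a]) *
          (time_axis[a + 1] - time_axis[a])
      }
    }
    # right crossing
    nt <- length(y)
    tr <- time_axis[nt]
    if (j < nt) {
      below <- which(y[(j + 1):nt] < half)
      if (length(below)) {
        b <- j + min(below)
        tr <- time_axis[b - 1] + (y[b - 1] - half) / (y[b - 1] - y[b]) *
          (time_axis[b] - time_axis[b - 1])
      }
    }
    fwhm[i] <- tr - tl
  }
  data.frame(ttp = ttp, peak = peak, fwhm = fwhm)
}

#' Select the arterial input function automatically
#'
#' Candidate voxels are the top `top_frac` fraction of brain voxels by peak
#' enhancement that also exceed an amplitude floor (separating vessels
#' from tissue). The floor is the larger of `amplitude_floor_hu` and
#' `rel_floor` times the strongest candidate peak; the relative part
#' keeps noise spikes on tissue curves out of the pool whenever genuine
#' vessel curves are present. Candidates are clustered into two groups on
#' standardized (time-to-peak, peak amplitude) with deterministic
#' initialization; the earlier-peaking group is the arterial pool, the
#' other the venous pool. Arterial candidates without any spatially
#' adjacent (26-neighbourhood) fellow candidate are discarded as isolated
#' noise voxels. Remaining candidates are ranked by the quality score
#' `peak / (FWHM * TTP)` — an early, tall, narrow curve scores highest —
#' with ties broken by the lowest linear voxel index, and the mean of the
#' top `top_k` curves is returned.
#'
#' @param series a (preprocessed) [dynamic_series()].
#' @param brain_mask logical brain volume.
#' @param baseline 3-D pre-contrast baseline volume.
#' @param top_frac fraction of brain voxels admitted as candidates.
#' @param amplitude_floor_hu minimum peak enhancement in HU.
#' @param rel_floor minimum peak as a fraction of the strongest peak.
#' @param top_k number of top candidates averaged.
#' @return List of class `aif_selection`: `curve` (baseline-subtracted HU),
#'   `time_axis_s`, `voxel_location` (x, y, z of the best candidate),
#'   `features` (ttp, peak, fwhm, quality of the best candidate),
#'   `pool` (candidate feature table with pool assignment).
#' @export
select_aif <- function(series, brain_mask, baseline,
                       top_frac = 0.02, amplitude_floor_hu = 20,
                       rel_floor = 0.4, top_k = 5) {
  stopifnot(inherits(series, "dynamic_series"))
  dims <- dim(series$data)[1:3]
  nt <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nt)
  brain_idx <- which(brain_mask)
  enh <- flat[brain_idx, , drop = FALSE] - as.vector(baseline)[brain_idx]
  peaks <- apply(enh, 1L, max)

  cut <- stats::quantile(peaks, probs = 1 - top_frac, names = FALSE)
  floor_hu <- max(amplitude_floor_hu, rel_floor * max(peaks))
  cand <- which(peaks >= cut & peaks > floor_hu)
  if (!length(cand)) stop("AIF selection failed: no candidates above the amplitude floor")

  cand_idx <- brain_idx[cand]            # linear indices in the volume
  curves <- enh[cand, , drop = FALSE]
  feats <- curve_features(curves, series$time_axis_s)

  # two-group clustering on standardized (ttp, peak); arterial = earlier pool
  pool <- rep("arterial", nrow(feats))
  if (nrow(feats) >= 2 && stats::sd(feats$ttp) > 1e-9) {
    z <- scale(cbind(feats$ttp, feats$peak))
    z[is.nan(z)] <- 0
    init <- z[c(which.min(feats$ttp), which.max(feats$ttp)), , drop = FALSE]
    if (sum((init[1, ] - init[2, ])^2) > 1e-12) {
      km <- stats::kmeans(z, centers = init, iter.max = 50)
      early <- which.min(tapply(feats$ttp, km$cluster, mean))
      pool <- ifelse(km$cluster == as.integer(early), "arterial", "venous")
    }
  }

  # spatial contiguity: drop arterial candidates with no candidate neighbour
  art <- which(pool == "arterial")
  if (length(art) > 1) {
    pos <- arrayInd(cand_idx, dims)
    keep <- vapply(art, function(i) {
      d <- abs(sweep(pos, 2, pos[i, ], "-"))
      cheb <- pmax(d[, 1], d[, 2], d[, 3])
      any(cheb == 1L)  # at least one fellow candidate in the 26-neighbourhood
    }, logical(1))
    if (any(keep)) art <- art[keep]
  }

  ttp_pos <- pmax(feats$ttp, stats::median(diff(series$time_axis_s)) / 2)
  quality <- feats$peak / (feats$fwhm * ttp_pos)
  ord <- art[order(-quality[art], cand_idx[art])]
  top <- ord[seq_len(min(top_k, length(ord)))]

  aif_curve <- colMeans(curves[top, , drop = FALSE])
  if (max(aif_curve) <= 0) stop("AIF selection failed: non-positive selected curve")
  best <- top[1]
  structure(list(
    curve = aif_curve,
    time_axis_s = series$time_axis_s,
    voxel_location = arrayInd(cand_idx[best], dims)[1, ],
    features = list(
      ttp = feats$ttp[best], peak = feats$peak[best],
      fwhm = feats$fwhm[best], quality = quality[best]
    ),
    pool = data.frame(
      voxel = cand_idx, ttp = feats$ttp, peak = feats$peak,
      fwhm = feats$fwhm, quality = quality, pool = pool,
      stringsAsFactors = FALSE
    ),
    top_voxels = cand_idx[top]
  ), class = "aif_selection")
}

#' @export
print.aif_selection <- function(x, ...) {
  cat(sprintf(
    "<aif_selection> peak %.1f HU at t = %.1f s (FWHM %.1f s), voxel (%s); %d arterial / %d venous candidates\n",
    x$features$peak, x$features$ttp, x$features$fwhm,
    paste(x$voxel_location, collapse = ", "),
    sum(x$pool$pool == "arterial"), sum(x$pool$pool == "venous")
  ))
  invisible(x)
}
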