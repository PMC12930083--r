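# Regularized-SVD (Tikhonov) deconvolution of tissue time-attenuation
# curves with the arterial input function.  The convolution matrix is
# built from the AIF samples as a lower-triangular Toeplitz matrix, or as
# a zero-padded block-circulant matrix (default) whose wrap-around makes
# the estimate insensitive to tracer-arrival delay.  The SVD is computed
# once per scan and the filtered inverse applied to all voxels at once.

#' Deconvolve tissue curves with an AIF (matrix form)
#'
#' Low-level work-horse operating on a matrix of baseline-subtracted
#' curves. The Tikhonov filter factors are
#' `f_i = s_i^2 / (s_i^2 + (lambda_rel * s_1)^2)` applied to the singular
#' values `s_i`; `lambda_rel = 0` gives the (pseudo-inverse) unregularized
#' solution.
#'
#' @param curves numeric matrix, one column per voxel, `nt` rows of
#'   baseline-subtracted attenuation.
#' @param aif baseline-subtracted AIF samples (length `nt`).
#' @param dt frame interval in seconds.
#' @param lambda_rel regularization strength as a fraction of the largest
#'   singular value (>= 0).
#' @param circulant use the delay-insensitive block-circulant formulation
#'   (zero-padded to `2 * nt`).
#' @param quadrature discretization of the convolution integral:
#'   `"linear"` (default) models the AIF as piecewise linear between
#'   samples (taps `(a_j + a_{j-1}) / 2`), which markedly reduces the
#'   discretization bias of both CBF and Tmax for curves generated by a
#'   continuous-time system; `"rect"` uses the raw samples (the classical
#'   construction); `"simpson"` uses `(a_{j-1} + 4 a_j + a_{j+1}) / 6`.
#' @return Matrix of residue estimates `k(t)` (units 1/s scaled by the
#'   tissue-to-arterial amplitude ratio), `nt` rows (Toeplitz) or `2 * nt`
#'   rows (circulant), one column per voxel.
#' @export
deconvolve_matrix <- function(curves, aif, dt, lambda_rel = 0.12,
                              circulant = TRUE,
                              quadrature = c("linear", "rect", "simpson")) {
  quadrature <- match.arg(quadrature)
  if (lambda_rel < 0) stop("lambda_rel must be >= 0")
  if (all(aif == 0)) stop("all-zero AIF")
  nt <- length(aif)
  stopifnot(nrow(curves) == nt)
  taps <- switch(quadrature,
    rect = aif,
    linear = (aif + c(0, aif[-nt])) / 2,
    simpson = {
      ap <- c(0, aif, 0)
      (ap[1:nt] + 4 * ap[2:(nt + 1)] + ap[3:(nt + 2)]) / 6
    }
  )
  L <- if (circulant) 2L * nt else nt
  a_pad <- c(taps, rep(0, L - nt))
  shift_mat <- outer(seq_len(L), seq_len(L), `-`)
  if (circulant) {
    A <- dt * matrix(a_pad[(shift_mat %% L) + 1L], L, L)
  } else {
    A <- matrix(0, L, L)
    lower <- shift_mat >= 0
    A[lower] <- dt * a_pad[shift_mat[lower] + 1L]
  }
  sv <- svd(A)
  lambda <- lambda_rel * sv$d[1]
  filt <- if (lambda > 0) {
    sv$d / (sv$d^2 + lambda^2)
  } else {
    ifelse(sv$d > sv$d[1] * 1e-12, 1 / sv$d, 0)  # pseudo-inverse
  }
  C <- rbind(curves, matrix(0, L - nt, ncol(curves)))
  sv$v %*% (filt * crossprod(sv$u, C))
}

#' Voxelwise deconvolution of a dynamic series
#'
#' Applies [deconvolve_matrix()] to every brain voxel of a preprocessed
#' series.
#'
#' @param series a (preprocessed) [dynamic_series()].
#' @param aif an [select_aif()] result (or a list with `curve`).
#' @param brain_mask logical volume of voxels to deconvolve.
#' @param baseline 3-D pre-contrast baseline volume.
#' @param lambda_rel,circulant,quadrature see [deconvolve_matrix()].
#' @return List of class `residue_fit`: `k` (residue matrix, one column
#'   per mask voxel), `mask_idx`, `dt_s`, `nt`, `dim`, plus the inputs
#'   needed downstream.
#' @export
deconvolve_voxelwise <- function(series, aif, brain_mask, baseline,
                                 lambda_rel = 0.12, circulant = TRUE,
                                 quadrature = "linear") {
  stopifnot(inherits(series, "dynamic_series"))
  aif_curve <- if (is.list(aif)) aif$curve else aif
  if (max(aif_curve) <= 0) stop("AIF peak must be positive")
  nt <- dim(series$data)[4]
  dt <- stats::median(diff(series$time_axis_s))
  flat <- matrix(series$data, ncol = nt)
  idx <- which(brain_mask)
  curves <- t(flat[idx, , drop = FALSE] - as.vector(baseline)[idx])
  k <- deconvolve_matrix(curves, aif_curve, dt, lambda_rel, circulant, quadrature)
  structure(list(
    k = k, mask_idx = idx, dt_s = dt, nt = nt,
    dim = dim(series$data)[1:3], circulant = circulant,
    lambda_rel = lambda_rel, quadrature = quadrature
  ), class = "residue_fit")
}

#' Compute perfusion maps from residue estimates
#'
#' CBF is the maximum of the residue estimate over the physical (first
#' `nt`) samples; Tmax is the time of that maximum (first maximum on
#' ties); CBV is the trapezoid-rule area of the enhancement curve divided
#' by the AIF area, negatives clipped to zero; MTT = CBV / CBF where CBF
#' exceeds a small floor, `NA` elsewhere. CBF carries deconvolution units
#' (1/s relative to the arterial amplitude); no absolute calibration is
#' attempted because all downstream metrics are relative or in seconds.
#'
#' With `map_filter = "median"` (default) the raw CBF and CBV maps are
#' passed through a masked 26-neighbourhood median filter — an
#' edge-preserving denoising step for the voxelwise deconvolution noise.
#' Tmax is deliberately left unfiltered: lesion boundaries in the Tmax
#' map are convex, and a neighbourhood median systematically erodes
#' convex shapes, whereas Tmax speckle is already handled by the
#' minimum-cluster filter during segmentation.
#'
#' With `cbf_bias_correction = TRUE` (default) the (filtered)
#' max-of-residue estimate is then divided by the factor
#' `(MTT/dt) * (1 - exp(-dt/MTT))`, the amount by which sampling at
#' interval `dt` underestimates the peak of a mono-exponential residue of
#' the voxel's (iteratively re-estimated) MTT. The correction removes
#' most of the MTT dependence of the CBF bias, which would otherwise
#' inflate relative CBF in long-MTT lesions; it runs after the filter
#' because its MTT feedback would amplify unfiltered voxel noise.
#'
#' @param residues a [deconvolve_voxelwise()] result.
#' @param series the matching [dynamic_series()].
#' @param aif the [select_aif()] result used for deconvolution.
#' @param baseline 3-D baseline volume.
#' @param cbf_bias_correction logical, see above.
#' @param map_filter `"median"` or `"none"`.
#' @return List of class `perfusion_maps` with 3-D maps `cbf`, `cbv`,
#'   `mtt`, `tmax` (`NA` outside the mask), `rcbf`/`rcbv` (filled by
#'   [normalize_relative()]), `brain_mask`, `voxel_size_mm`, `dt_s`.
#' @export
compute_maps <- function(residues, series, aif, baseline,
                         cbf_bias_correction = TRUE,
                         map_filter = c("median", "none")) {
  map_filter <- match.arg(map_filter)
  stopifnot(inherits(residues, "residue_fit"))
  nt <- residues$nt
  dt <- residues$dt_s
  k_phys <- residues$k[seq_len(nt), , drop = FALSE]

  amax <- max.col(t(k_phys), ties.method = "first")
  cbf_v <- k_phys[cbind(amax, seq_along(amax))]
  cbf_v <- pmax(cbf_v, 0)
  tmax_v <- (amax - 1) * dt

  aif_curve <- if (is.list(aif)) aif$curve else aif
  w <- trapz_weights(series$time_axis_s)
  flat <- matrix(series$data, ncol = nt)
  enh <- flat[residues$mask_idx, , drop = FALSE] -
    as.vector(baseline)[residues$mask_idx]
  cbv_v <- pmax(as.vector(enh %*% w) / sum(w * aif_curve), 0)

  blank <- array(NA_real_, residues$dim)
  maps <- list(cbf = blank, cbv = blank, mtt = blank, tmax = blank,
    rcbf = blank, rcbv = blank)
  maps$cbf[residues$mask_idx] <- cbf_v
  maps$cbv[residues$mask_idx] <- cbv_v
  maps$tmax[residues$mask_idx] <- tmax_v
  maps$brain_mask <- array(FALSE, residues$dim)
  maps$brain_mask[residues$mask_idx] <- TRUE

  if (map_filter == "median") {
    for (nm in c("cbf", "cbv")) {
      maps[[nm]] <- median_filter_map(maps[[nm]], maps$brain_mask)
    }
  }
  if (cbf_bias_correction) {
    cbf0 <- pmax(maps$cbf[residues$mask_idx], 1e-12)
    cbvf <- maps$cbv[residues$mask_idx]
    cbf_c <- cbf0
    for (i in 1:3) {
      mtt_i <- pmin(pmax(cbvf / cbf_c, dt), 30)
      cbf_c <- cbf0 / ((mtt_i / dt) * (1 - exp(-dt / mtt_i)))
    }
    maps$cbf[residues$mask_idx] <- ifelse(maps$cbf[residues$mask_idx] > 0,
      cbf_c, 0)
  }
  maps$mtt[residues$mask_idx] <- ifelse(maps$cbf[residues$mask_idx] > 1e-8,
    maps$cbv[residues$mask_idx] / maps$cbf[residues$mask_idx], NA_real_)

  maps$voxel_size_mm <- series$voxel_size_mm
  maps$dt_s <- dt
  maps$map_filter <- map_filter
  class(maps) <- "perfusion_maps"
  maps
}

#' Normalize CBF and CBV to normally perfused tissue
#'
#' Normally perfused reference tissue is brain with Tmax below
#' `tmax_normal_s` (default 4 s); `rcbf` and `rcbv` are the absolute maps
#' expressed as a percentage of the reference median. The reference set
#' is additionally eroded away from the brain surface
#' (`erode_reference` six-neighbourhood iterations) so that
#' partial-volume-dampened edge voxels do not drag the reference median
#' down; erosion is skipped if it would empty the reference.
#'
#' @param maps a [compute_maps()] result.
#' @param brain_mask logical volume (defaults to the mask stored in
#'   `maps`).
#' @param tmax_normal_s Tmax threshold defining normal tissue, s.
#' @param erode_reference integer, erosion iterations for the reference
#'   set (0 disables).
#' @return `maps` with `rcbf` and `rcbv` filled.
#' @export
normalize_relative <- function(maps, brain_mask = maps$brain_mask,
                               tmax_normal_s = 4, erode_reference = 2L) {
  stopifnot(inherits(maps, "perfusion_maps"))
  core_brain <- brain_mask
  if (erode_reference > 0) {
    eroded <- erode3d(brain_mask, as.integer(erode_reference))
    if (any(eroded)) core_brain <- eroded
  }
  normal <- core_brain & !is.na(maps$tmax) & maps$tmax < tmax_normal_s &
    is.finite(maps$cbf)
  if (!any(normal)) normal <- brain_mask & !is.na(maps$tmax) &
    maps$tmax < tmax_normal_s & is.finite(maps$cbf)
  if (!any(normal)) stop("no normally perfused reference tissue (Tmax < ",
    tmax_normal_s, " s)")
  ref_cbf <- stats::median(maps$cbf[normal])
  ref_cbv <- stats::median(maps$cbv[normal])
  if (ref_cbf <= 0 || ref_cbv <= 0) {
    stop("non-positive reference median; cannot normalize")
  }
  maps$rcbf <- 100 * maps$cbf / ref_cbf
  maps$rcbv <- 100 * maps$cbv / ref_cbv
  maps$reference <- list(
    n_voxels = sum(normal), median_cbf = ref_cbf, median_cbv = ref_cbv,
    tmax_normal_s = tmax_normal_s
  )
  maps
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat("<perfusion_maps>\n")
  for (nm in c("cbf", "cbv", "mtt", "tmax", "rcbf")) {
    v <- x[[nm]][x$brain_mask]
    cat(sprintf("  %-5s median %8.4g  (IQR %.4g-%.4g)\n", nm,
      stats::median(v, na.rm = TRUE),
      stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE),
      stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE)))
  }
  invisible(x)
}
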