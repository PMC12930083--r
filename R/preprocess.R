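# Frame-wise preprocessing: optional Gaussian denoising, optional rigid
# (translation) frame-to-first registration, baseline estimation and
# bolus-arrival detection.

# 1-D Gaussian convolution matrix with renormalized (truncated) edge rows.
#' @noRd
gauss_kernel_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(3 * sigma_vox))
  kx <- (-half):half
  kern <- exp(-kx^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (j in seq_along(kx)) {
    idx <- seq_len(n) + kx[j]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + kern[j]
  }
  K / rowSums(K)
}

# Separable spatial Gaussian smoothing of a 3-D volume or every frame of a
# 4-D series at once (one BLAS multiply per axis), FWHM in mm.
#' @noRd
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm  # per-axis sigma, voxels
  dims <- dim(vol)
  nd <- length(dims)
  out <- vol
  if (sigma[1] >= 1e-3) {
    K <- gauss_kernel_matrix(dims[1], sigma[1])
    out <- array(K %*% matrix(out, nrow = dims[1]), dims)
  }
  if (sigma[2] >= 1e-3) {
    K <- gauss_kernel_matrix(dims[2], sigma[2])
    perm <- c(2L, 1L, seq_len(nd)[-(1:2)])
    m <- matrix(aperm(out, perm), nrow = dims[2])
    out <- aperm(array(K %*% m, dims[perm]), order(perm))
  }
  if (sigma[3] >= 1e-3) {
    tK <- t(gauss_kernel_matrix(dims[3], sigma[3]))
    n12 <- dims[1] * dims[2]
    if (nd == 3L) {
      out <- array(matrix(out, n12, dims[3]) %*% tK, dims)
    } else {
      for (i in seq_len(dims[4])) {
        out[, , , i] <- array(matrix(out[, , , i], n12, dims[3]) %*% tK,
          dims[1:3])
      }
    }
  }
  out
}

# Integer-voxel translation of one frame relative to a reference, by phase
# correlation.  Returns c(dx, dy, dz).
#' @noRd
estimate_translation3d <- function(ref, frame) {
  fr <- stats::fft(ref)
  ff <- stats::fft(frame)
  cross <- fr * Conj(ff)
  denom <- Mod(cross)
  denom[denom < 1e-12] <- 1
  corr <- Re(stats::fft(cross / denom, inverse = TRUE))
  idx <- arrayInd(which.max(corr), dim(corr)) - 1L
  dims <- dim(ref)
  shift <- ifelse(idx > dims / 2, idx - dims, idx)
  as.integer(shift)
}

# Circular integer roll of a 3-D array.
#' @noRd
roll3d <- function(vol, shift) {
  dims <- dim(vol)
  idx <- lapply(1:3, function(a) {
    s <- shift[a] %% dims[a]
    if (s == 0) seq_len(dims[a]) else c((dims[a] - s + 1):dims[a], 1:(dims[a] - s))
  })
  vol[idx[[1]], idx[[2]], idx[[3]]]
}

#' Preprocess a dynamic CTP series
#'
#' Applies optional per-frame Gaussian smoothing and optional rigid
#' (integer-translation) frame-to-first motion correction, then estimates
#' the pre-contrast baseline and the bolus-arrival frame. Arrival is the
#' first frame whose whole-brain mean enhancement exceeds `arrival_z` times
#' the standard deviation of the first three frames' means (with a small
#' floor so that noise-free data still triggers); the baseline volume is
#' the voxelwise mean over all pre-arrival frames. If fewer than
#' `min_baseline_frames` frames precede arrival, the first
#' `min_baseline_frames` frames are used with a warning.
#'
#' @param series a [dynamic_series()].
#' @param smoothing_fwhm_mm Gaussian FWHM in mm (0 = no smoothing).
#' @param motion_correction logical; rigid translation to the first frame.
#' @param brain_mask logical volume; computed from the first frame via
#'   [compute_brain_mask()] when `NULL`.
#' @param arrival_z detection multiple of the pre-bolus SD.
#' @param min_baseline_frames minimum number of baseline frames.
#' @return List with `series` (processed), `series_raw` (motion-corrected
#'   but unsmoothed, for AIF extraction), `baseline` / `baseline_raw`
#'   (3-D volumes), `arrival_index` (1-based frame), `baseline_frames`,
#'   `global_curve` and `brain_mask`.
#' @export
preprocess_series <- function(series, smoothing_fwhm_mm = 0,
                              motion_correction = FALSE,
                              brain_mask = NULL, arrival_z = 3,
                              min_baseline_frames = 3L) {
  stopifnot(inherits(series, "dynamic_series"))
  arr <- series$data
  nt <- dim(arr)[4]
  if (is.null(brain_mask)) {
    brain_mask <- compute_brain_mask(arr[, , , 1], voxel_size_mm = series$voxel_size_mm)
  }
  if (motion_correction) {
    ref <- arr[, , , 1]
    for (i in 2:nt) {
      sh <- estimate_translation3d(ref, arr[, , , i])
      if (any(sh != 0L)) arr[, , , i] <- roll3d(arr[, , , i], sh)
    }
  }
  arr_raw <- arr  # motion-corrected but unsmoothed (AIF extraction)
  if (smoothing_fwhm_mm > 0) {
    arr <- gaussian_smooth_3d(arr, smoothing_fwhm_mm, series$voxel_size_mm)
  }

  flat <- matrix(arr, ncol = nt)
  g <- colMeans(flat[which(brain_mask), , drop = FALSE])
  b0 <- mean(g[1:3])
  s0 <- max(stats::sd(g[1:3]), 1e-3)  # floor keeps noise-free data detectable
  above <- which(g - b0 > arrival_z * s0)
  if (!length(above)) stop("no bolus detected in series")
  arrival <- above[1]

  if (arrival - 1L < min_baseline_frames) {
    warning("fewer than ", min_baseline_frames,
      " pre-arrival frames; using the first ", min_baseline_frames, " frames")
    base_frames <- seq_len(min_baseline_frames)
  } else {
    base_frames <- seq_len(arrival - 1L)
  }
  baseline <- array(rowMeans(flat[, base_frames, drop = FALSE]), dim = dim(arr)[1:3])

  out_series <- series
  out_series$data <- arr
  raw_series <- series
  raw_series$data <- arr_raw
  baseline_raw <- array(rowMeans(matrix(arr_raw, ncol = nt)[, base_frames,
    drop = FALSE]), dim = dim(arr)[1:3])
  list(
    series = out_series,
    series_raw = raw_series,
    baseline = baseline,
    baseline_raw = baseline_raw,
    arrival_index = arrival,
    baseline_frames = base_frames,
    global_curve = g,
    brain_mask = brain_mask
  )
}
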