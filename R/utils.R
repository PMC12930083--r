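# Internal geometry / array helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Voxel-centre coordinates in mm, origin at the grid centre.  For even
# dimensions the midline falls between two voxel columns, so mirroring
# i -> n+1-i is an exact symmetry.
#' @noRd
voxel_coords <- function(dim, voxel_size) {
  lapply(1:3, function(a) (seq_len(dim[a]) - (dim[a] + 1) / 2) * voxel_size[a])
}

# 3-D arrays of per-voxel x/y/z mm coordinates.
#' @noRd
coord_arrays <- function(dim, voxel_size) {
  cc <- voxel_coords(dim, voxel_size)
  list(
    x = array(rep(cc[[1]], times = dim[2] * dim[3]), dim = dim),
    y = array(rep(rep(cc[[2]], each = dim[1]), times = dim[3]), dim = dim),
    z = array(rep(cc[[3]], each = dim[1] * dim[2]), dim = dim)
  )
}

# Normalized squared ellipsoid metric ((p-c)/r)^2 summed over axes.
#' @noRd
ellipsoid_metric <- function(dim, voxel_size, center_mm, radii_mm) {
  co <- coord_arrays(dim, voxel_size)
  ((co$x - center_mm[1]) / radii_mm[1])^2 +
    ((co$y - center_mm[2]) / radii_mm[2])^2 +
    ((co$z - center_mm[3]) / radii_mm[3])^2
}

#' @noRd
ellipsoid_mask <- function(dim, voxel_size, center_mm, radii_mm) {
  ellipsoid_metric(dim, voxel_size, center_mm, radii_mm) <= 1
}

# Mask of exactly n voxels closest (in the ellipsoid metric) to the centre;
# deterministic tie-break on linear voxel index.
#' @noRd
nearest_n_mask <- function(dim, voxel_size, center_mm, radii_mm, n) {
  m <- ellipsoid_metric(dim, voxel_size, center_mm, radii_mm)
  ord <- order(as.vector(m), seq_along(m))
  out <- array(FALSE, dim)
  out[ord[seq_len(min(n, length(ord)))]] <- TRUE
  out
}

# Frontier-based flood fill over the 6-neighbourhood from seed linear
# indices; returns logical array of reached voxels within `mask`.
#' @noRd
flood_fill3d <- function(mask, seeds) {
  dims <- dim(mask)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]; n12 <- n1 * n2
  visited <- logical(length(mask))
  frontier <- seeds[mask[seeds]]
  frontier <- unique(frontier)
  while (length(frontier)) {
    visited[frontier] <- TRUE
    x <- (frontier - 1L) %% n1 + 1L
    y <- ((frontier - 1L) %/% n1) %% n2 + 1L
    z <- (frontier - 1L) %/% n12 + 1L
    nb <- c(
      frontier[x > 1L] - 1L, frontier[x < n1] + 1L,
      frontier[y > 1L] - n1, frontier[y < n2] + n1,
      frontier[z > 1L] - n12, frontier[z < n3] + n12
    )
    nb <- unique(nb)
    frontier <- nb[mask[nb] & !visited[nb]]
  }
  array(visited, dims)
}

# Largest 6-connected component of a logical volume.
#' @noRd
largest_component3d <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- -1L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_fill3d(remaining, seed)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  best %||% mask
}

# Fill cavities: background components not connected to the volume border.
#' @noRd
fill_holes3d <- function(mask) {
  dims <- dim(mask)
  bg <- !mask
  co <- coord_arrays(dims, c(1, 1, 1))
  border <- which(
    abs(co$x) == max(abs(co$x)) | abs(co$y) == max(abs(co$y)) |
      abs(co$z) == max(abs(co$z))
  )
  outside <- flood_fill3d(bg, border)
  mask | (bg & !outside)
}

# Reflect across the midsagittal grid plane (left-right axis).
#' @noRd
flip_lr <- function(arr, lr_axis = 1L) {
  nd <- length(dim(arr))
  idx <- lapply(dim(arr), seq_len)
  idx[[lr_axis]] <- rev(idx[[lr_axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# Shift a 3-D/4-D array along z: scanner slice k shows object slice k+shift,
# vacated slices filled with `fill`.
#' @noRd
shift_z <- function(arr, shift, fill = 0) {
  if (shift == 0L) return(arr)
  dims <- dim(arr)
  nz <- dims[3]
  out <- array(fill, dims)
  src <- seq_len(nz) + shift
  ok <- src >= 1L & src <= nz
  if (length(dims) == 3L) {
    out[, , which(ok)] <- arr[, , src[ok]]
  } else {
    out[, , which(ok), ] <- arr[, , src[ok], ]
  }
  out
}

# Trapezoid quadrature weights for a (possibly non-uniform) time axis.
#' @noRd
trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

# MD5 of an R object via a temporary serialized copy (provenance stamping).
#' @noRd
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Binary erosion by the 6-neighbourhood, `iter` times.
#' @noRd
erode3d <- function(mask, iter = 1L) {
  dims <- dim(mask)
  out <- mask
  for (k in seq_len(iter)) {
    m <- out
    shifted <- function(df) {
      s <- array(FALSE, dims)
      idx_to <- lapply(dims, seq_len); idx_from <- idx_to
      ax <- which(df != 0)
      if (df[ax] > 0) { idx_to[[ax]] <- 2:dims[ax]; idx_from[[ax]] <- 1:(dims[ax]-1) }
      else { idx_to[[ax]] <- 1:(dims[ax]-1); idx_from[[ax]] <- 2:dims[ax] }
      s <- do.call(`[<-`, c(list(s), idx_to, list(do.call(`[`, c(list(m), idx_from)))))
      s
    }
    out <- m &
      shifted(c(1,0,0)) & shifted(c(-1,0,0)) &
      shifted(c(0,1,0)) & shifted(c(0,-1,0)) &
      shifted(c(0,0,1)) & shifted(c(0,0,-1))
  }
  out
}
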