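# Shared fixtures built in code: small synthetic series and hand-crafted
# map/mask objects used by several test files.

# Minimal dynamic series on a tiny grid; curves supplied per voxel via a
# generator function f(x, y, z) -> numeric(nt).
tiny_series <- function(dims = c(8, 8, 2), nt = 16, dt = 2, f) {
  arr <- array(0, c(dims, nt))
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) for (x in seq_len(dims[1])) {
    arr[x, y, z, ] <- f(x, y, z)
  }
  dynamic_series(arr, seq(0, by = dt, length.out = nt), c(2, 2, 4))
}

# Hand-crafted perfusion_maps object from plain arrays.
fake_maps <- function(cbf, tmax, cbv = cbf, brain_mask = NULL,
                      voxel_size = c(1, 1, 1), dt = 2) {
  brain_mask <- brain_mask %||% array(TRUE, dim(cbf))
  maps <- list(
    cbf = cbf, cbv = cbv,
    mtt = ifelse(cbf > 1e-8, cbv / cbf, NA_real_),
    tmax = tmax,
    rcbf = array(NA_real_, dim(cbf)), rcbv = array(NA_real_, dim(cbf)),
    brain_mask = brain_mask, voxel_size_mm = voxel_size, dt_s = dt
  )
  class(maps) <- "perfusion_maps"
  maps
}

fake_lesions <- function(hypo, core, voxel_size = c(1, 1, 1)) {
  structure(list(
    hypoperfusion_mask = hypo, core_mask = core,
    hypoperfusion_ml = mask_volume_ml(hypo, voxel_size),
    core_ml = mask_volume_ml(core, voxel_size),
    mismatch_ml = mask_volume_ml(hypo, voxel_size) - mask_volume_ml(core, voxel_size),
    thresholds = list(tmax_s = 6, rcbf_pct = 30, min_cluster_ml = 0)
  ), class = "lesion_masks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_aif_params <- function() list(amplitude = 350, t0 = 8, alpha = 3, beta = 1.5)
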