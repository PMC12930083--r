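# End-to-end quantification: preprocess -> AIF -> deconvolve -> maps ->
# normalize -> segment -> ASPECTS -> intensity metrics, per scan; paired
# differences and agreement statistics per cohort.

# Run one stage, rethrowing errors with the stage name attached.
#' @noRd
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Quantify a single CTP (+ NCCT) scan
#'
#' Runs the full single-scan pipeline and collects the six study metrics.
#' A suboptimal-bolus warning flag is set when the selected AIF has not
#' returned below `bolus_residual_warn_frac` of its peak by the last
#' frame.
#'
#' @param ctp a [dynamic_series()].
#' @param ncct 3-D NCCT HU volume, or `NULL` (ASPECTS and the NCCT metric
#'   are then `NA`).
#' @param atlas atlas list (labels + names) for ASPECTS; `NULL` skips
#'   ASPECTS.
#' @param config a [perfstab_config()].
#' @return List of class `scan_result`: `maps`, `lesions`, `aspects`,
#'   `metrics` (named list of the six metrics), `aif`, `brain_mask`,
#'   `flags` (character vector of warnings).
#' @export
run_scan_analysis <- function(ctp, ncct = NULL, atlas = NULL,
                              config = perfstab_config()) {
  stopifnot(inherits(config, "perfstab_config"))
  flags <- character(0)

  prep <- run_stage("preprocess", preprocess_series(ctp,
    smoothing_fwhm_mm = config$smoothing_fwhm_mm,
    motion_correction = config$motion_correction,
    arrival_z = config$arrival_z))
  mask <- prep$brain_mask

  aif <- run_stage("aif_selection", select_aif(prep$series_raw, mask,
    prep$baseline_raw,
    top_frac = config$aif_top_frac,
    amplitude_floor_hu = config$aif_amplitude_floor_hu,
    top_k = config$aif_top_k))
  nt <- length(aif$curve)
  if (aif$curve[nt] > config$bolus_residual_warn_frac * max(aif$curve)) {
    flags <- c(flags, "suboptimal_bolus_coverage")
  }

  res <- run_stage("deconvolution", deconvolve_voxelwise(prep$series, aif, mask,
    prep$baseline, lambda_rel = config$lambda_rel,
    circulant = config$circulant, quadrature = config$quadrature))
  maps <- run_stage("maps", compute_maps(res, prep$series, aif, prep$baseline,
    cbf_bias_correction = config$cbf_bias_correction,
    map_filter = config$map_filter))
  if (config$cbf_smoothing_fwhm_mm > config$smoothing_fwhm_mm) {
    # flow path: CBF/CBV from more strongly denoised curves (the 30 % core
    # threshold needs low voxel noise; timing boundaries stay on the light
    # path above)
    flow_series <- prep$series_raw
    ntq <- dim(flow_series$data)[4]
    flow_series$data <- gaussian_smooth_3d(flow_series$data,
      config$cbf_smoothing_fwhm_mm, flow_series$voxel_size_mm)
    flow_base <- array(rowMeans(matrix(flow_series$data,
      ncol = ntq)[, prep$baseline_frames, drop = FALSE]), dim = dim(mask))
    res_f <- run_stage("deconvolution_flow", deconvolve_voxelwise(flow_series,
      aif, mask, flow_base, lambda_rel = config$cbf_lambda_rel,
      circulant = config$circulant, quadrature = config$quadrature))
    maps_f <- run_stage("maps_flow", compute_maps(res_f, flow_series, aif,
      flow_base, cbf_bias_correction = config$cbf_bias_correction,
      map_filter = config$map_filter))
    maps$cbf <- maps_f$cbf
    maps$cbv <- maps_f$cbv
    maps$mtt <- maps_f$mtt
  }
  maps <- run_stage("normalization", normalize_relative(maps, mask,
    tmax_normal_s = config$tmax_normal_s))
  lesions <- run_stage("segmentation", segment_lesions(maps, mask,
    tmax_threshold_s = config$tmax_hypoperfusion_s,
    rcbf_threshold_pct = config$rcbf_core_pct,
    min_cluster_ml = config$min_cluster_ml,
    restrict_core_to_hypoperfusion = config$restrict_core_to_hypoperfusion))

  aspects <- NULL
  if (!is.null(ncct) && !is.null(atlas)) {
    aspects <- run_stage("aspects", score_aspects(ncct,
      regions = map_atlas_regions(ncct, atlas,
        alignment_mode = config$alignment_mode,
        hu_window = config$hu_window),
      delta_threshold_hu = config$aspects_delta_hu,
      stat = config$aspects_stat, trim = config$aspects_trim))
  }

  intensity <- run_stage("intensity_metrics",
    lesion_intensity_metrics(maps, ncct, lesions, mask))

  metrics <- list(
    core_ml = lesions$core_ml,
    hypoperfusion_ml = lesions$hypoperfusion_ml,
    aspects = if (is.null(aspects)) NA_real_ else as.numeric(aspects$score),
    median_tmax_hypo_s = intensity$median_tmax_hypo_s,
    rel_cbf_core_pct = intensity$rel_cbf_core_pct,
    rel_hu_core_pct = intensity$rel_hu_core_pct
  )

  structure(list(
    maps = maps, lesions = lesions, aspects = aspects,
    metrics = metrics, aif = aif, brain_mask = mask, flags = flags,
    acquisition_time = ctp$acquisition_time
  ), class = "scan_result")
}

# Shift phantom-space atlas labels into the acquisition window of a scan
# whose z origin was moved (coverage-shift scenario).
#' @noRd
atlas_for_scan <- function(atlas, series) {
  shift <- round(series$z_origin_mm / series$voxel_size_mm[3])
  if (shift == 0) return(atlas)
  atlas$labels <- shift_z(atlas$labels, as.integer(shift), fill = 0L)
  atlas
}

#' Analyse a repeated-scan pair
#'
#' Quantifies both scans of a [make_scan_pair()] result with identical
#' configuration, then computes per-metric signed differences
#' (scan 2 minus scan 1) and the inter-scan interval from the acquisition
#' timestamps. Deterministic given the pair and configuration; the
#' configuration (with MD5 hash and package version) is embedded in the
#' report.
#'
#' @param pair a `scan_pair`.
#' @param config a [perfstab_config()].
#' @return List of class `pair_report`: `scan1`, `scan2` (scan results),
#'   `metrics1`, `metrics2`, `diff`, `interval_h`, `scenario`, `flags`,
#'   `provenance`.
#' @export
run_pair_analysis <- function(pair, config = perfstab_config()) {
  stopifnot(inherits(pair, "scan_pair"))
  r1 <- run_scan_analysis(pair$scan1$ctp, pair$scan1$ncct,
    atlas = atlas_for_scan(pair$truth1$atlas, pair$scan1$ctp), config = config)
  r2 <- run_scan_analysis(pair$scan2$ctp, pair$scan2$ncct,
    atlas = atlas_for_scan(pair$truth2$atlas, pair$scan2$ctp), config = config)
  interval_h <- scan_interval_hours(pair$scan1$acquisition_time,
    pair$scan2$acquisition_time)
  diffs <- mapply(function(a, b) b - a, r1$metrics, r2$metrics, SIMPLIFY = FALSE)
  flags <- unique(c(
    if (length(r1$flags)) paste0("scan1:", r1$flags),
    if (length(r2$flags)) paste0("scan2:", r2$flags)
  ))
  structure(list(
    scan1 = r1, scan2 = r2,
    metrics1 = r1$metrics, metrics2 = r2$metrics, diff = diffs,
    interval_h = interval_h, scenario = pair$scenario, seed = pair$seed,
    flags = flags,
    provenance = config_stamp(config)
  ), class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("<pair_report> scenario '%s', interval %.2f h\n", x$scenario,
    x$interval_h))
  m <- rbind(scan1 = unlist(x$metrics1), scan2 = unlist(x$metrics2),
    diff = unlist(x$diff))
  print(round(m, 2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# One tidy row per pair report, for cohort aggregation.
#' @noRd
pair_metrics_row <- function(report, pair_id) {
  row <- data.frame(pair_id = pair_id, scenario = report$scenario,
    interval_h = report$interval_h, stringsAsFactors = FALSE)
  for (m in names(report$metrics1)) {
    row[[paste0(m, "_1")]] <- report$metrics1[[m]]
    row[[paste0(m, "_2")]] <- report$metrics2[[m]]
    row[[paste0(m, "_d")]] <- report$diff[[m]]
  }
  row$flags <- paste(report$flags, collapse = ";")
  row
}

#' Analyse a cohort of repeated-scan pairs
#'
#' Runs [run_pair_analysis()] on every pair, assembles the tidy per-pair
#' metric table, and aggregates it with [cohort_report()] (pairs with a
#' disruptive-event scenario are excluded from the agreement statistics
#' but listed in the report). Optionally writes the report JSON, the tidy
#' CSV and Bland-Altman figures to `out_dir`.
#'
#' @param pairs list of `scan_pair` objects (or of precomputed
#'   `pair_report`s).
#' @param config a [perfstab_config()].
#' @param out_dir optional output directory.
#' @param progress print one line per pair.
#' @return List of class `cohort_result`: `report` (an
#'   `agreement_report`), `pair_table`, `provenance`.
#' @export
run_cohort <- function(pairs, config = perfstab_config(), out_dir = NULL,
                       progress = FALSE) {
  stopifnot(length(pairs) >= 1)
  reports <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    r <- if (inherits(p, "pair_report")) p else run_pair_analysis(p, config)
    if (progress) {
      message(sprintf("pair %d/%d (%s) done", i, length(pairs), r$scenario))
    }
    r
  })
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    pair_metrics_row(reports[[i]], pair_id = i)
  }))
  rep <- cohort_report(tab, interval_assoc = config$interval_assoc)
  out <- structure(list(
    report = rep, pair_table = tab,
    provenance = config_stamp(config)
  ), class = "cohort_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "pair_metrics.csv"), row.names = FALSE)
    json <- list(
      table = rep$table, excluded = rep$excluded, n_pairs = rep$n_pairs,
      n_excluded = rep$n_excluded, status = rep$status,
      provenance = out$provenance
    )
    jsonlite::write_json(json, file.path(out_dir, "agreement_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    if (!is.null(rep$table)) {
      for (m in rep$table$metric) {
        v1 <- tab[[paste0(m, "_1")]][!tab$scenario %in% DISRUPTIVE_SCENARIOS]
        v2 <- tab[[paste0(m, "_2")]][!tab$scenario %in% DISRUPTIVE_SCENARIOS]
        if (sum(is.finite(v1) & is.finite(v2)) >= 3) {
          grDevices::png(file.path(out_dir, paste0("bland_altman_", m, ".png")),
            width = 600, height = 600)
          plot_bland_altman(v1, v2, main = m)
          grDevices::dev.off()
        }
      }
    }
  }
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
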