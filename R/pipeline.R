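#' Run configuration with pipeline defaults
#'
#' Bundles every tunable of the measurement pipeline with its default:
#' segmentation HU band \[1200, 2200\], ring volume threshold 50 voxels,
#' 72 angular sectors, amplitude fraction 0.6, 2 mm cluster radius, proximal
#' observation points, 5 mm match threshold, angles in degrees. The config
#' (and its hash) is embedded in every output for provenance.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(lo_hu = 1200, hi_hu = 2200, region_fraction = 0.1,
              min_volume_voxels = 50, n_sectors = 72, amp_fraction = 0.6,
              nms_window = 2L, min_amplitude_mm = 2.0, cluster_radius = 2.0,
              orientation = "proximal", match_threshold = 5.0,
              angle_units = "degrees", resample_mm = 1.0,
              proximal_hint = c(0, 0, 1e6), seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Hash of a run configuration (provenance key)
#'
#' Canonical-JSON MD5; two artifacts with equal hashes were produced with
#' identical parameters.
#'
#' @param config a [run_config()].
#' @return character MD5 hex digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a case manifest (JSON)
#'
#' A manifest describes one case's follow-up series: `case_id` and a list of
#' `timepoints`, each with `label`, a `volume` (HU NIfTI) or `mask` (binary
#' NIfTI) path, an `origin` landmark \[x, y, z\] in mm, and optionally a
#' `reference_points` CSV for extraction QC. Relative paths resolve against
#' the manifest's directory.
#'
#' @param path manifest JSON path.
#' @return validated manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$case_id) || is.null(m$timepoints) || !length(m$timepoints))
    stop("manifest needs case_id and a non-empty timepoints list")
  base <- dirname(normalizePath(path))
  labels <- character(0)
  m$timepoints <- lapply(m$timepoints, function(tp) {
    if (is.null(tp$label)) stop("manifest timepoint without label")
    if (is.null(tp$volume) && is.null(tp$mask))
      stop("timepoint ", tp$label, ": needs a volume or mask path")
    if (is.null(tp$origin) || length(tp$origin) != 3L)
      stop("timepoint ", tp$label, ": origin must be [x, y, z] mm")
    for (f in c("volume", "mask", "reference_points")) {
      if (!is.null(tp[[f]]) && !grepl("^/", tp[[f]]))
        tp[[f]] <- file.path(base, tp[[f]])
      if (!is.null(tp[[f]]) && !file.exists(tp[[f]]))
        stop("timepoint ", tp$label, ": missing file ", tp[[f]])
    }
    tp$origin <- as.numeric(unlist(tp$origin))
    tp
  })
  labels <- vapply(m$timepoints, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate timepoint labels in manifest")
  m
}

#' 3-D scatter plot of observation point sets
#'
#' Static orthographic 3-D scatter (PNG), one color per timepoint, each
#' ring's peaks connected in angular order — the standard follow-up overlay
#' view. Deterministic output for fixed input.
#'
#' @param sets list of [observation_point_set()]s.
#' @param out_path output PNG path.
#' @param view_deg c(azimuth, elevation) of the orthographic view, degrees.
#' @return `out_path`, invisibly.
#' @export
plot_points <- function(sets, out_path, view_deg = c(30, 20)) {
  stopifnot(length(sets) >= 1L)
  az <- view_deg[1] * pi / 180; el <- view_deg[2] * pi / 180
  proj <- function(xyz) {
    x1 <- xyz[, 1] * cos(az) + xyz[, 2] * sin(az)
    y1 <- -xyz[, 1] * sin(az) + xyz[, 2] * cos(az)
    cbind(h = x1, v = xyz[, 3] * cos(el) - y1 * sin(el))
  }
  all_xyz <- do.call(rbind, lapply(sets, peak_coords))
  pr_all <- proj(all_xyz)
  cols <- grDevices::hcl.colors(max(length(sets), 2L), "Dark 3")
  grDevices::png(out_path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  graphics::plot(pr_all, type = "n", xlab = "", ylab = "", asp = 1,
                 main = paste0(sets[[1]]$case_id, ": observation points"))
  if (nrow(all_xyz) == 0L) warning("plot_points: empty point sets")
  for (i in seq_along(sets)) {
    p <- sets[[i]]$peaks
    if (!nrow(p)) next
    for (r in unique(p$ring_index)) for (o in unique(p$orientation)) {
      sub <- p[p$ring_index == r & p$orientation == o, , drop = FALSE]
      pr <- proj(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]))
      if (nrow(pr) > 2L)
        graphics::lines(rbind(pr, pr[1, , drop = FALSE]), col = cols[i])
      graphics::points(pr, col = cols[i], pch = 19)
    }
  }
  graphics::legend("topright",
                   legend = vapply(sets, `[[`, character(1), "timepoint"),
                   col = cols[seq_along(sets)], pch = 19)
  invisible(out_path)
}

#' Run the full measurement pipeline for one case
#'
#' Per timepoint: read the volume or mask; if a volume, resample to isotropic
#' spacing, threshold-segment and keep the stent region; extract the peak
#' observation points; register to the timepoint's origin landmark. Then
#' measure the follow-up series (slip, ring rate, deflection), optionally
#' score extraction against reference point sets, and write all artifacts
#' (point CSVs, report JSON, overlay PNG) under `out_dir`. The report embeds
#' the config and its hash and contains no timestamps, so reruns are
#' byte-identical.
#'
#' @param manifest manifest list from [read_manifest()] (or equivalent).
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param plot also write the 3-D overlay PNG.
#' @return the report list, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir,
                         plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(label, what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s / %s / %s] %s", manifest$case_id, label, what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  sets <- list()
  agreements <- list()
  log_lines <- character(0)
  logit <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  for (tp in manifest$timepoints) {
    mask <- if (!is.null(tp$mask)) {
      stage(tp$label, "read_mask", read_volume(tp$mask))
    } else {
      vol <- stage(tp$label, "read_volume", read_volume(tp$volume))
      if (max(abs(vol$spacing - config$resample_mm)) > 1e-9)
        vol <- stage(tp$label, "resample",
                     resample_isotropic(vol, config$resample_mm))
      m <- stage(tp$label, "threshold",
                 threshold_segment(vol, config$lo_hu, config$hi_hu))
      logit("%s: threshold mask %d voxels", tp$label, sum(m$values))
      stage(tp$label, "select_region",
            select_stent_region(m, "largest",
                                fraction = config$region_fraction))
    }
    logit("%s: stent mask %d voxels", tp$label, sum(mask$values))
    pts <- stage(tp$label, "extract_peaks", extract_peaks(
      mask, orientation = config$orientation,
      n_sectors = config$n_sectors, amp_fraction = config$amp_fraction,
      nms_window = config$nms_window,
      min_amplitude_mm = config$min_amplitude_mm,
      cluster_radius = config$cluster_radius,
      min_volume_voxels = config$min_volume_voxels,
      proximal_hint = config$proximal_hint,
      case_id = manifest$case_id, timepoint = tp$label,
      origin_landmark = tp$origin))
    logit("%s: %d peaks in %d ring(s)", tp$label, nrow(pts$peaks),
          length(unique(pts$peaks$ring_index)))
    write_points(pts, file.path(out_dir, paste0("points_", tp$label, ".csv")))
    if (!is.null(tp$reference_points)) {
      ref <- stage(tp$label, "reference", read_points(tp$reference_points))
      agr <- compare_point_sets(pts, ref,
                                match_threshold = config$match_threshold)
      agreements[[tp$label]] <- list(
        n_reference = agr$n_reference, n_missing = agr$n_missing,
        missing_rate_pct = agr$missing_rate_pct,
        d_mean_mm = agr$d_mean, d_max_mm = agr$d_max)
    }
    sets[[tp$label]] <- stage(tp$label, "register", register_to_origin(pts))
  }
  report <- NULL
  if (length(sets) >= 2L) {
    rep_ <- stage("series", "measure",
                  measure_series(sets,
                                 degrees = config$angle_units == "degrees"))
    report <- list(slip = rep_$slip, diameter = rep_$diameter,
                   deflection = rep_$deflection)
  }
  out <- list(case_id = manifest$case_id,
              timepoints = vapply(manifest$timepoints, `[[`, character(1),
                                  "label"),
              config = unclass(config), config_hash = config_hash(config),
              extraction_agreement = if (length(agreements)) agreements,
              measurements = report)
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  if (plot && length(sets))
    plot_points(sets, file.path(out_dir, "points.png"))
  invisible(out)
}
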