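#' Observation point set
#'
#' The basic, non-divisible dataset of the measurement method: the peak
#' (apex) points of every support ring of one case at one timepoint, plus the
#' skeletal origin landmark used to register timepoints into a common frame.
#'
#' @param peaks data.frame with columns `ring_index`, `peak_index`,
#'   `orientation` ("proximal"/"distal"), `x_mm`, `y_mm`, `z_mm`,
#'   `angular_deg`, `axial_mm`, `source` ("auto"/"manual"). Missing
#'   `angular_deg`/`axial_mm`/`source` are filled with NA/"manual".
#' @param case_id case identifier.
#' @param timepoint follow-up label ("T1", "T2", ...).
#' @param origin_landmark world-mm skeletal origin (12th thoracic vertebra
#'   landmark) for this timepoint.
#' @param registered whether coordinates are already origin-registered.
#' @return object of class `observation_point_set`; rows canonically ordered
#'   by ring, orientation, then angular coordinate (peak index as fallback).
#' @export
observation_point_set <- function(peaks, case_id = "case",
                                  timepoint = "T1",
                                  origin_landmark = c(0, 0, 0),
                                  registered = FALSE) {
  need <- c("ring_index", "peak_index", "orientation", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (!"angular_deg" %in% names(peaks)) peaks$angular_deg <- NA_real_
  if (!"axial_mm" %in% names(peaks)) peaks$axial_mm <- NA_real_
  if (!"source" %in% names(peaks)) peaks$source <- "manual"
  if (anyDuplicated(peaks[, c("ring_index", "peak_index", "orientation")]))
    stop("duplicate (ring_index, peak_index, orientation) in peak table")
  ang <- ifelse(is.na(peaks$angular_deg), peaks$peak_index, peaks$angular_deg)
  ord <- order(peaks$ring_index, peaks$orientation, ang, peaks$peak_index)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  origin_landmark <- as.numeric(origin_landmark)
  stopifnot(length(origin_landmark) == 3L)
  structure(list(case_id = case_id, timepoint = timepoint,
                 origin_landmark = origin_landmark,
                 registered = isTRUE(registered), peaks = peaks),
            class = "observation_point_set")
}

#' @export
print.observation_point_set <- function(x, ...) {
  cat(sprintf("<observation_point_set> case %s, %s: %d peaks in %d ring(s)%s\n",
              x$case_id, x$timepoint, nrow(x$peaks),
              length(unique(x$peaks$ring_index)),
              if (x$registered) " (registered)" else ""))
  invisible(x)
}

peak_coords <- function(set, ring = NULL, orientation = NULL) {
  p <- set$peaks
  if (!is.null(ring)) p <- p[p$ring_index %in% ring, , drop = FALSE]
  if (!is.null(orientation))
    p <- p[p$orientation %in% orientation, , drop = FALSE]
  as.matrix(p[, c("x_mm", "y_mm", "z_mm")])
}

#' Write an observation point set to CSV
#'
#' Columns: case_id, timepoint, ring_index, peak_index, orientation, x_mm,
#' y_mm, z_mm, angular_deg, axial_mm, source, registered, origin_{x,y,z}_mm.
#' Coordinates are serialized at 17 significant digits so the round trip is
#' exact.
#'
#' @param set an [observation_point_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(set, path) {
  stopifnot(inherits(set, "observation_point_set"))
  p <- set$peaks
  df <- data.frame(
    case_id = set$case_id, timepoint = set$timepoint,
    ring_index = p$ring_index, peak_index = p$peak_index,
    orientation = p$orientation,
    x_mm = sprintf("%.17g", p$x_mm), y_mm = sprintf("%.17g", p$y_mm),
    z_mm = sprintf("%.17g", p$z_mm),
    angular_deg = sprintf("%.17g", p$angular_deg),
    axial_mm = sprintf("%.17g", p$axial_mm),
    source = p$source,
    registered = set$registered,
    origin_x_mm = sprintf("%.17g", set$origin_landmark[1]),
    origin_y_mm = sprintf("%.17g", set$origin_landmark[2]),
    origin_z_mm = sprintf("%.17g", set$origin_landmark[3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation point set from CSV
#'
#' @param path CSV written by [write_points()] (or hand-made with the same
#'   schema; origin/registration columns default to unregistered origin 0).
#' @return an [observation_point_set()].
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("no such point-set file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ring_index", "peak_index", "orientation", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("point-set CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  origin <- if (all(c("origin_x_mm", "origin_y_mm", "origin_z_mm") %in%
                    names(df)) && nrow(df) > 0) {
    c(df$origin_x_mm[1], df$origin_y_mm[1], df$origin_z_mm[1])
  } else c(0, 0, 0)
  observation_point_set(
    df[, intersect(names(df),
                   c(need, "angular_deg", "axial_mm", "source"))],
    case_id = if ("case_id" %in% names(df) && nrow(df)) df$case_id[1] else "case",
    timepoint = if ("timepoint" %in% names(df) && nrow(df)) df$timepoint[1] else "T1",
    origin_landmark = origin,
    registered = "registered" %in% names(df) && nrow(df) > 0 &&
      isTRUE(as.logical(df$registered[1])))
}

#' Write an observation point set as JSON (with provenance metadata)
#'
#' @param set an [observation_point_set()].
#' @param path output JSON path.
#' @param config optional run configuration to hash into the metadata.
#' @return `path`, invisibly.
#' @export
write_points_json <- function(set, path, config = NULL) {
  obj <- list(case_id = set$case_id, timepoint = set$timepoint,
              origin_landmark = set$origin_landmark,
              registered = set$registered,
              config_hash = if (!is.null(config)) config_hash(config) else NULL,
              peaks = set$peaks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an observation point set from JSON
#' @param path JSON written by [write_points_json()].
#' @return an [observation_point_set()].
#' @export
read_points_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  observation_point_set(as.data.frame(obj$peaks), case_id = obj$case_id,
                        timepoint = obj$timepoint,
                        origin_landmark = unlist(obj$origin_landmark),
                        registered = isTRUE(obj$registered))
}
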