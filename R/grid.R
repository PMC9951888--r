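#' Voxel grid container
#'
#' A `voxel_grid` is the carrier of CT intensity data (Hounsfield units) and of
#' binary stent masks: a 3-D array plus the geometry needed to convert between
#' 0-based voxel indices and world millimetre coordinates,
#' `world = origin + index * spacing` (axis-aligned grids only).
#'
#' @param values numeric or integer 3-D array.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world-mm coordinate of voxel (0,0,0)'s
#'   center.
#' @return An object of class `voxel_grid` with elements `values`, `spacing`,
#'   `origin`, `dims`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         dims = dim(values)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

is_binary_grid <- function(grid) {
  v <- grid$values
  all(v == 0 | v == 1)
}

stopifnot_same_geometry <- function(a, b) {
  if (!identical(a$dims, b$dims) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop("voxel grids have mismatched geometry (dims/spacing/origin)")
  invisible(TRUE)
}

#' Convert 0-based voxel indices to world millimetres
#'
#' @param grid a [voxel_grid()].
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric matrix (n x 3) of world-mm coordinates of voxel centers.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Convert world millimetres to (fractional) 0-based voxel indices
#' @param grid a [voxel_grid()].
#' @param xyz numeric matrix (n x 3) of world-mm points.
#' @return numeric matrix (n x 3) of fractional 0-based indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid$origin, `-`), 2, grid$spacing, `/`)
}

# n x 3 matrix of 0-based indices of all foreground (> 0) voxels
foreground_indices <- function(grid) {
  w <- which(grid$values > 0)
  if (length(w) == 0L)
    return(matrix(numeric(0), ncol = 3))
  arrayInd(w, grid$dims) - 1L
}

# world-mm coordinates of all foreground voxel centers
foreground_world <- function(grid) {
  voxel_to_world(grid, foreground_indices(grid))
}
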