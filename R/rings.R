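#' Separate a stent mask into support-ring components
#'
#' Labels 26-connected components and drops those below `min_volume_voxels`
#' (speckle; real support rings are orders of magnitude larger at 1 mm
#' resolution). Components are returned sorted by label with voxel indices,
#' volumes and voxel-mass centroids.
#'
#' @param mask binary [voxel_grid()].
#' @param min_volume_voxels minimum component volume in voxels.
#' @param connectivity 6, 18 or 26.
#' @return list of `ring_component` objects: `label`, `voxel_idx` (0-based
#'   n x 3), `volume_voxels`, `volume_mm3`, `centroid` (world mm),
#'   `ring_index` (NA until [order_rings()]).
#' @export
label_rings <- function(mask, min_volume_voxels = 50, connectivity = 26L) {
  stopifnot(inherits(mask, "voxel_grid"))
  cc <- label_components_26(mask, connectivity)
  if (length(cc$sizes) == 0L) stop("mask contains no foreground voxels")
  keep <- which(cc$sizes >= min_volume_voxels)
  if (length(keep) == 0L)
    stop("no component reaches min_volume_voxels = ", min_volume_voxels)
  n_dropped <- length(cc$sizes) - length(keep)
  if (n_dropped > 0)
    message(sprintf("label_rings: dropped %d sub-threshold component(s) (%d voxels total)",
                    n_dropped, sum(cc$sizes[-keep])))
  vox_mm3 <- prod(mask$spacing)
  lapply(seq_along(keep), function(i) {
    lab <- keep[i]
    vidx <- cc$idx[cc$labels == lab, , drop = FALSE]
    structure(list(
      label = i,
      voxel_idx = vidx,
      volume_voxels = nrow(vidx),
      volume_mm3 = nrow(vidx) * vox_mm3,
      centroid = colMeans(voxel_to_world(mask, vidx)),
      ring_index = NA_integer_), class = "ring_component")
  })
}

#' Midpoint of a ring's peak points
#'
#' The ring midpoint (point_mid) is the per-axis arithmetic mean of the peak
#' point coordinates — the basic derived quantity all ring-level parameters
#' build on.
#'
#' @param points numeric matrix (n x 3) of points, mm.
#' @return numeric length-3 mean point.
#' @export
point_mid <- function(points) {
  points <- rbind(points)
  if (nrow(points) == 0L) stop("point_mid of an empty point list")
  colMeans(points)
}

#' Voxel-mass centroid of a ring component
#'
#' The center of gravity of all foreground voxel centers in world mm.
#' Distinct from [point_mid()], which averages extracted peak points; both
#' are exposed and the centroid is the default control point for centerline
#' fitting.
#'
#' @param component a `ring_component` from [label_rings()].
#' @param grid the mask [voxel_grid()] the component was labeled in.
#' @return numeric length-3 centroid, mm.
#' @export
ring_centroid <- function(component, grid) {
  if (nrow(component$voxel_idx) == 0L) stop("empty ring component")
  colMeans(voxel_to_world(grid, component$voxel_idx))
}

#' Assign ring indices from proximal to distal
#'
#' Projects the component centroids on their first principal direction,
#' orients that axis toward `proximal_hint` (a world-mm point near the
#' proximal end; default far +z, the superior direction in RAS-oriented
#' volumes), and numbers rings 1 (most proximal) to M. Ties are broken by
#' label order.
#'
#' @param components list of `ring_component`s.
#' @param proximal_hint world-mm point marking the proximal side.
#' @return the components, reordered with `ring_index` set to 1..M.
#' @export
order_rings <- function(components, proximal_hint = c(0, 0, 1e6)) {
  stopifnot(length(components) >= 1L)
  cen <- do.call(rbind, lapply(components, `[[`, "centroid"))
  if (length(components) == 1L) {
    components[[1]]$ring_index <- 1L
    return(components)
  }
  cen_c <- sweep(cen, 2, colMeans(cen), `-`)
  axis <- svd(cen_c, nu = 0, nv = 1)$v[, 1]
  # orient axis so the proximal hint projects highest
  if (sum((proximal_hint - colMeans(cen)) * axis) < 0) axis <- -axis
  proj <- as.vector(cen_c %*% axis)
  ord <- order(-proj, seq_along(components))   # most proximal first
  if (anyDuplicated(round(proj, 9)))
    warning("tied centroid projections; ring order broken by label")
  out <- components[ord]
  for (i in seq_along(out)) out[[i]]$ring_index <- i
  out
}

#' Fit the stent centerline through ordered ring centroids
#'
#' Interpolating natural cubic spline through the ring centroids, one spline
#' per coordinate, parameterized by cumulative chord length (avoids ringing
#' with uneven ring spacing). With two centroids the spline degenerates to
#' the straight segment.
#'
#' @param centroids matrix (M x 3) of ring centroids ordered proximal to
#'   distal.
#' @return a `centerline` object with `$position(t)`, `$tangent(t)` (unit),
#'   `$t_control` (parameter of each centroid) and `$control_points`.
#' @export
fit_centerline <- function(centroids) {
  centroids <- rbind(centroids)
  m <- nrow(centroids)
  if (m < 2L) stop("centerline needs at least 2 ring centroids")
  seg <- sqrt(rowSums(diff(centroids)^2))
  if (any(seg < 1e-9)) stop("duplicate consecutive centroids")
  t_ctrl <- c(0, cumsum(seg))
  fns <- lapply(1:3, function(a) {
    stats::splinefun(t_ctrl, centroids[, a], method = "natural")
  })
  position <- function(t) {
    cbind(fns[[1]](t), fns[[2]](t), fns[[3]](t))
  }
  tangent <- function(t) {
    d <- cbind(fns[[1]](t, deriv = 1), fns[[2]](t, deriv = 1),
               fns[[3]](t, deriv = 1))
    nrm <- sqrt(rowSums(d^2))
    if (any(nrm < 1e-12)) stop("degenerate centerline tangent")
    d / nrm
  }
  structure(list(position = position, tangent = tangent,
                 t_control = t_ctrl, control_points = centroids),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d control points, length %.1f mm (chord)\n",
              nrow(x$control_points), max(x$t_control)))
  invisible(x)
}
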