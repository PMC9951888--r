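#' Parametric stent phantom specification
#'
#' Describes a multi-ring zig-zag stent-graft phantom: `n_rings` circumferential
#' support rings, each a closed wire following
#' `C_r(theta) = O_r + R (cos(theta) U + sin(theta) V) + A z(N_p * theta) T`,
#' where `z` is a unit triangle wave (sharp apices; a sinusoid is available via
#' `profile = "sine"`). Every ring has `apices_per_ring` proximal and as many
#' distal apices. Defaults are sized like a thoracic stent-graft at the 1 mm
#' isotropic resolution the measurement pipeline works at.
#'
#' @param n_rings number of support rings M (>= 1).
#' @param apices_per_ring zig-zag apex count per ring N_p (>= 3).
#' @param ring_radius ring radius R in mm.
#' @param apex_amplitude half peak-to-peak axial excursion A of the zig-zag, mm.
#' @param ring_spacing centerline distance between consecutive ring centers, mm.
#' @param wire_radius wire (strut) radius in mm.
#' @param centerline_kind `"straight"` or `"arc"` (circular arc in the x-z
#'   plane with radius `centerline_radius`).
#' @param centerline_radius arc radius in mm (used when `centerline_kind`
#'   is `"arc"`).
#' @param grid_spacing isotropic voxel size for voxelization, mm.
#' @param stent_hu,vessel_hu,background_hu Hounsfield values for CT synthesis;
#'   stent metal must lie in the segmentation band \[1200, 2200\] and
#'   contrast-filled vessel in \[300, 700\].
#' @param noise_sd additive Gaussian CT noise, HU.
#' @param seed RNG seed for CT noise.
#' @param profile `"triangle"` (default, sharp apices) or `"sine"`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_rings = 7, apices_per_ring = 5,
                         ring_radius = 15, apex_amplitude = 7.5,
                         ring_spacing = 22, wire_radius = 0.8,
                         centerline_kind = c("straight", "arc"),
                         centerline_radius = 200,
                         grid_spacing = 1,
                         stent_hu = 1700, vessel_hu = 500, background_hu = 0,
                         noise_sd = 0, seed = 1L,
                         profile = c("triangle", "sine")) {
  centerline_kind <- match.arg(centerline_kind)
  profile <- match.arg(profile)
  if (n_rings < 1) stop("n_rings must be >= 1")
  if (apices_per_ring < 3) stop("apices_per_ring must be >= 3 (degenerate ring)")
  lens <- c(ring_radius, apex_amplitude, ring_spacing, wire_radius,
            grid_spacing, centerline_radius)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom dimensions must be positive")
  if (stent_hu < 1200 || stent_hu > 2200)
    stop("stent_hu must lie in [1200, 2200]")
  if (vessel_hu < 300 || vessel_hu > 700)
    stop("vessel_hu must lie in [300, 700]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(n_rings = as.integer(n_rings),
         apices_per_ring = as.integer(apices_per_ring),
         ring_radius = ring_radius, apex_amplitude = apex_amplitude,
         ring_spacing = ring_spacing, wire_radius = wire_radius,
         centerline_kind = centerline_kind,
         centerline_radius = centerline_radius,
         grid_spacing = grid_spacing,
         stent_hu = stent_hu, vessel_hu = vessel_hu,
         background_hu = background_hu,
         noise_sd = noise_sd, seed = as.integer(seed), profile = profile),
    class = "phantom_spec")
}

# unit triangle wave: period 2*pi, z(0) = 1, z(pi) = -1, linear in between
triangle_wave <- function(u) {
  w <- (u / (2 * pi)) %% 1
  ifelse(w < 0.5, 1 - 4 * w, 4 * w - 3)
}

zigzag_profile <- function(u, profile) {
  if (profile == "sine") cos(u) else triangle_wave(u)
}

# centerline position and orthonormal frame (U radial-ish, V, T tangent) at
# arc length s from the proximal end; proximal end at world origin (0,0,0),
# tangent pointing distal (+z at s = 0)
centerline_frame <- function(s, spec) {
  if (spec$centerline_kind == "straight") {
    list(O = c(0, 0, s), U = c(1, 0, 0), V = c(0, 1, 0), T = c(0, 0, 1))
  } else {
    Rc <- spec$centerline_radius
    phi <- s / Rc
    O <- c(Rc * (1 - cos(phi)), 0, Rc * sin(phi))
    T <- c(sin(phi), 0, cos(phi))
    U <- c(cos(phi), 0, -sin(phi))
    V <- c(0, 1, 0)                      # T x U = (0,1,0) kept right-handed
    list(O = O, U = U, V = V, T = T)
  }
}

ring_curve_points <- function(ring, thetas, spec) {
  z <- zigzag_profile(spec$apices_per_ring * thetas, spec$profile)
  pts <- outer(cos(thetas), ring$U) + outer(sin(thetas), ring$V)
  pts <- spec$ring_radius * pts + spec$apex_amplitude * outer(z, ring$T)
  sweep(pts, 2, ring$O, `+`)
}

#' Generate an analytic stent phantom with apex ground truth
#'
#' Builds the ring curves, densely samples them (step `grid_spacing / 4`, so
#' voxelization aliasing stays below a quarter voxel), and records the exact
#' analytic apex coordinates: `apices_per_ring` proximal apices at the zig-zag
#' maxima and as many distal apices at the minima of every ring. Ring centers
#' are spaced `ring_spacing` apart along the centerline, ring 1 most proximal.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `stent_phantom`: the spec, per-ring frames and
#'   dense curve samples, a `ground_truth` data.frame (ring_index, apex_index,
#'   orientation, x_mm, y_mm, z_mm), `ring_centers` matrix, and the (initially
#'   empty) list of applied deformations.
#' @export
generate_stent <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  Np <- spec$apices_per_ring
  step <- spec$grid_spacing / 4
  speed_max <- sqrt(spec$ring_radius^2 + (2 * spec$apex_amplitude * Np / pi)^2)
  n_theta <- max(64L, ceiling(2 * pi * speed_max / step))
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  prox_theta <- 2 * pi * (seq_len(Np) - 1L) / Np
  dist_theta <- prox_theta + pi / Np

  rings <- vector("list", spec$n_rings)
  gt <- vector("list", spec$n_rings)
  centers <- matrix(0, spec$n_rings, 3)
  # ring 1 is most proximal; arc length s runs distal -> proximal so the
  # frame tangent T (and the +A apices) point proximal (superior, +z)
  for (r in seq_len(spec$n_rings)) {
    fr <- centerline_frame((spec$n_rings - r) * spec$ring_spacing, spec)
    fr$curve <- ring_curve_points(fr, thetas, spec)
    rings[[r]] <- fr
    centers[r, ] <- fr$O
    pa <- ring_curve_points(fr, prox_theta, spec)
    da <- ring_curve_points(fr, dist_theta, spec)
    gt[[r]] <- data.frame(
      ring_index = r,
      apex_index = rep(seq_len(Np), 2L),
      orientation = rep(c("proximal", "distal"), each = Np),
      x_mm = c(pa[, 1], da[, 1]), y_mm = c(pa[, 2], da[, 2]),
      z_mm = c(pa[, 3], da[, 3]))
  }
  structure(
    list(spec = spec, rings = rings,
         ground_truth = do.call(rbind, gt),
         ring_centers = centers,
         transforms = list()),
    class = "stent_phantom")
}

#' @export
print.stent_phantom <- function(x, ...) {
  cat(sprintf(
    "<stent_phantom> %d rings x %d apices, R = %g mm, A = %g mm, %d deformation(s)\n",
    x$spec$n_rings, x$spec$apices_per_ring, x$spec$ring_radius,
    x$spec$apex_amplitude, length(x$transforms)))
  invisible(x)
}

apex_matrix <- function(gt) {
  as.matrix(gt[, c("x_mm", "y_mm", "z_mm")])
}

#' Voxelize a stent phantom into a binary mask
#'
#' A voxel is foreground iff its center lies within `wire_radius` of any dense
#' curve sample. The grid covers the stent with a margin and stores
#' spacing/origin so voxel-to-mm conversion is exact.
#'
#' @param stent a [generate_stent()] result (possibly deformed).
#' @param spec the [phantom_spec()]; defaults to the one inside `stent`.
#' @param margin_mm extra empty space around the stent bounding box.
#' @return binary [voxel_grid()] mask.
#' @export
voxelize <- function(stent, spec = stent$spec, margin_mm = 3) {
  stopifnot(inherits(stent, "stent_phantom"))
  h <- spec$grid_spacing
  samples <- do.call(rbind, lapply(stent$rings, `[[`, "curve"))
  lo <- apply(samples, 2, min) - spec$wire_radius - margin_mm
  hi <- apply(samples, 2, max) + spec$wire_radius + margin_mm
  dims <- as.integer(floor((hi - lo) / h)) + 1L
  origin <- lo
  vals <- array(0L, dim = dims)

  # voxel centers within wire_radius of a sample are at most
  # wire_radius/h + 0.5 index steps from the sample's nearest voxel
  r_off <- floor(spec$wire_radius / h + 0.5)
  offs <- as.matrix(expand.grid(dx = -r_off:r_off, dy = -r_off:r_off,
                                dz = -r_off:r_off))
  nearest <- round(sweep(samples, 2, origin, `-`) / h)
  for (k in seq_len(nrow(offs))) {
    cand <- sweep(nearest, 2, offs[k, ], `+`)
    centers <- sweep(cand * h, 2, origin, `+`)
    d2 <- rowSums((centers - samples)^2)
    ok <- d2 <= spec$wire_radius^2 &
      cand[, 1] >= 0 & cand[, 1] < dims[1] &
      cand[, 2] >= 0 & cand[, 2] < dims[2] &
      cand[, 3] >= 0 & cand[, 3] < dims[3]
    if (any(ok)) {
      lin <- cand[ok, 1] + dims[1] * (cand[ok, 2] + dims[2] * cand[ok, 3])
      vals[lin + 1] <- 1L
    }
  }
  if (sum(vals) == 0L)
    stop("voxelization produced an empty mask (wire_radius ",
         spec$wire_radius, " mm too thin for grid_spacing ", h, " mm)")
  voxel_grid(vals, spacing = rep(h, 3), origin = origin)
}

#' Voxelize the vessel lumen around the phantom centerline
#'
#' Builds a solid tube of radius `ring_radius` (the stent apposes the vessel
#' wall) on the same grid as `mask`, used as the vessel compartment for CT
#' synthesis.
#'
#' @param stent a [generate_stent()] result.
#' @param mask the stent mask [voxel_grid()] whose grid geometry to reuse.
#' @param lumen_radius vessel lumen radius, mm; default `ring_radius`.
#' @return binary [voxel_grid()].
#' @export
voxelize_vessel <- function(stent, mask, lumen_radius = stent$spec$ring_radius) {
  spec <- stent$spec
  s_end <- (spec$n_rings - 1) * spec$ring_spacing + 2 * spec$apex_amplitude
  s_grid <- seq(-2 * spec$apex_amplitude, s_end, by = spec$grid_spacing / 2)
  cl <- t(vapply(s_grid, function(s) centerline_frame(s, spec)$O, numeric(3)))

  idx <- as.matrix(expand.grid(x = 0:(mask$dims[1] - 1L),
                               y = 0:(mask$dims[2] - 1L),
                               z = 0:(mask$dims[3] - 1L)))
  xyz <- voxel_to_world(mask, idx)
  inside <- rep(FALSE, nrow(xyz))
  # chunked nearest-centerline distance to bound memory
  chunk <- 20000L
  for (start in seq(1L, nrow(xyz), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(xyz))
    d2 <- matrix(Inf, length(rows), 1)
    best <- rep(Inf, length(rows))
    for (cstart in seq(1L, nrow(cl), by = 500L)) {
      crows <- cstart:min(cstart + 499L, nrow(cl))
      dd <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rep(1, length(crows))) -
        2 * xyz[rows, , drop = FALSE] %*% t(cl[crows, , drop = FALSE]) +
        outer(rep(1, length(rows)), rowSums(cl[crows, , drop = FALSE]^2))
      best <- pmin(best, apply(dd, 1, min))
    }
    inside[rows] <- best <= lumen_radius^2
  }
  vals <- array(0L, dim = mask$dims)
  vals[inside] <- 1L
  voxel_grid(vals, spacing = mask$spacing, origin = mask$origin)
}

#' Synthesize a CT-like HU volume from stent and vessel masks
#'
#' Stent voxels get `stent_hu`, vessel voxels `vessel_hu`, the rest
#' `background_hu`; stent occludes vessel where they overlap. Gaussian noise
#' of `noise_sd` HU is added under `spec$seed`, so output is deterministic for
#' a fixed seed.
#'
#' @param mask binary stent mask [voxel_grid()].
#' @param vessel_mask binary vessel mask on the same grid, or `NULL`.
#' @param spec a [phantom_spec()] carrying HU values, noise level and seed.
#' @return HU [voxel_grid()].
#' @export
synthesize_ct <- function(mask, vessel_mask = NULL, spec) {
  stopifnot(inherits(mask, "voxel_grid"), inherits(spec, "phantom_spec"))
  if (!is.null(vessel_mask)) stopifnot_same_geometry(mask, vessel_mask)
  vals <- array(spec$background_hu, dim = mask$dims)
  if (!is.null(vessel_mask)) vals[vessel_mask$values > 0] <- spec$vessel_hu
  vals[mask$values > 0] <- spec$stent_hu
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(length(vals), sd = spec$noise_sd),
                         dim = dim(vals))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  voxel_grid(vals, spacing = mask$spacing, origin = mask$origin)
}

#' Describe one kinematic follow-up deformation
#'
#' Deformations stand in for the motion and deformation a stent-graft
#' undergoes between follow-up scans. Supported kinds: `translate` (rigid
#' shift, mm vector), `radial_scale` (in-plane scaling about each selected
#' ring's own center), `twist` (rotation of each selected ring about its local
#' centerline tangent, degrees, right-handed about the proximal direction), and
#' `bend` (rigid rotation of the selected rings about an axis through a pivot
#' point).
#'
#' @param kind one of `"translate"`, `"radial_scale"`, `"twist"`, `"bend"`.
#' @param parameters `translate`: length-3 mm vector; `radial_scale`: positive
#'   scalar factor; `twist`: angle in degrees; `bend`: list(axis, angle_deg,
#'   pivot).
#' @param applies_to integer ring indices, or `NULL` for the whole stent.
#' @param timepoint_label label such as `"T2"`.
#' @return object of class `deformation_record`.
#' @export
deformation <- function(kind = c("translate", "radial_scale", "twist", "bend"),
                        parameters, applies_to = NULL,
                        timepoint_label = "T2") {
  kind <- match.arg(kind)
  if (kind == "translate") {
    parameters <- as.numeric(parameters)
    if (length(parameters) != 3L || any(!is.finite(parameters)))
      stop("translate needs a finite length-3 mm vector")
  } else if (kind == "radial_scale") {
    parameters <- as.numeric(parameters)
    if (length(parameters) != 1L || !is.finite(parameters) || parameters <= 0)
      stop("radial_scale factor must be a positive scalar")
  } else if (kind == "twist") {
    parameters <- as.numeric(parameters)
    if (length(parameters) != 1L || !is.finite(parameters))
      stop("twist angle (degrees) must be a finite scalar")
  } else {
    if (!is.list(parameters) || is.null(parameters$axis) ||
        is.null(parameters$angle_deg))
      stop("bend needs list(axis, angle_deg, pivot)")
    parameters$axis <- as.numeric(parameters$axis)
    if (sqrt(sum(parameters$axis^2)) <= 0) stop("bend axis must be nonzero")
  }
  structure(list(kind = kind, parameters = parameters,
                 applies_to = if (!is.null(applies_to)) as.integer(applies_to),
                 timepoint_label = timepoint_label),
            class = "deformation_record")
}

rotate_about_axis <- function(pts, axis, angle_rad, pivot) {
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(rbind(pts), 2, pivot, `-`)
  kx <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
              k[3] * p[, 1] - k[1] * p[, 3],
              k[1] * p[, 2] - k[2] * p[, 1])
  kdot <- as.vector(p %*% k)
  out <- p * cos(angle_rad) + kx * sin(angle_rad) +
    outer(kdot * (1 - cos(angle_rad)), k)
  sweep(out, 2, pivot, `+`)
}

#' Apply a deformation to a stent phantom, tracking ground truth exactly
#'
#' Transforms the dense ring curves, the analytic apex ground truth, the ring
#' centers (and frames where the deformation rotates them), and appends the
#' record to the phantom's transform history so compositions are replayable.
#'
#' @param stent a [generate_stent()] result.
#' @param record a [deformation()].
#' @return the deformed `stent_phantom`.
#' @export
apply_deformation <- function(stent, record) {
  stopifnot(inherits(stent, "stent_phantom"),
            inherits(record, "deformation_record"))
  sel <- if (is.null(record$applies_to)) seq_len(stent$spec$n_rings) else
    record$applies_to
  if (any(sel < 1L | sel > stent$spec$n_rings))
    stop("applies_to ring indices out of range 1..", stent$spec$n_rings)
  gt_rows <- stent$ground_truth$ring_index %in% sel
  ap <- apex_matrix(stent$ground_truth)

  if (record$kind == "translate") {
    v <- record$parameters
    for (r in sel) {
      stent$rings[[r]]$curve <- sweep(stent$rings[[r]]$curve, 2, v, `+`)
      stent$rings[[r]]$O <- stent$rings[[r]]$O + v
      stent$ring_centers[r, ] <- stent$ring_centers[r, ] + v
    }
    ap[gt_rows, ] <- sweep(ap[gt_rows, , drop = FALSE], 2, v, `+`)
  } else if (record$kind == "radial_scale") {
    s <- record$parameters
    scale_ring <- function(pts, O, T) {
      rel <- sweep(rbind(pts), 2, O, `-`)
      ax <- as.vector(rel %*% T)
      rad <- rel - outer(ax, T)
      sweep(s * rad + outer(ax, T), 2, O, `+`)
    }
    for (r in sel) {
      fr <- stent$rings[[r]]
      stent$rings[[r]]$curve <- scale_ring(fr$curve, fr$O, fr$T)
      rows <- which(gt_rows & stent$ground_truth$ring_index == r)
      ap[rows, ] <- scale_ring(ap[rows, , drop = FALSE], fr$O, fr$T)
    }
  } else if (record$kind == "twist") {
    ang <- record$parameters * pi / 180
    for (r in sel) {
      fr <- stent$rings[[r]]
      stent$rings[[r]]$curve <- rotate_about_axis(fr$curve, fr$T, ang, fr$O)
      rows <- which(gt_rows & stent$ground_truth$ring_index == r)
      ap[rows, ] <- rotate_about_axis(ap[rows, , drop = FALSE], fr$T, ang, fr$O)
    }
  } else {                               # bend
    p <- record$parameters
    pivot <- if (!is.null(p$pivot)) as.numeric(p$pivot) else
      stent$ring_centers[sel[1], ]
    ang <- p$angle_deg * pi / 180
    for (r in sel) {
      fr <- stent$rings[[r]]
      stent$rings[[r]]$curve <- rotate_about_axis(fr$curve, p$axis, ang, pivot)
      stent$rings[[r]]$O <-
        as.vector(rotate_about_axis(fr$O, p$axis, ang, pivot))
      for (f in c("U", "V", "T"))
        stent$rings[[r]][[f]] <-
          as.vector(rotate_about_axis(fr[[f]], p$axis, ang, c(0, 0, 0)))
      stent$ring_centers[r, ] <- stent$rings[[r]]$O
      rows <- which(gt_rows & stent$ground_truth$ring_index == r)
      ap[rows, ] <- rotate_about_axis(ap[rows, , drop = FALSE], p$axis, ang,
                                      pivot)
    }
  }
  stent$ground_truth$x_mm <- ap[, 1]
  stent$ground_truth$y_mm <- ap[, 2]
  stent$ground_truth$z_mm <- ap[, 3]
  stent$transforms <- c(stent$transforms, list(record))
  stent
}

#' Ground-truth apices as an observation point set
#'
#' Converts a phantom's analytic apex table into the same point-set structure
#' the landmark extractor emits, for direct comparison.
#'
#' @param stent a [generate_stent()] result.
#' @param orientation `"proximal"`, `"distal"` or `"both"`.
#' @param timepoint label for the set.
#' @param case_id case identifier.
#' @return an `observation_point_set`.
#' @export
ground_truth_points <- function(stent, orientation = "proximal",
                                timepoint = "T1", case_id = "phantom") {
  gt <- stent$ground_truth
  if (orientation != "both") gt <- gt[gt$orientation == orientation, ]
  peaks <- data.frame(
    ring_index = gt$ring_index, peak_index = gt$apex_index,
    orientation = gt$orientation,
    x_mm = gt$x_mm, y_mm = gt$y_mm, z_mm = gt$z_mm,
    angular_deg = NA_real_, axial_mm = NA_real_, source = "manual")
  observation_point_set(peaks, case_id = case_id, timepoint = timepoint,
                        origin_landmark = c(0, 0, 0))
}
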