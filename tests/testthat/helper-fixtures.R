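# Shared fixtures (built in code, memoized: voxelization is the slow step)
# and independent brute-force oracles used to freeze expected values.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small 3-ring, 5-apex phantom: fast to voxelize, rings well separated
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_rings = 3, apices_per_ring = 5, ring_radius = 10,
         apex_amplitude = 5, ring_spacing = 16, wire_radius = 0.8,
         grid_spacing = 1),
    list(...))
  do.call(phantom_spec, args)
}

small_stent <- function() cached("small_stent", generate_stent(small_spec()))
small_mask <- function() cached("small_mask", voxelize(small_stent()))
small_peaks <- function() {
  cached("small_peaks", extract_peaks(small_mask(), timepoint = "T1"))
}

# clinically sized phantom (thoracic dimensions) with a chosen ring count
sized_spec <- function(n_rings = 3, apices_per_ring = 5, ...) {
  phantom_spec(n_rings = n_rings, apices_per_ring = apices_per_ring,
               ring_radius = 15, apex_amplitude = 7.5, ring_spacing = 22,
               wire_radius = 0.8, grid_spacing = 1, ...)
}

# --- independent oracles -----------------------------------------------------

# all-pairs scan for the characteristic diameter (naive double loop)
oracle_max_pairwise <- function(pts) {
  pts <- rbind(pts)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    for (j in (i + 1):nrow(pts)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# covariance-formula R^2 (independent of stats::cor)
oracle_r_squared <- function(a, b) {
  n <- length(a)
  sxy <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
  sxx <- sum((a - mean(a))^2) / (n - 1)
  syy <- sum((b - mean(b))^2) / (n - 1)
  sxy^2 / (sxx * syy)
}

# brute-force projected-angle deflection: project both peak vectors into the
# plane perpendicular to nvec and measure the signed in-plane angle
oracle_projected_angle_deg <- function(p1, p2, center1, center2, nvec) {
  nvec <- nvec / sqrt(sum(nvec^2))
  a <- sweep(rbind(p1), 2, center1, `-`)
  b <- sweep(rbind(p2), 2, center2, `-`)
  proj <- function(m) m - outer(as.vector(m %*% nvec), nvec)
  a <- proj(a); b <- proj(b)
  ang <- vapply(seq_len(nrow(a)), function(j) {
    u <- a[j, ]; v <- b[j, ]
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    atan2(sum(cr * nvec), sum(u * v))
  }, numeric(1))
  mean(ang) * 180 / pi
}

# regular polygon in the z = z0 plane, one vertex at angle phase
regular_polygon <- function(n, radius, z0 = 0, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(th), radius * sin(th), z0)
}

rotate_z <- function(pts, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rbind(pts) %*% t(R)
}

# tiny peak data.frame for cluster tests
cand_df <- function(xyz, ring = 1L, orientation = "proximal") {
  xyz <- rbind(xyz)
  data.frame(ring_index = ring, peak_index = seq_len(nrow(xyz)),
             orientation = orientation,
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             angular_deg = (atan2(xyz[, 2], xyz[, 1]) %% (2 * pi)) * 180 / pi,
             axial_mm = xyz[, 3], source = "auto")
}

expect_vec_equal <- function(got, want, tol = 1e-9) {
  expect_lt(max(abs(got - want)), tol)
}
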