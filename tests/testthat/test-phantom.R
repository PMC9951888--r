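test_that("phantom spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(apices_per_ring = 2), "degenerate")
  expect_error(phantom_spec(n_rings = 0), "n_rings")
  expect_error(phantom_spec(ring_radius = -1), "positive")
  expect_error(phantom_spec(wire_radius = 0), "positive")
  expect_error(phantom_spec(stent_hu = 900), "1200")
  expect_error(phantom_spec(vessel_hu = 1000), "vessel_hu")
})

test_that("generate_stent produces 2*N_p analytic apices per ring", {
  st <- small_stent()
  gt <- st$ground_truth
  for (r in 1:3) {
    expect_equal(sum(gt$ring_index == r & gt$orientation == "proximal"), 5)
    expect_equal(sum(gt$ring_index == r & gt$orientation == "distal"), 5)
  }
  # apices are analytic: proximal apex of a single-ring stent at theta = 0
  st1 <- generate_stent(phantom_spec(n_rings = 1, apices_per_ring = 5,
                                     ring_radius = 10, apex_amplitude = 5))
  a1 <- st1$ground_truth[st1$ground_truth$orientation == "proximal" &
                           st1$ground_truth$apex_index == 1, ]
  expect_vec_equal(c(a1$x_mm, a1$y_mm, a1$z_mm), c(10, 0, 5))
  expect_vec_equal(st1$ring_centers[1, ], c(0, 0, 0))
})

test_that("mean of a ring's apices equals its center (triangle-wave symmetry)", {
  st <- small_stent()
  for (r in 1:3) {
    sub <- st$ground_truth[st$ground_truth$ring_index == r, ]
    expect_vec_equal(colMeans(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])),
                     st$ring_centers[r, ])
  }
  # ring 1 is most proximal (largest z on the straight centerline)
  expect_true(st$ring_centers[1, 3] > st$ring_centers[3, 3])
})

test_that("arc centerline spaces ring centers by ring_spacing along the arc", {
  st <- generate_stent(phantom_spec(n_rings = 4, centerline_kind = "arc",
                                    centerline_radius = 150))
  gaps <- sqrt(rowSums(diff(st$ring_centers)^2))
  # chord of a 22 mm arc on a 150 mm circle
  expect_vec_equal(gaps, rep(2 * 150 * sin(22 / 150 / 2), 3), tol = 1e-9)
})

test_that("voxelize covers every analytic apex and conserves volume", {
  st <- small_stent()
  mask <- small_mask()
  fg <- foreground_world(mask)
  ap <- as.matrix(st$ground_truth[, c("x_mm", "y_mm", "z_mm")])
  tol <- st$spec$wire_radius + sqrt(3) / 2 * st$spec$grid_spacing
  for (i in seq_len(nrow(ap))) {
    d <- sqrt(min(rowSums(sweep(fg, 2, ap[i, ], `-`)^2)))
    expect_lt(d, tol)
  }
  # doubling the voxel size cuts foreground count by ~8x
  mask2 <- voxelize(st, phantom_spec(n_rings = 3, apices_per_ring = 5,
                                     ring_radius = 10, apex_amplitude = 5,
                                     ring_spacing = 16, grid_spacing = 2))
  ratio <- sum(mask$values) / sum(mask2$values)
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
})

test_that("disjoint rings voxelize to exactly M 26-connected components", {
  cc <- label_components_26(small_mask())
  expect_equal(length(cc$sizes), 3L)
})

test_that("a wire thinner than the grid resolves to an explicit failure", {
  sp <- small_spec(wire_radius = 1e-6)
  expect_error(voxelize(generate_stent(sp), sp), "empty mask")
})

test_that("synthesize_ct assigns HU compartments and is seed-deterministic", {
  st <- small_stent()
  mask <- small_mask()
  sp <- small_spec(stent_hu = 1700, vessel_hu = 500)
  vessel <- cached("small_vessel", voxelize_vessel(st, mask))
  ct <- synthesize_ct(mask, vessel, sp)
  stent_vox <- ct$values[mask$values > 0]
  expect_true(all(stent_vox >= 1200 & stent_vox <= 2200))
  vessel_only <- vessel$values > 0 & mask$values == 0
  expect_true(all(ct$values[vessel_only] == 500))
  expect_true(all(ct$values[vessel$values == 0 & mask$values == 0] == 0))

  spn <- small_spec(noise_sd = 80, seed = 11)
  ct1 <- synthesize_ct(mask, vessel, spn)
  ct2 <- synthesize_ct(mask, vessel, spn)
  expect_identical(ct1$values, ct2$values)
  ct3 <- synthesize_ct(mask, vessel, small_spec(noise_sd = 80, seed = 12))
  expect_false(identical(ct1$values, ct3$values))
})

test_that("translate shifts ground truth exactly and composes additively", {
  st <- small_stent()
  v1 <- c(3, 0, 0); v2 <- c(-1, 2, 4)
  st_a <- apply_deformation(st, deformation("translate", v1))
  expect_vec_equal(as.matrix(st_a$ground_truth[, c("x_mm", "y_mm", "z_mm")]),
                   sweep(as.matrix(st$ground_truth[, c("x_mm", "y_mm", "z_mm")]),
                         2, v1, `+`))
  st_ab <- apply_deformation(st_a, deformation("translate", v2))
  st_sum <- apply_deformation(st, deformation("translate", v1 + v2))
  expect_vec_equal(as.matrix(st_ab$ground_truth[, c("x_mm", "y_mm", "z_mm")]),
                   as.matrix(st_sum$ground_truth[, c("x_mm", "y_mm", "z_mm")]))
  expect_length(st_ab$transforms, 2L)
})

test_that("radial_scale scales in-plane apex distances about the ring center", {
  st <- small_stent()
  s <- 1.2
  st2 <- apply_deformation(st, deformation("radial_scale", s, applies_to = 2))
  for (o in c("proximal", "distal")) {
    p0 <- st$ground_truth[st$ground_truth$ring_index == 2 &
                            st$ground_truth$orientation == o, ]
    p1 <- st2$ground_truth[st2$ground_truth$ring_index == 2 &
                             st2$ground_truth$orientation == o, ]
    d0 <- oracle_max_pairwise(as.matrix(p0[, c("x_mm", "y_mm", "z_mm")]))
    d1 <- oracle_max_pairwise(as.matrix(p1[, c("x_mm", "y_mm", "z_mm")]))
    expect_equal(d1, s * d0, tolerance = 1e-12)
  }
  # untouched rings unchanged
  other0 <- st$ground_truth[st$ground_truth$ring_index != 2, ]
  other1 <- st2$ground_truth[st2$ground_truth$ring_index != 2, ]
  expect_vec_equal(as.matrix(other0[, c("x_mm", "y_mm", "z_mm")]),
                   as.matrix(other1[, c("x_mm", "y_mm", "z_mm")]))
})

test_that("twist advances the angular coordinate, leaving axial unchanged", {
  st <- small_stent()
  st2 <- apply_deformation(st, deformation("twist", 10, applies_to = 1))
  g0 <- st$ground_truth[st$ground_truth$ring_index == 1, ]
  g1 <- st2$ground_truth[st2$ground_truth$ring_index == 1, ]
  O <- st$ring_centers[1, ]
  ang <- function(g) atan2(g$y_mm - O[2], g$x_mm - O[1])
  dtheta <- (ang(g1) - ang(g0)) %% (2 * pi)
  expect_vec_equal(dtheta, rep(10 * pi / 180, nrow(g0)))
  expect_vec_equal(g1$z_mm, g0$z_mm)
})

test_that("bend rotates selected rings rigidly about the pivot axis", {
  st <- small_stent()
  rec <- deformation("bend", list(axis = c(0, 1, 0), angle_deg = 15,
                                  pivot = c(0, 0, 0)))
  st2 <- apply_deformation(st, rec)
  p0 <- as.matrix(st$ground_truth[, c("x_mm", "y_mm", "z_mm")])
  p1 <- as.matrix(st2$ground_truth[, c("x_mm", "y_mm", "z_mm")])
  # rigid: all pairwise distances preserved
  expect_equal(as.vector(dist(p1)), as.vector(dist(p0)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(p0, p1)))
  # frames stay orthonormal with T = U x V ordering intact
  fr <- st2$rings[[2]]
  expect_vec_equal(c(sum(fr$U * fr$V), sum(fr$U * fr$T), sum(fr$V * fr$T)),
                   c(0, 0, 0))
})

test_that("deformation records validate their parameters", {
  expect_error(deformation("translate", c(1, 2)), "length-3")
  expect_error(deformation("radial_scale", -2), "positive")
  expect_error(deformation("twist", Inf), "finite")
  expect_error(deformation("bend", list(axis = c(0, 0, 0), angle_deg = 5)),
               "nonzero")
  st <- small_stent()
  expect_error(
    apply_deformation(st, deformation("translate", c(1, 0, 0),
                                      applies_to = 9)),
    "out of range")
})
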