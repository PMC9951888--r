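test_that("register_to_origin subtracts the skeletal landmark once", {
  pts <- observation_point_set(
    cand_df(rbind(c(12, 10, 10))), origin_landmark = c(10, 10, 10))
  reg <- register_to_origin(pts)
  expect_vec_equal(peak_coords(reg), rbind(c(2, 0, 0)))
  expect_vec_equal(reg$origin_landmark, c(0, 0, 0))
  expect_error(register_to_origin(reg), "already registered")
  # zero origin: identity on coordinates
  id <- register_to_origin(observation_point_set(cand_df(c(1, 2, 3))))
  expect_vec_equal(peak_coords(id), rbind(c(1, 2, 3)))
})

make_registered <- function(xyz_by_ring, timepoint = "T1") {
  peaks <- do.call(rbind, lapply(seq_along(xyz_by_ring), function(r) {
    cand_df(xyz_by_ring[[r]], ring = r)
  }))
  s <- observation_point_set(peaks, timepoint = timepoint)
  s$registered <- TRUE
  s
}

test_that("end_slip is the end-ring midpoint difference, antisymmetric", {
  a <- make_registered(list(regular_polygon(5, 10, z0 = 40) + 1,
                            regular_polygon(5, 10, z0 = 0)), "T1")
  b <- make_registered(list(sweep(regular_polygon(5, 10, z0 = 40) + 1,
                                  2, c(0, 0, 3), `+`),
                            regular_polygon(5, 10, z0 = 0)), "T2")
  sl <- end_slip(a, b, "proximal")
  expect_vec_equal(sl$delta, c(0, 0, -3))
  # identical sets -> zero slip
  expect_vec_equal(end_slip(a, a, "distal")$delta, c(0, 0, 0))
  # antisymmetry
  expect_vec_equal(end_slip(b, a, "proximal")$delta, -sl$delta)
  unreg <- observation_point_set(a$peaks)
  expect_error(end_slip(unreg, b), "registered")
})

test_that("characteristic diameter matches closed forms and the all-pairs oracle", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(characteristic_diameter(sq)$rho, sqrt(2), tolerance = 1e-12)
  expect_equal(characteristic_diameter(rbind(c(0, 0, 0), c(30, 0, 0)))$rho, 30)
  # regular pentagon, circumradius 15: rho = 2 * 15 * sin(2*pi/5)
  pent <- regular_polygon(5, 15)
  expect_equal(characteristic_diameter(pent)$rho, 2 * 15 * sin(2 * pi / 5),
               tolerance = 1e-12)
  expect_equal(characteristic_diameter(pent)$rho, oracle_max_pairwise(pent),
               tolerance = 1e-15)
  expect_error(characteristic_diameter(rbind(c(0, 0, 0))), ">= 2")
  set.seed(17)
  for (i in 1:20) {
    pts <- matrix(rnorm(3 * sample(3:12, 1), sd = 20), ncol = 3)
    expect_identical(characteristic_diameter(pts)$rho,
                     oracle_max_pairwise(pts))
  }
})

test_that("ring rate is the squared baseline ratio", {
  expect_equal(ring_rate(10, 10), 1)
  expect_equal(ring_rate(20, 10), 4)
  expect_error(ring_rate(5, 0), "> 0")
})

test_that("deflection of a planar ring rotated about its normal is exact", {
  pent1 <- regular_polygon(5, 15, z0 = 10, phase = 0.3)
  pent2 <- rotate_z(pent1 - rep(c(0, 0, 10), each = 5), 10) +
    rep(c(0, 0, 10), each = 5)
  O_k <- c(0, 0, 10); O_k1 <- c(0, 0, -12)      # normal along +z
  dr <- deflection_angle(pent1, pent2, O_k, O_k1)
  expect_equal(dr$beta, 10, tolerance = 1e-6)
  expect_vec_equal(dr$alphas, rep(10, 5), tol = 1e-6)
  # brute-force projected-angle oracle agrees on the planar case
  expect_equal(
    oracle_projected_angle_deg(pent1, pent2, point_mid(pent1),
                               point_mid(pent2), O_k - O_k1),
    10, tolerance = 1e-9)
  # reversed normal flips the sign
  expect_equal(deflection_angle(pent1, pent2, O_k1, O_k)$beta, -10,
               tolerance = 1e-6)
  # identical periods -> zero
  expect_equal(deflection_angle(pent1, pent1, O_k, O_k1)$beta, 0)
})

test_that("deflection validates input geometry", {
  pent <- regular_polygon(5, 15)
  expect_error(deflection_angle(pent, pent[1:4, ], c(0, 0, 1), c(0, 0, 0)),
               "equal peak counts")
  expect_error(deflection_angle(pent, pent, c(0, 0, 1), c(0, 0, 1)),
               "coincident")
  # all T1 peaks coincide with their own midpoint: OP_j has zero length
  same <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_error(deflection_angle(same, pent[1:3, ], c(0, 0, 1), c(0, 0, 0)),
               "midpoint")
})

test_that("deflection is equivariant under a common rotation", {
  set.seed(31)
  pent1 <- regular_polygon(6, 12, phase = 0.1)
  pent2 <- rotate_z(pent1, 7)
  base <- deflection_angle(pent1, pent2, c(0, 0, 5), c(0, 0, -5))$beta
  # rotate everything (both periods and the normal) by a random rotation
  ax <- c(1, 2, 3) / sqrt(14)
  rot <- function(m) rotate_about_axis(m, ax, 0.8, c(0, 0, 0))
  rotated <- deflection_angle(rot(pent1), rot(pent2),
                              as.vector(rot(c(0, 0, 5))),
                              as.vector(rot(c(0, 0, -5))))$beta
  expect_equal(rotated, base, tolerance = 1e-9)
})

test_that("arcsin clamping absorbs float excess but rejects real violations", {
  # a 90 degree in-plane rotation drives the arcsin argument to 1 (+ float eps)
  pent <- regular_polygon(5, 15, phase = 0.123)
  dr <- deflection_angle(pent, rotate_z(pent, 90), c(0, 0, 1), c(0, 0, 0),
                         match_peaks = FALSE)
  expect_equal(dr$beta, 90, tolerance = 1e-9)
  expect_true(all(abs(dr$alphas) <= 90))
})

test_that("method agreement matches the covariance-formula oracle", {
  set.seed(12)
  a <- rnorm(100); b <- 0.8 * a + rnorm(100, sd = 0.4)
  ma <- method_agreement(a, b)
  expect_equal(ma$r_squared, oracle_r_squared(a, b), tolerance = 1e-12)
  expect_equal(ma$mean_difference, mean(a - b), tolerance = 1e-12)
  expect_equal(ma$sd_difference, stats::sd(a - b), tolerance = 1e-12)

  same <- method_agreement(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)
  expect_equal(same$r_squared, 1)

  shifted <- method_agreement(a + 1, a)
  expect_equal(shifted$mean_difference, 1, tolerance = 1e-12)
  expect_equal(shifted$sd_difference, 0)
  expect_equal(shifted$r_squared, 1, tolerance = 1e-12)

  # degenerate: constant series, unequal -> flagged NA, not 0
  degen <- method_agreement(rep(2, 5), rep(3, 5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$r_squared))
  expect_error(method_agreement(1:3, 1:4), "equal length")
})

test_that("rho, ring rate and beta are translation-invariant; slip is not", {
  set.seed(44)
  r1 <- list(regular_polygon(5, 14, z0 = 30, phase = 0.2),
             regular_polygon(5, 15, z0 = 0))
  r2 <- list(rotate_z(regular_polygon(5, 13, z0 = 31, phase = 0.2), 6),
             regular_polygon(5, 15.5, z0 = -1))
  v <- c(8, -3, 12)
  s1 <- make_registered(r1, "T1"); s2 <- make_registered(r2, "T2")
  s1t <- make_registered(lapply(r1, function(m) sweep(m, 2, v, `+`)), "T1")
  s2t <- make_registered(lapply(r2, function(m) sweep(m, 2, v, `+`)), "T2")
  rep0 <- measure_series(list(s1, s2))
  rept <- measure_series(list(s1t, s2t))
  expect_vec_equal(rept$diameter$rho_mm, rep0$diameter$rho_mm, tol = 1e-9)
  expect_vec_equal(rept$diameter$ring_rate, rep0$diameter$ring_rate,
                   tol = 1e-12)
  expect_vec_equal(rept$deflection$beta, rep0$deflection$beta, tol = 1e-8)
  # slip moves only when the origin does not co-translate
  expect_vec_equal(
    unlist(rept$slip[1, c("dx_mm", "dy_mm", "dz_mm")]),
    unlist(rep0$slip[1, c("dx_mm", "dy_mm", "dz_mm")]), tol = 1e-9)
})

test_that("measure_series reports identity for an unchanged stent", {
  rings <- list(regular_polygon(5, 14, z0 = 30), regular_polygon(5, 15, z0 = 0))
  s1 <- make_registered(rings, "T1"); s2 <- make_registered(rings, "T2")
  rep_ <- measure_series(list(s1, s2))
  expect_true(all(abs(as.matrix(rep_$slip[, c("dx_mm", "dy_mm", "dz_mm")]))
                  < 1e-12))
  expect_true(all(abs(rep_$diameter$ring_rate - 1) < 1e-12))
  expect_true(all(abs(rep_$deflection$beta) < 1e-9))
})

test_that("translation-only follow-up leaves shape parameters unchanged", {
  rings <- list(regular_polygon(5, 14, z0 = 30, phase = 0.4),
                regular_polygon(5, 15, z0 = 0))
  v <- c(4, -1, 2)
  s1 <- make_registered(rings, "T1")
  s2 <- make_registered(lapply(rings, function(m) sweep(m, 2, v, `+`)), "T2")
  rep_ <- measure_series(list(s1, s2))
  expect_true(all(abs(rep_$diameter$ring_rate - 1) < 1e-12))
  expect_true(all(abs(rep_$deflection$beta) < 1e-8))
  expect_vec_equal(unlist(rep_$slip[rep_$slip$end == "proximal",
                                    c("dx_mm", "dy_mm", "dz_mm")][1, ]), -v)
})

test_that("a 4-timepoint series enumerates 3 consecutive + first-last pairs", {
  rings <- list(regular_polygon(5, 14, z0 = 30), regular_polygon(5, 15, z0 = 0))
  sets <- lapply(1:4, function(i) make_registered(rings, paste0("T", i)))
  rep_ <- measure_series(sets)
  pair_ids <- unique(paste(rep_$slip$period_i, rep_$slip$period_j))
  expect_setequal(pair_ids, c("T1 T2", "T2 T3", "T3 T4", "T1 T4"))
  expect_equal(nrow(rep_$slip), 4 * 2)          # 4 pairs x 2 ends
  expect_equal(nrow(rep_$deflection), 4 * 2)    # 4 pairs x 2 rings
  expect_error(measure_series(sets[1]), ">= 2")
})

test_that("mismatched ring counts restrict to common indices with a warning", {
  s1 <- make_registered(list(regular_polygon(5, 14, z0 = 30),
                             regular_polygon(5, 15, z0 = 0)), "T1")
  s2 <- make_registered(list(regular_polygon(5, 14, z0 = 30)), "T2")
  expect_warning(rep_ <- measure_series(list(s1, s2)), "common indices")
  expect_equal(unique(rep_$diameter$ring_index), 1L)
})
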