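# Morphological parameters of stent-graft follow-up:
#   end-slip vector      Delta = P_O(i) - P_O(j), P_O the end-ring midpoint
#   characteristic rho   rho = max_{i<j} |P_i P_j|;  ring rate R_k = (rho_k/rho_1)^2
#   deflection angle     alpha_j = arcsin(((OP_j x OP_j') / (|OP_j||OP_j'|)) . n),
#                        n along O_{k+1} -> O_k;  beta = mean(alpha_j)

#' Register a point set to its skeletal origin landmark
#'
#' Translates every coordinate by minus the origin landmark so that all
#' timepoints of a case share one coordinate frame (pure translation; a
#' single skeletal point fixes three degrees of freedom, rotation is not
#' corrected).
#'
#' @param pts an [observation_point_set()].
#' @return the registered set (origin becomes (0,0,0), `registered = TRUE`).
#' @export
register_to_origin <- function(pts) {
  stopifnot(inherits(pts, "observation_point_set"))
  if (pts$registered) stop("point set is already registered")
  o <- pts$origin_landmark
  pts$peaks$x_mm <- pts$peaks$x_mm - o[1]
  pts$peaks$y_mm <- pts$peaks$y_mm - o[2]
  pts$peaks$z_mm <- pts$peaks$z_mm - o[3]
  pts$origin_landmark <- c(0, 0, 0)
  pts$registered <- TRUE
  pts
}

end_ring_index <- function(set, end = c("proximal", "distal")) {
  end <- match.arg(end)
  rings <- sort(unique(set$peaks$ring_index))
  if (end == "proximal") rings[1] else rings[length(rings)]
}

#' End-slip vector between two follow-up periods
#'
#' The componentwise displacement of the end ring's midpoint between periods
#' i and j: `Delta = P_O(i) - P_O(j)` (earlier minus later when i precedes
#' j). Both sets must be origin-registered. Antisymmetric under period swap.
#'
#' @param set_i,set_j registered [observation_point_set()]s for periods i, j.
#' @param end `"proximal"` or `"distal"` stent end.
#' @return `slip_vector` list: `delta` (mm), `period_pair`, `end`.
#' @export
end_slip <- function(set_i, set_j, end = c("proximal", "distal")) {
  end <- match.arg(end)
  for (s in list(set_i, set_j))
    if (!s$registered)
      stop("end_slip needs origin-registered point sets (see register_to_origin)")
  ri <- end_ring_index(set_i, end); rj <- end_ring_index(set_j, end)
  pi_ <- peak_coords(set_i, ring = ri)
  pj_ <- peak_coords(set_j, ring = rj)
  if (nrow(pi_) == 0L || nrow(pj_) == 0L)
    stop("missing ", end, " end ring in one of the point sets")
  structure(list(delta = point_mid(pi_) - point_mid(pj_),
                 period_pair = c(set_i$timepoint, set_j$timepoint),
                 end = end), class = "slip_vector")
}

#' @export
print.slip_vector <- function(x, ...) {
  cat(sprintf("<slip_vector> %s end, %s vs %s: (%.3f, %.3f, %.3f) mm\n",
              x$end, x$period_pair[1], x$period_pair[2],
              x$delta[1], x$delta[2], x$delta[3]))
  invisible(x)
}

#' Characteristic diameter of a support ring
#'
#' Support rings in vivo are rarely regular polygons, so the ring's size is
#' summarized by its characteristic length: the maximum Euclidean distance
#' over all unordered peak pairs. Ties are broken toward the lowest peak
#' index pair (the length itself is tie-invariant).
#'
#' @param peaks numeric matrix (n x 3) of one ring's peak coordinates, n >= 2.
#' @return `ring_diameter` list: `rho` (mm), `argmax_pair` (row indices).
#' @export
characteristic_diameter <- function(peaks) {
  peaks <- rbind(peaks)
  n <- nrow(peaks)
  if (n < 2L) stop("characteristic diameter needs >= 2 peaks")
  best <- -Inf; pair <- c(NA_integer_, NA_integer_)
  for (i in 1:(n - 1)) {
    d2 <- rowSums(sweep(peaks[(i + 1):n, , drop = FALSE], 2,
                        peaks[i, ], `-`)^2)
    j <- which.max(d2)
    if (d2[j] > best) {
      best <- d2[j]
      pair <- c(i, i + j)
    }
  }
  structure(list(rho = sqrt(best), argmax_pair = pair),
            class = "ring_diameter")
}

#' Ring rate: squared characteristic-length ratio versus baseline
#'
#' `R_k = (rho_k / rho_1)^2`, the relative radial deformation of a ring in
#' period k against the first period (`R_1 = 1` by definition).
#'
#' @param rho_k characteristic length in period k, mm.
#' @param rho_1 baseline characteristic length, mm (> 0).
#' @return numeric ring rate.
#' @export
ring_rate <- function(rho_k, rho_1) {
  if (any(!is.finite(rho_1)) || any(rho_1 <= 0))
    stop("baseline characteristic length must be > 0")
  (rho_k / rho_1)^2
}

#' Ring deflection angle between two periods
#'
#' Both periods' peaks are recentered so their ring midpoints coincide at O.
#' For each matched peak pair (P_j, P_j'), the deflection is
#' `alpha_j = arcsin(((OP_j x OP_j') / (|OP_j||OP_j'|)) . n)` with `n` the
#' unit vector along O_{k+1} -> O_k (the approximation to the ring-plane
#' normal; it points proximal). `beta` is the mean of the `alpha_j`. Peaks
#' are matched by rank of their angular coordinate in the baseline ring's
#' plane frame, which is exact for twists smaller than half the inter-peak
#' angle.
#'
#' @param peaks_t1,peaks_t2 numeric matrices (N x 3) of the ring's peaks in
#'   the two periods, N equal.
#' @param O_k,O_k1 ring midpoints of rings k and k+1 (baseline period) used
#'   for the plane normal.
#' @param degrees report angles in degrees (default) or radians.
#' @param match_peaks match rows by angular rank (default) or take rows as
#'   already corresponding (`FALSE`).
#' @return `deflection_result` list: `alphas`, `beta`, `normal_used`.
#' @export
deflection_angle <- function(peaks_t1, peaks_t2, O_k, O_k1, degrees = TRUE,
                             match_peaks = TRUE) {
  peaks_t1 <- rbind(peaks_t1); peaks_t2 <- rbind(peaks_t2)
  if (nrow(peaks_t1) != nrow(peaks_t2))
    stop("deflection needs equal peak counts in both periods")
  if (nrow(peaks_t1) < 1L) stop("deflection needs at least one peak")
  nvec <- O_k - O_k1
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-9) stop("coincident ring midpoints O_k and O_{k+1}")
  nvec <- nvec / nn

  c1 <- point_mid(peaks_t1); c2 <- point_mid(peaks_t2)
  a <- sweep(peaks_t1, 2, c1, `-`)
  b <- sweep(peaks_t2, 2, c2, `-`)
  if (match_peaks) {
    fr <- plane_frame(nvec)
    ang_of <- function(m) atan2(m %*% fr$V, m %*% fr$U) %% (2 * pi)
    a <- a[order(ang_of(a)), , drop = FALSE]
    b <- b[order(ang_of(b)), , drop = FALSE]
  }
  na_ <- sqrt(rowSums(a^2)); nb_ <- sqrt(rowSums(b^2))
  if (any(na_ < 1e-9) || any(nb_ < 1e-9))
    stop("a peak coincides with the ring midpoint; deflection undefined")
  au <- a / na_; bu <- b / nb_
  cr <- cbind(au[, 2] * bu[, 3] - au[, 3] * bu[, 2],
              au[, 3] * bu[, 1] - au[, 1] * bu[, 3],
              au[, 1] * bu[, 2] - au[, 2] * bu[, 1])
  arg <- as.vector(cr %*% nvec)
  over <- abs(arg) - 1
  if (any(over > 1e-9))
    stop("arcsin argument exceeds 1 beyond tolerance (", max(over), ")")
  arg <- pmin(pmax(arg, -1), 1)
  alphas <- asin(arg)
  if (degrees) alphas <- alphas * 180 / pi
  structure(list(alphas = alphas, beta = mean(alphas), normal_used = nvec,
                 degrees = degrees), class = "deflection_result")
}

#' @export
print.deflection_result <- function(x, ...) {
  cat(sprintf("<deflection_result> beta = %.4f%s over %d peaks\n",
              x$beta, if (x$degrees) " deg" else " rad", length(x$alphas)))
  invisible(x)
}

#' Agreement statistics between two measurement methods
#'
#' For paired series a (method 1) and b (method 2): mean and sample SD
#' (n - 1) of the differences a - b, and the squared Pearson correlation.
#' When either series has zero variance R^2 is undefined; identical series
#' are reported as perfect agreement (`r_squared = 1`, `degenerate = TRUE`),
#' other zero-variance cases as `NA` with the degenerate flag set.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2).
#' @return `method_agreement` list: `n_pairs`, `mean_difference`,
#'   `sd_difference`, `r_squared`, `degenerate`, `relative_error` (the
#'   mean(|a-b|)/mean(|a|) convention).
#' @export
method_agreement <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired series must have equal length")
  n <- length(values_a)
  if (n < 2L) stop("method agreement needs >= 2 pairs")
  d <- values_a - values_b
  degenerate <- stats::var(values_a) == 0 || stats::var(values_b) == 0
  r2 <- if (!degenerate) {
    stats::cor(values_a, values_b)^2
  } else if (all(d == 0)) 1 else NA_real_
  structure(list(
    n_pairs = n, mean_difference = mean(d),
    sd_difference = stats::sd(d), r_squared = r2,
    degenerate = degenerate,
    relative_error = if (mean(abs(values_a)) > 0)
      mean(abs(d)) / mean(abs(values_a)) else NA_real_),
    class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  cat(sprintf("<method_agreement> n = %d, diff mean %.4f, diff SD %.4f, R^2 %.4f%s\n",
              x$n_pairs, x$mean_difference, x$sd_difference, x$r_squared,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# ring midpoints (point_mid of peaks) by ring index for one set
ring_midpoints <- function(set) {
  rings <- sort(unique(set$peaks$ring_index))
  mids <- t(vapply(rings, function(r) point_mid(peak_coords(set, ring = r)),
                   numeric(3)))
  list(rings = rings, mids = mids)
}

# Eq.-4 plane normal for ring k from baseline ring midpoints: along
# O_{k+1} -> O_k; for the most distal ring the O_{M-1} -> O_M direction is
# negated and reused, so the normal always points proximal.
deflection_normal <- function(mids, k_pos) {
  M <- nrow(mids)
  if (M < 2L) stop("deflection normal needs >= 2 rings")
  if (k_pos < M) mids[k_pos, ] - mids[k_pos + 1L, ]
  else mids[k_pos - 1L, ] - mids[k_pos, ]
}

#' Measure the full follow-up parameter report for a series
#'
#' For every consecutive period pair and the first-versus-last pair, computes
#' proximal and distal end-slip vectors, per-ring characteristic lengths and
#' ring rates (baseline = first period), and per-ring deflection angles.
#' Rings are corresponded across timepoints by `ring_index`; indices absent
#' from some timepoint are skipped with a warning.
#'
#' @param series list of registered [observation_point_set()]s in timepoint
#'   order (>= 2).
#' @param degrees report deflection angles in degrees (default).
#' @return `followup_report` list of data.frames: `slip`, `diameter`
#'   (rho and ring rate per ring/timepoint), `deflection`.
#' @export
measure_series <- function(series, degrees = TRUE) {
  if (length(series) < 2L) stop("a follow-up series needs >= 2 timepoints")
  for (s in series) {
    stopifnot(inherits(s, "observation_point_set"))
    if (!s$registered) stop("all timepoints must be origin-registered")
  }
  labels <- vapply(series, `[[`, character(1), "timepoint")
  ring_sets <- lapply(series, function(s) sort(unique(s$peaks$ring_index)))
  common <- Reduce(intersect, ring_sets)
  if (length(common) == 0L) stop("no ring index common to all timepoints")
  if (any(vapply(ring_sets, length, integer(1)) != length(common)))
    warning("ring count differs across timepoints; restricting to common indices")

  n_t <- length(series)
  pairs <- lapply(seq_len(n_t - 1L), function(i) c(i, i + 1L))
  if (n_t > 2L) pairs <- c(pairs, list(c(1L, n_t)))

  slip <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("proximal", "distal"), function(e) {
      sv <- end_slip(series[[pr[1]]], series[[pr[2]]], end = e)
      data.frame(period_i = labels[pr[1]], period_j = labels[pr[2]], end = e,
                 dx_mm = sv$delta[1], dy_mm = sv$delta[2], dz_mm = sv$delta[3])
    }))
  }))

  diam <- do.call(rbind, lapply(seq_len(n_t), function(ti) {
    do.call(rbind, lapply(common, function(r) {
      rho <- characteristic_diameter(peak_coords(series[[ti]], ring = r))$rho
      data.frame(timepoint = labels[ti], ring_index = r, rho_mm = rho)
    }))
  }))
  base <- diam[diam$timepoint == labels[1], ]
  diam$ring_rate <- ring_rate(
    diam$rho_mm, base$rho_mm[match(diam$ring_index, base$ring_index)])

  defl <- do.call(rbind, lapply(pairs, function(pr) {
    rm1 <- ring_midpoints(series[[pr[1]]])
    keep <- rm1$rings %in% common
    mids <- rm1$mids[keep, , drop = FALSE]
    rings <- rm1$rings[keep]
    do.call(rbind, lapply(seq_along(rings), function(kp) {
      r <- rings[kp]
      p1 <- peak_coords(series[[pr[1]]], ring = r)
      p2 <- peak_coords(series[[pr[2]]], ring = r)
      if (nrow(p1) != nrow(p2)) {
        warning("ring ", r, ": unequal peak counts between ", labels[pr[1]],
                " and ", labels[pr[2]], "; skipped")
        return(NULL)
      }
      if (length(rings) < 2L) return(NULL)
      nvec <- deflection_normal(mids, kp)
      dr <- deflection_angle(p1, p2, O_k = nvec, O_k1 = c(0, 0, 0),
                             degrees = degrees)
      data.frame(period_i = labels[pr[1]], period_j = labels[pr[2]],
                 ring_index = r, beta = dr$beta)
    }))
  }))
  structure(list(slip = slip, diameter = diam, deflection = defl,
                 timepoints = labels, angle_units = if (degrees) "degrees"
                 else "radians"),
            class = "followup_report")
}

#' @export
print.followup_report <- function(x, ...) {
  cat(sprintf("<followup_report> timepoints: %s\n",
              paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  %d slip rows, %d diameter rows, %d deflection rows (%s)\n",
              nrow(x$slip), nrow(x$diameter),
              if (is.null(x$deflection)) 0L else nrow(x$deflection),
              x$angle_units))
  invisible(x)
}
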