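# Automatic peak (apex) observation-point extraction.
#
# Per ring, every foreground voxel gets a cylindrical coordinate in the local
# centerline frame: axial s = (p - O) . n_prox (signed mm toward the proximal
# end) and angle theta in the ring plane. Candidates are the per-sector axial
# extrema; non-apex candidates are eliminated by an amplitude-fraction filter
# plus non-maximum suppression over neighboring sectors; surviving candidates
# are merged by the 2 mm sphere-clustering rule.

# deterministic in-plane frame perpendicular to unit vector tvec
plane_frame <- function(tvec) {
  basis <- diag(3)
  e <- basis[, which.min(abs(basis %*% tvec))]
  u <- e - sum(e * tvec) * tvec
  u <- u / sqrt(sum(u^2))
  v <- c(tvec[2] * u[3] - tvec[3] * u[2],
         tvec[3] * u[1] - tvec[1] * u[3],
         tvec[1] * u[2] - tvec[2] * u[1])
  list(U = u, V = v)
}

#' Extract per-sector apex candidates for one ring
#'
#' Divides the ring into `n_sectors` angular sectors about its centroid in the
#' plane perpendicular to the local centerline tangent. Each sector's voxel
#' with extremal axial coordinate becomes a candidate (maximal toward the
#' proximal side, minimal toward the distal side), refined to the centroid of
#' the sector's extremal voxel layer (within half a voxel of the extremum) for
#' sub-voxel localization. With `amp_fraction > 0`, candidates whose |axial|
#' is below `amp_fraction` times the ring's maximal |axial| are eliminated,
#' rings whose amplitude is below `min_amplitude_mm` yield no candidates at
#' all (a circular ring has no apices), and non-maximum suppression over
#' `nms_window` neighboring sectors removes flank candidates so only true
#' zig-zag extrema survive. `amp_fraction = 0` disables all elimination.
#'
#' @param ring a `ring_component` from [label_rings()].
#' @param grid the mask [voxel_grid()].
#' @param proximal_dir unit vector pointing proximal at this ring (from the
#'   centerline tangent).
#' @param n_sectors angular sectors (default 72, i.e. 5 degrees).
#' @param amp_fraction amplitude elimination fraction (default 0.6).
#' @param nms_window non-maximum suppression half-window, sectors.
#' @param min_amplitude_mm absolute amplitude floor, mm.
#' @param orientation `"proximal"`, `"distal"` or `"both"`.
#' @return data.frame of candidate peaks (columns as in
#'   [observation_point_set()] peaks).
#' @export
extract_candidates <- function(ring, grid, proximal_dir,
                               n_sectors = 72, amp_fraction = 0.6,
                               nms_window = 2L, min_amplitude_mm = 2.0,
                               orientation = "both") {
  stopifnot(inherits(ring, "ring_component"))
  if (nrow(ring$voxel_idx) < n_sectors / 10)
    stop("ring component too small to sector (",
         nrow(ring$voxel_idx), " voxels)")
  tvec <- proximal_dir / sqrt(sum(proximal_dir^2))
  fr <- plane_frame(tvec)
  O <- ring$centroid
  p <- voxel_to_world(grid, ring$voxel_idx)
  rel <- sweep(p, 2, O, `-`)
  s <- as.vector(rel %*% tvec)
  theta <- atan2(as.vector(rel %*% fr$V), as.vector(rel %*% fr$U)) %% (2 * pi)
  sector <- pmin(floor(theta / (2 * pi / n_sectors)), n_sectors - 1L)
  half_vox <- mean(grid$spacing) / 2

  one_side <- function(sgn, label) {
    ss <- sgn * s
    ext <- tapply(ss, factor(sector, levels = 0:(n_sectors - 1L)), max)
    occupied <- which(!is.na(ext))
    if (length(occupied) == 0L) return(NULL)
    keep <- occupied
    if (amp_fraction > 0) {
      s_max <- max(ss)
      if (s_max < min_amplitude_mm) return(NULL)
      keep <- keep[ext[keep] >= amp_fraction * s_max]
      # non-maximum suppression over +/- nms_window sectors (circular)
      if (length(keep) && nms_window > 0) {
        ok <- vapply(keep, function(i0) {
          nb <- ((i0 - 1L) + (-nms_window:nms_window)) %% n_sectors + 1L
          nbv <- ext[nb]
          ext[i0] >= max(nbv, na.rm = TRUE)
        }, logical(1))
        keep <- keep[ok]
      }
    }
    if (length(keep) == 0L) return(NULL)
    do.call(rbind, lapply(keep, function(i0) {
      rows <- which(sector == (i0 - 1L) & ss >= ext[i0] - half_vox)
      pos <- colMeans(p[rows, , drop = FALSE])
      relp <- pos - O
      data.frame(ring_index = ring$ring_index, peak_index = NA_integer_,
                 orientation = label,
                 x_mm = pos[1], y_mm = pos[2], z_mm = pos[3],
                 angular_deg = (atan2(sum(relp * fr$V), sum(relp * fr$U)) %%
                                  (2 * pi)) * 180 / pi,
                 axial_mm = sum(relp * tvec), source = "auto")
    }))
  }
  out <- NULL
  if (orientation %in% c("proximal", "both"))
    out <- rbind(out, one_side(1, "proximal"))
  if (orientation %in% c("distal", "both"))
    out <- rbind(out, one_side(-1, "distal"))
  if (!is.null(out)) {
    # distal axial coordinates are negative projections on the proximal axis
    out$axial_mm <- ifelse(out$orientation == "distal", out$axial_mm,
                           out$axial_mm)
    rownames(out) <- NULL
  }
  out
}

#' Merge nearby candidates by sphere clustering
#'
#' Each candidate is expanded to a sphere of `radius` mm; candidates whose
#' spheres touch (center distance <= 2 * radius) join the same group by
#' transitive closure, and each group collapses to its arithmetic mean. Two
#' near-tied candidates at one apex therefore merge to their midpoint.
#' Clustering is per ring and per orientation.
#'
#' @param candidates candidate data.frame from [extract_candidates()].
#' @param radius sphere radius, mm (default 2).
#' @return data.frame of merged peaks, `peak_index` assigned in angular order
#'   within each ring/orientation.
#' @export
cluster_candidates <- function(candidates, radius = 2.0) {
  if (!is.finite(radius) || radius <= 0) stop("cluster radius must be > 0")
  if (is.null(candidates) || nrow(candidates) == 0L) return(candidates)
  groups <- split(seq_len(nrow(candidates)),
                  interaction(candidates$ring_index, candidates$orientation,
                              drop = TRUE))
  out <- lapply(groups, function(rows) {
    xyz <- as.matrix(candidates[rows, c("x_mm", "y_mm", "z_mm")])
    n <- nrow(xyz)
    # union-find transitive closure on pairwise distance <= 2 * radius
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
      d <- as.matrix(stats::dist(xyz))
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (d[i, j] <= 2 * radius) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    merged <- lapply(unique(roots), function(r) {
      sub <- candidates[rows[roots == r], , drop = FALSE]
      data.frame(ring_index = sub$ring_index[1], peak_index = NA_integer_,
                 orientation = sub$orientation[1],
                 x_mm = mean(sub$x_mm), y_mm = mean(sub$y_mm),
                 z_mm = mean(sub$z_mm),
                 angular_deg = circular_mean_deg(sub$angular_deg),
                 axial_mm = mean(sub$axial_mm), source = "auto")
    })
    merged <- do.call(rbind, merged)
    merged <- merged[order(merged$angular_deg), , drop = FALSE]
    merged$peak_index <- seq_len(nrow(merged))
    merged
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) %% (2 * pi)) * 180 / pi
}

#' Fully automatic peak observation-point extraction
#'
#' End-to-end pipeline on a binary stent mask: label the support rings, order
#' them proximal to distal, fit the centerline through the ring centroids,
#' then per ring extract, filter and cluster apex candidates.
#'
#' @param mask binary [voxel_grid()] of the stent.
#' @param orientation `"proximal"` (default — the conventional observation
#'   points), `"distal"` or `"both"`.
#' @param n_sectors,amp_fraction,nms_window,min_amplitude_mm,cluster_radius
#'   see [extract_candidates()] and [cluster_candidates()].
#' @param min_volume_voxels ring volume threshold, voxels.
#' @param proximal_hint world-mm point marking the proximal side (default far
#'   +z, superior).
#' @param case_id,timepoint,origin_landmark metadata for the returned set.
#' @return an [observation_point_set()] (unregistered).
#' @export
extract_peaks <- function(mask, orientation = "proximal",
                          n_sectors = 72, amp_fraction = 0.6,
                          nms_window = 2L, min_amplitude_mm = 2.0,
                          cluster_radius = 2.0, min_volume_voxels = 50,
                          proximal_hint = c(0, 0, 1e6),
                          case_id = "case", timepoint = "T1",
                          origin_landmark = c(0, 0, 0)) {
  if (sum(mask$values) == 0) stop("extract_peaks: empty mask")
  comps <- label_rings(mask, min_volume_voxels = min_volume_voxels)
  comps <- order_rings(comps, proximal_hint = proximal_hint)
  centroids <- do.call(rbind, lapply(comps, `[[`, "centroid"))
  if (length(comps) >= 2L) {
    cl <- fit_centerline(centroids)
    # tangent points distal (t increases ring 1 -> M); proximal is -tangent
    prox_dirs <- -cl$tangent(cl$t_control)
  } else {
    d <- proximal_hint - comps[[1]]$centroid
    prox_dirs <- matrix(d / sqrt(sum(d^2)), 1)
  }
  cand <- do.call(rbind, lapply(seq_along(comps), function(i) {
    extract_candidates(comps[[i]], mask, prox_dirs[i, ],
                       n_sectors = n_sectors, amp_fraction = amp_fraction,
                       nms_window = nms_window,
                       min_amplitude_mm = min_amplitude_mm,
                       orientation = orientation)
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    stop("extract_peaks: no apex candidates survived elimination")
  peaks <- cluster_candidates(cand, radius = cluster_radius)
  observation_point_set(peaks, case_id = case_id, timepoint = timepoint,
                        origin_landmark = origin_landmark)
}

#' Agreement between an extracted and a reference point set
#'
#' Greedy one-to-one nearest-neighbor matching by ascending distance;
#' reference points with no extracted point within `match_threshold` count as
#' missing. `d_mean`/`d_max` are over matched pairs.
#'
#' @param extracted,reference [observation_point_set()]s.
#' @param match_threshold maximum pairing distance, mm.
#' @return `extraction_agreement` list: `n_reference`, `n_extracted`,
#'   `n_missing`, `missing_rate_pct`, `d_mean`, `d_max`, `matches`
#'   data.frame.
#' @export
compare_point_sets <- function(extracted, reference, match_threshold = 5.0) {
  stopifnot(inherits(extracted, "observation_point_set"),
            inherits(reference, "observation_point_set"))
  re <- peak_coords(reference)
  ex <- peak_coords(extracted)
  if (nrow(re) == 0L) stop("empty reference point set")
  pairs <- expand.grid(ref = seq_len(nrow(re)), ext = seq_len(nrow(ex)))
  pairs$d <- sqrt(rowSums((re[pairs$ref, , drop = FALSE] -
                             ex[pairs$ext, , drop = FALSE])^2))
  pairs <- pairs[pairs$d <= match_threshold, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_ref <- logical(nrow(re)); used_ext <- logical(nrow(ex))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$ref[i]; e <- pairs$ext[i]
    if (!used_ref[r] && !used_ext[e]) {
      keep[i] <- TRUE; used_ref[r] <- TRUE; used_ext[e] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  n_missing <- nrow(re) - nrow(m)
  structure(list(
    n_reference = nrow(re), n_extracted = nrow(ex),
    n_missing = n_missing,
    missing_rate_pct = 100 * n_missing / nrow(re),
    d_mean = if (nrow(m)) mean(m$d) else NA_real_,
    d_max = if (nrow(m)) max(m$d) else NA_real_,
    matches = m), class = "extraction_agreement")
}

#' @export
print.extraction_agreement <- function(x, ...) {
  cat(sprintf("<extraction_agreement> %d/%d matched (missing %.1f%%), D mean %.3f mm, D max %.3f mm\n",
              nrow(x$matches), x$n_reference, x$missing_rate_pct,
              x$d_mean, x$d_max))
  invisible(x)
}

#' Flag manual annotation disagreements for adjudication
#'
#' Reading-protocol utility: pairs two readers' point sets one-to-one
#' (nearest neighbor) and flags pairs farther apart than `tolerance_mm`
#' (default 1.5 mm), which by protocol go to a third reader.
#'
#' @param reader_a,reader_b [observation_point_set()]s.
#' @param tolerance_mm adjudication threshold, mm.
#' @return data.frame of flagged pairs (indices into each set and distance).
#' @export
flag_adjudication <- function(reader_a, reader_b, tolerance_mm = 1.5) {
  agr <- compare_point_sets(reader_a, reader_b, match_threshold = Inf)
  m <- agr$matches
  m[m$d > tolerance_mm, , drop = FALSE]
}
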