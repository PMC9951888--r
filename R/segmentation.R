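#' Resample a volume to isotropic spacing
#'
#' Linearly interpolates an HU volume (or nearest-neighbor resamples a binary
#' mask) onto an isotropic grid, the standard preprocessing before stent
#' measurement at 1 mm resolution. The world-coordinate extent and origin are
#' preserved.
#'
#' @param volume a [voxel_grid()].
#' @param target isotropic voxel size, mm (> 0).
#' @param interpolation `"auto"` (trilinear for scalar volumes,
#'   nearest-neighbor for binary masks), `"linear"`, or `"nearest"`.
#' @return resampled [voxel_grid()].
#' @export
resample_isotropic <- function(volume, target = 1.0,
                               interpolation = c("auto", "linear", "nearest")) {
  stopifnot(inherits(volume, "voxel_grid"))
  interpolation <- match.arg(interpolation)
  if (!is.finite(target) || target <= 0) stop("target spacing must be > 0")
  if (interpolation == "auto")
    interpolation <- if (is_binary_grid(volume)) "nearest" else "linear"

  extent <- (volume$dims - 1L) * volume$spacing
  new_dims <- pmax(1L, as.integer(round(extent / target)) + 1L)
  # fractional source indices of each output voxel center, per axis
  src <- lapply(1:3, function(a) {
    (seq_len(new_dims[a]) - 1) * target / volume$spacing[a]
  })
  out <- array(0, dim = new_dims)
  v <- volume$values
  d <- volume$dims

  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(src[[1]]), 0), d[1] - 1L) + 1L
    iy <- pmin(pmax(round(src[[2]]), 0), d[2] - 1L) + 1L
    iz <- pmin(pmax(round(src[[3]]), 0), d[3] - 1L) + 1L
    out <- v[ix, iy, iz, drop = FALSE]
    dim(out) <- new_dims
  } else {
    fx <- pmin(pmax(src[[1]], 0), d[1] - 1)
    fy <- pmin(pmax(src[[2]], 0), d[2] - 1)
    fz <- pmin(pmax(src[[3]], 0), d[3] - 1)
    x0 <- pmin(floor(fx), d[1] - 2L); wx <- fx - x0
    y0 <- pmin(floor(fy), d[2] - 2L); wy <- fy - y0
    z0 <- pmin(floor(fz), d[3] - 2L); wz <- fz - z0
    if (d[1] == 1L) { x0 <- rep(0, new_dims[1]); wx <- rep(0, new_dims[1]) }
    if (d[2] == 1L) { y0 <- rep(0, new_dims[2]); wy <- rep(0, new_dims[2]) }
    if (d[3] == 1L) { z0 <- rep(0, new_dims[3]); wz <- rep(0, new_dims[3]) }
    corner <- function(ox, oy, oz) {
      xi <- pmin(x0 + ox, d[1] - 1L) + 1L
      yi <- pmin(y0 + oy, d[2] - 1L) + 1L
      zi <- pmin(z0 + oz, d[3] - 1L) + 1L
      vv <- v[xi, yi, zi, drop = FALSE]
      dim(vv) <- new_dims
      wxa <- if (ox == 0) 1 - wx else wx
      wya <- if (oy == 0) 1 - wy else wy
      wza <- if (oz == 0) 1 - wz else wz
      vv * outer(outer(wxa, wya), wza)
    }
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1)
      out <- out + corner(ox, oy, oz)
  }
  voxel_grid(out, spacing = rep(target, 3), origin = volume$origin)
}

#' Threshold segmentation of the stent from an HU volume
#'
#' Stent metal is far denser than contrast-filled vessel; the classical
#' segmentation keeps voxels inside an HU band, by default \[1200, 2200\]
#' (lower bound above vascular contrast, upper bound below blooming
#' artifacts). Inclusive at both ends.
#'
#' @param volume HU [voxel_grid()].
#' @param lo,hi HU band (lo <= hi).
#' @return binary [voxel_grid()]; warns if the mask comes out empty.
#' @export
threshold_segment <- function(volume, lo = 1200, hi = 2200) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (lo > hi) stop("threshold lo must be <= hi")
  vals <- array(0L, dim = volume$dims)
  vals[volume$values >= lo & volume$values <= hi] <- 1L
  if (sum(vals) == 0L)
    warning("threshold segmentation produced an empty mask")
  voxel_grid(vals, spacing = volume$spacing, origin = volume$origin)
}

# 26-connected component labeling of a binary mask.
# Returns list(labels = integer vector per foreground voxel, idx = n x 3
# 0-based foreground indices, sizes = voxel count per label), labels 1..K
# ordered by first occurrence.
label_components_26 <- function(mask, connectivity = 26L) {
  stopifnot(is_binary_grid(mask))
  idx <- foreground_indices(mask)
  n <- nrow(idx)
  if (n == 0L) return(list(labels = integer(0), idx = idx, sizes = integer(0)))
  d <- mask$dims
  key <- idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  else if (connectivity == 18L)
    offsets <- offsets[rowSums(abs(offsets)) <= 2, , drop = FALSE]
  else if (connectivity != 26L)
    stop("connectivity must be 6, 18 or 26")
  # half the offsets suffice (undirected edges)
  lex <- offsets[, 1] + 3 * offsets[, 2] + 9 * offsets[, 3]
  offsets <- offsets[lex > 0, , drop = FALSE]

  edges_from <- integer(0); edges_to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(idx, 2, offsets[k, ], `+`)
    inb <- nb[, 1] >= 0 & nb[, 1] < d[1] &
      nb[, 2] >= 0 & nb[, 2] < d[2] &
      nb[, 3] >= 0 & nb[, 3] < d[3]
    nb_key <- nb[inb, 1] + d[1] * (nb[inb, 2] + d[2] * nb[inb, 3])
    m <- match(nb_key, key)
    hit <- !is.na(m)
    edges_from <- c(edges_from, which(inb)[hit])
    edges_to <- c(edges_to, m[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  comp <- igraph::components(g)
  # renumber by first occurrence so labels are deterministic in voxel order
  first <- match(unique(comp$membership), comp$membership)
  relabel <- match(comp$membership, comp$membership[sort(first)])
  ord_labels <- comp$membership[sort(first)]
  relabel <- match(comp$membership, ord_labels)
  list(labels = relabel, idx = idx,
       sizes = as.integer(tabulate(relabel, max(relabel))))
}

#' Keep the stent's connected region(s), discarding speckle
#'
#' Mirrors region-grow stent selection after thresholding. In `"largest"`
#' mode every 26-connected component whose volume is at least `fraction` of
#' the largest component is kept, so a stent made of disjoint support rings
#' survives while small speckle is removed. In seed mode only the component
#' containing `seed` (world mm) is kept.
#'
#' @param mask binary [voxel_grid()].
#' @param mode `"largest"` or `"seed"`.
#' @param seed world-mm point inside the wanted component (seed mode).
#' @param fraction keep components with volume >= fraction * largest.
#' @param connectivity 6, 18 or 26 (default 26: thin oblique wires fragment
#'   under face connectivity).
#' @return binary [voxel_grid()] of the selected component(s).
#' @export
select_stent_region <- function(mask, mode = c("largest", "seed"), seed = NULL,
                                fraction = 0.1, connectivity = 26L) {
  mode <- match.arg(mode)
  if (sum(mask$values) == 0) stop("cannot select a region from an empty mask")
  cc <- label_components_26(mask, connectivity)
  keep_labels <- if (mode == "largest") {
    which(cc$sizes >= fraction * max(cc$sizes))
  } else {
    if (is.null(seed)) stop("seed mode needs a world-mm seed point")
    svox <- round(world_to_voxel(mask, seed))
    hit <- which(cc$idx[, 1] == svox[1] & cc$idx[, 2] == svox[2] &
                   cc$idx[, 3] == svox[3])
    if (length(hit) == 0L)
      stop("seed point does not lie inside any foreground component")
    cc$labels[hit[1]]
  }
  keep <- cc$labels %in% keep_labels
  vals <- array(0L, dim = mask$dims)
  ii <- cc$idx[keep, , drop = FALSE]
  vals[ii[, 1] + mask$dims[1] * (ii[, 2] + mask$dims[2] * ii[, 3]) + 1] <- 1L
  voxel_grid(vals, spacing = mask$spacing, origin = mask$origin)
}

#' Dice overlap between two binary masks
#'
#' `dice = 2|A intersect B| / (|A| + |B|)`; `dice_loss = 1 - dice` is the
#' annotation-QC discrepancy measure. Two empty masks are defined as
#' perfectly agreeing (dice 1, loss 0).
#'
#' @param a,b binary [voxel_grid()]s on identical grids.
#' @return a `segmentation_report` list: `dice`, `dice_loss`, `n_a`, `n_b`,
#'   `n_intersection`.
#' @export
dice_score <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  stopifnot_same_geometry(a, b)
  if (!is_binary_grid(a) || !is_binary_grid(b))
    stop("dice_score needs binary masks")
  na <- sum(a$values); nb <- sum(b$values)
  ni <- sum(a$values * b$values)
  dice <- if (na + nb == 0) 1 else 2 * ni / (na + nb)
  structure(list(dice = dice, dice_loss = 1 - dice,
                 n_a = na, n_b = nb, n_intersection = ni),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> dice %.4f (loss %.4f); |A| = %d, |B| = %d, |A&B| = %d\n",
              x$dice, x$dice_loss, x$n_a, x$n_b, x$n_intersection))
  invisible(x)
}
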