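# Programmatic fixtures shared across test files.

# Axis-aligned cylinder mask of radius r spanning z in [0, zlen], on an
# isotropic grid whose voxel boundaries are aligned with the cut planes
# (centres at odd multiples of spacing/2).
cylinder_fixture <- function(r = 3, zlen = 12, spacing = 0.25, pad = 2,
                             semi_axes = NULL, center = c(0, 0)) {
  half_xy <- (if (is.null(semi_axes)) r else max(semi_axes)) + pad
  n_xy <- 2L * ceiling(half_xy / spacing)
  n_z <- ceiling((zlen + 2 * pad) / spacing)
  origin <- c(-(n_xy / 2) * spacing + spacing / 2,
              -(n_xy / 2) * spacing + spacing / 2,
              -pad + spacing / 2)
  grid <- image_volume(array(0, dim = c(n_xy, n_xy, n_z)),
                       spacing = rep(spacing, 3), origin = origin)
  xyz <- voxel_centers(grid)
  dx <- xyz[, 1] - center[1]
  dy <- xyz[, 2] - center[2]
  radial <- if (is.null(semi_axes))
    sqrt(dx^2 + dy^2) <= r
  else
    (dx / semi_axes[1])^2 + (dy / semi_axes[2])^2 <= 1
  m <- radial & xyz[, 3] >= 0 & xyz[, 3] <= zlen
  mask <- seg_mask(array(m, dim = dim(grid$data)), grid = grid)
  pts <- control_points(A = c(center, 0), B = c(center, zlen),
                        C = c(center, -5), D = c(center, zlen + 5))
  list(mask = mask, points = pts, voi = build_voi(pts, 20))
}

# Random small binary mask.
random_mask <- function(dims = c(8L, 8L, 8L), p = 0.35, spacing = c(1, 1, 1)) {
  m <- array(runif(prod(dims)) < p, dim = dims)
  seg_mask(m, spacing = spacing)
}

# Solid cube mask of n voxels per side inside a padded grid.
cube_mask <- function(n = 8L, pad = 2L, spacing = 0.25, offset = c(0L, 0L, 0L)) {
  d <- rep(n + 2L * pad + 8L, 3L) # fixed headroom so offsets share one grid
  m <- array(FALSE, dim = d)
  ix <- lapply(1:3, function(ax) pad + offset[ax] + seq_len(n))
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  seg_mask(m, spacing = rep(spacing, 3))
}

# Restrict a mask to a VOI by testing each foreground voxel centre.
rasterize_voi_intersect <- function(mask, voi) {
  idx <- which(mask$data)
  keep <- idx[voi_contains(voi, voxel_centers(mask, idx))]
  m <- array(FALSE, dim = dim(mask$data))
  m[keep] <- TRUE
  seg_mask(m, grid = mask)
}

# Unique undirected edges of a mesh.
unique_edges <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# Sort matrix rows lexicographically (order-independent comparison).
msort <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

# Rotation matrix about z by `deg` degrees.
rot_z <- function(deg) {
  th <- deg * pi / 180
  cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
}

# A generic (non-axis-aligned) rotation used in frame-invariance tests.
generic_rotation <- function() {
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 0.6
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
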