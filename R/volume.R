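#' Image volume container
#'
#' A 3D scalar grid together with its physical geometry: voxel spacing in mm,
#' the world position (mm, LPS) of the centre of voxel index `(0,0,0)`, and an
#' orthonormal direction matrix mapping index axes to world axes. All world
#' coordinates inside the package are LPS (the DICOM convention); readers for
#' RAS-native formats (NIfTI, 3D Slicer markups) convert at the boundary.
#'
#' The world position of the (0-based) voxel index `v` is
#' `origin + direction %*% (spacing * v)`. Voxel indices are 0-based in all
#' geometric formulas; the world position of a voxel is its centre.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each index axis; all > 0.
#' @param origin numeric length-3, world mm of the centre of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix (index axes to world axes).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers")
  check_orthonormal(direction)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' Binary segmentation mask on a volume grid
#'
#' A label map: a logical 3D array sharing the grid (spacing, origin,
#' direction) of its parent [image_volume()].
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param grid an `image_volume` or `seg_mask` supplying the geometry, or
#'   `NULL` to pass `spacing`/`origin`/`direction` directly.
#' @inheritParams image_volume
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, grid = NULL, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.null(grid)) {
    spacing <- grid$spacing; origin <- grid$origin; direction <- grid$direction
  }
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be 0/1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1 numeric")
  data[is.na(data)] <- FALSE
  obj <- image_volume(array(FALSE, dim = dim(data)), spacing, origin, direction)
  obj$data <- data
  class(obj) <- c("seg_mask", "image_volume")
  obj
}

check_orthonormal <- function(direction, tol = 1e-6) {
  if (max(abs(crossprod(direction) - diag(3))) > tol)
    stop("'direction' must be orthonormal (within 1e-6)")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "seg_mask")) "seg_mask" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) [LPS]\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              paste(signif(x$origin, 6), collapse = ", ")))
  if (inherits(x, "seg_mask"))
    cat(sprintf("  foreground: %d voxels (%.4g mm^3)\n", sum(x$data),
                sum(x$data) * prod(x$spacing)))
  invisible(x)
}

#' Do two objects share the same voxel grid?
#' @param a,b `image_volume` / `seg_mask` objects.
#' @param tol geometric tolerance in mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  length(dim(a$data)) == length(dim(b$data)) &&
    all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' World coordinates of voxel centres
#'
#' @param grid an `image_volume` or `seg_mask`.
#' @param idx integer vector of 1-based linear indices into the array, or an
#'   n x 3 matrix of 1-based array indices. `NULL` returns all voxels.
#' @return n x 3 matrix of world mm (LPS).
#' @export
voxel_centers <- function(grid, idx = NULL) {
  d <- dim(grid$data)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ijk <- if (is.matrix(idx)) idx else arrayInd(idx, d)
  ijk0 <- sweep(ijk, 2, c(1, 1, 1)) # to 0-based
  xyz <- sweep(ijk0, 2, grid$spacing, `*`) %*% t(grid$direction)
  sweep(xyz, 2, grid$origin, `+`)
}

#' Convert world coordinates to continuous 0-based voxel indices
#' @param grid an `image_volume` or `seg_mask`.
#' @param xyz n x 3 matrix (or length-3 vector) of world mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
world_to_index <- function(grid, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  rel <- sweep(xyz, 2, grid$origin) %*% grid$direction # D^-1 = t(D)
  sweep(rel, 2, grid$spacing, `/`)
}

# Per-axis coordinate contributions so that
# world[i,j,k] = ax[i] + ay[j] + az[k] (componentwise per world axis).
# Returns list of three length-n_axis x 3 matrices.
axis_coords <- function(grid) {
  d <- dim(grid$data)
  lapply(1:3, function(ax) {
    i0 <- seq_len(d[ax]) - 1
    contrib <- outer(i0 * grid$spacing[ax], grid$direction[, ax])
    if (ax == 1) contrib <- sweep(contrib, 2, grid$origin, `+`)
    contrib
  })
}

#' Convert coordinates between the RAS and LPS world frames
#'
#' Negates the first two components. The transform is its own inverse.
#' @param xyz n x 3 matrix or length-3 vector.
#' @return same shape as input.
#' @export
ras_lps <- function(xyz) {
  if (is.matrix(xyz)) {
    xyz[, 1:2] <- -xyz[, 1:2]
    xyz
  } else {
    c(-xyz[1], -xyz[2], xyz[3])
  }
}

#' Volume of a mask in cubic millimetres
#'
#' Exactly (number of foreground voxels) x (voxel volume), where voxel volume
#' is the product of the three spacing components.
#'
#' @param mask a `seg_mask`.
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) {
  n <- sum(mask$data)
  if (n == 0L) stop("mask is empty")
  n * prod(mask$spacing)
}

# 1-based array indices of foreground voxels
mask_indices <- function(mask) which(mask$data)

#' Boundary voxels of a mask
#'
#' Foreground voxels with at least one background 6-neighbour; voxels on the
#' array edge count their out-of-volume neighbours as background.
#'
#' @param mask a `seg_mask`.
#' @return a `seg_mask` marking the boundary voxels.
#' @export
boundary_voxels <- function(mask) {
  m <- mask$data
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) {
    lo <- shift_array(m, ax, +1L) # neighbour at index-1 side
    hi <- shift_array(m, ax, -1L)
    interior <- interior & lo & hi
  }
  seg_mask(m & !interior, grid = mask)
}

# Shift a 3D array by `by` voxels along axis `ax`, padding with FALSE/0.
shift_array <- function(a, ax, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[ax]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_dst <- ix_src
  ix_src[[ax]] <- src
  ix_dst[[ax]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

#' Euclidean distance transform to a voxel set
#'
#' For every voxel of the grid, the physical distance (mm, anisotropy-aware)
#' to the centre of the nearest voxel where `feature` is foreground.
#'
#' @param feature a `seg_mask` of feature voxels.
#' @return 3D numeric array of distances (mm); `Inf` if `feature` is empty.
#' @export
distance_transform <- function(feature) {
  d2 <- .edt_sq(as.logical(feature$data), dim(feature$data), feature$spacing)
  array(sqrt(d2), dim = dim(feature$data))
}
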