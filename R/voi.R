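#' Truncated cylindrical volume of interest
#'
#' The VOI that initialises ear-canal segmentation: a cylinder of the given
#' diameter around the A-B axis, truncated by two tilted cut planes. The
#' lateral plane passes through A with outward normal along A->C; the medial
#' plane passes through B with outward normal along B->D. Both normals face
#' away from the canal interior.
#'
#' @param points a [control_points()] set.
#' @param diameter cylinder diameter in mm (default 20).
#' @return object of class `voi_definition` with fields `lateral_plane`,
#'   `medial_plane` (each `list(point, normal)`), `axis_start`, `axis_end`,
#'   `diameter`.
#' @export
build_voi <- function(points, diameter = 20) {
  stopifnot(inherits(points, "control_points"))
  if (!is.numeric(diameter) || diameter <= 0) stop("'diameter' must be > 0")
  A <- points$A; B <- points$B
  nC <- points$C - A
  nD <- points$D - B
  if (sqrt(sum(nC^2)) < 1e-12 || sqrt(sum(nD^2)) < 1e-12)
    stop("degenerate plane normal: C must differ from A and D from B")
  n_lat <- nC / sqrt(sum(nC^2))
  n_med <- nD / sqrt(sum(nD^2))
  ab <- B - A
  cosCA <- sum(nC * ab) / (sqrt(sum(nC^2)) * sqrt(sum(ab^2)))
  if (cosCA >= 1 - 1e-12)
    warning("point C lies on the interior side of the axis; ",
            "the lateral plane faces into the canal")
  structure(list(
    lateral_plane = list(point = A, normal = n_lat),
    medial_plane = list(point = B, normal = n_med),
    axis_start = A, axis_end = B, diameter = diameter),
    class = "voi_definition")
}

#' @export
print.voi_definition <- function(x, ...) {
  cat(sprintf("<voi_definition> axis (%s) -> (%s), diameter %g mm\n",
              paste(signif(x$axis_start, 6), collapse = ", "),
              paste(signif(x$axis_end, 6), collapse = ", "),
              x$diameter))
  invisible(x)
}

#' Point-in-VOI test
#'
#' A point is inside iff its distance to the infinite line through A and B is
#' at most `diameter / 2` and it lies on the interior (non-positive) side of
#' both cut planes. All three tests are boundary-inclusive.
#'
#' @param voi a [build_voi()] result.
#' @param x length-3 vector or n x 3 matrix of world mm.
#' @return logical vector.
#' @export
voi_contains <- function(voi, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 3)
  A <- voi$axis_start
  u <- voi$axis_end - A
  u <- u / sqrt(sum(u^2))
  w <- sweep(x, 2, A)
  proj <- as.numeric(w %*% u)
  d2 <- rowSums(w^2) - proj^2
  d2[d2 < 0] <- 0
  radial <- d2 <= (voi$diameter / 2)^2 + 1e-12
  lat <- as.numeric(sweep(x, 2, voi$lateral_plane$point) %*%
                      voi$lateral_plane$normal) <= 1e-12
  med <- as.numeric(sweep(x, 2, voi$medial_plane$point) %*%
                      voi$medial_plane$normal) <= 1e-12
  radial & lat & med
}

#' Rasterise a VOI onto a volume grid
#'
#' Marks every voxel whose centre (world mm) satisfies [voi_contains()].
#'
#' @param voi a [build_voi()] result.
#' @param grid an [image_volume()] (or `seg_mask`) supplying the grid.
#' @return a [seg_mask()] on the same grid.
#' @export
rasterize_voi <- function(voi, grid) {
  d <- dim(grid$data)
  ac <- axis_coords(grid)
  A <- voi$axis_start
  u <- voi$axis_end - A
  u <- u / sqrt(sum(u^2))
  # separable accumulation of w = p - A, per world axis
  inside <- array(TRUE, dim = d)
  # compute the three scalar fields needed: proj = w.u, |w|^2, plane dots
  sum_field <- function(coefs, const) {
    # coefs: length-3 weights applied to world components
    f1 <- as.numeric(ac[[1]] %*% coefs)
    f2 <- as.numeric(ac[[2]] %*% coefs)
    f3 <- as.numeric(ac[[3]] %*% coefs)
    outer(outer(f1, f2, `+`), f3, `+`) + const
  }
  proj <- sum_field(u, -sum(A * u))
  lat <- sum_field(voi$lateral_plane$normal,
                   -sum(voi$lateral_plane$point * voi$lateral_plane$normal))
  med <- sum_field(voi$medial_plane$normal,
                   -sum(voi$medial_plane$point * voi$medial_plane$normal))
  # |w|^2 = |p|^2 - 2 p.A + |A|^2; |p|^2 is not separable as a single sum,
  # so assemble from per-axis world coordinates
  X <- sum_field(c(1, 0, 0), 0)
  Y <- sum_field(c(0, 1, 0), 0)
  Z <- sum_field(c(0, 0, 1), 0)
  w2 <- (X - A[1])^2 + (Y - A[2])^2 + (Z - A[3])^2
  d2 <- w2 - proj^2
  inside <- (d2 <= (voi$diameter / 2)^2 + 1e-12) & (lat <= 1e-12) & (med <= 1e-12)
  if (!any(inside)) stop("VOI does not intersect volume")
  seg_mask(inside, grid = grid)
}
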