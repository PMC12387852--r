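#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined as identical (1).
#'
#' @param a,b [seg_mask()] objects on the same grid.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!same_grid(a, b)) stop("masks are not on the same grid")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$data & b$data) / (na + nb)
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Boundary voxels (foreground with a background 6-neighbour) are extracted
#' from both masks; for every boundary voxel of one mask the distance to the
#' nearest boundary voxel of the other is computed (world mm, exact), in both
#' directions. By default the two directed distance sets are pooled and the
#' 95th percentile (linear interpolation between order statistics) is
#' returned; `mode = "max_directed"` instead returns the larger of the two
#' directed 95th percentiles.
#'
#' @param a,b non-empty [seg_mask()] objects on the same grid.
#' @param probs percentile in `[0, 1]` (default 0.95).
#' @param mode `"pooled"` (default) or `"max_directed"`.
#' @return distance in mm.
#' @export
hd95 <- function(a, b, probs = 0.95, mode = c("pooled", "max_directed")) {
  mode <- match.arg(mode)
  sds <- surface_distances(a, b)
  if (mode == "pooled")
    quantile(c(sds$a_to_b, sds$b_to_a), probs, names = FALSE, type = 7)
  else
    max(quantile(sds$a_to_b, probs, names = FALSE, type = 7),
        quantile(sds$b_to_a, probs, names = FALSE, type = 7))
}

#' Symmetric nearest-surface distance sets between two masks
#'
#' @param a,b non-empty [seg_mask()] objects on the same grid.
#' @return `list(a_to_b, b_to_a)` of nearest-boundary distances (mm), one
#'   value per boundary voxel.
#' @export
surface_distances <- function(a, b) {
  if (!same_grid(a, b)) stop("masks are not on the same grid")
  if (!any(a$data) || !any(b$data)) stop("masks must be non-empty")
  ba <- boundary_voxels(a)
  bb <- boundary_voxels(b)
  da <- distance_transform(bb) # distance to nearest b-boundary voxel
  db <- distance_transform(ba)
  list(a_to_b = da[ba$data], b_to_a = db[bb$data])
}

#' Rigid point-cloud alignment by iterative closest point
#'
#' Point-to-point ICP: alternate nearest-neighbour matching of moving points
#' to fixed points with the closed-form least-squares rigid fit
#' (cross-covariance SVD, Kabsch / Arun), until the matched RMS improves by
#' less than `tol` or `max_iter` is reached. Matched MSE is non-increasing
#' across iterations; the result is a local optimum, so the inputs should be
#' coarsely aligned.
#'
#' @param moving,fixed n x 3 matrices of points (mm), each with at least 3
#'   non-collinear points.
#' @param max_iter maximum ICP iterations (default 100).
#' @param tol convergence tolerance on the matched RMS, mm (default 1e-5).
#' @return object of class `rigid_transform`: `list(rotation, translation,
#'   rms, iterations, converged)`; apply with [transform_points()].
#' @export
rigid_align <- function(moving, fixed, max_iter = 100L, tol = 1e-5) {
  moving <- as_points(moving); fixed <- as_points(fixed)
  check_noncollinear(moving); check_noncollinear(fixed)
  R <- diag(3)
  tr <- c(0, 0, 0)
  cur <- transform_points(list(rotation = R, translation = tr), moving)
  prev_rms <- Inf
  iters <- 0L
  converged <- FALSE
  repeat {
    nn <- .nn_sqdist(cur, fixed)
    rms <- sqrt(mean(nn$d2))
    if (iters >= max_iter) break
    if (prev_rms - rms < tol) { converged <- TRUE; break }
    prev_rms <- rms
    matched <- fixed[nn$idx, , drop = FALSE]
    fit <- kabsch(moving, matched)
    R <- fit$rotation; tr <- fit$translation
    cur <- transform_points(fit, moving)
    iters <- iters + 1L
  }
  structure(list(rotation = R, translation = tr, rms = rms,
                 iterations = iters, converged = converged),
            class = "rigid_transform")
}

# Least-squares rigid fit moving -> target with known correspondence.
kabsch <- function(moving, target) {
  mm <- colMeans(moving); mt <- colMeans(target)
  H <- crossprod(sweep(moving, 2, mm), sweep(target, 2, mt))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(mt - R %*% mm))
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform` (or `list(rotation, translation)`).
#' @param points n x 3 matrix.
#' @return n x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  points <- as_points(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' RMS nearest-surface distance from one point set to another
#'
#' Directed by default (each point of `a` to its nearest point of `b`),
#' matching the use of comparing an implant surface against the surrounding
#' canal surface; `symmetric = TRUE` pools both directions.
#'
#' @param a n x 3 matrix of query points (mm), or a [surface_mesh()] whose
#'   vertices are used.
#' @param b reference point set or [surface_mesh()].
#' @param symmetric pool distances from both directions.
#' @return RMS distance in mm.
#' @export
rms_distance <- function(a, b, symmetric = FALSE) {
  pa <- as_points(a); pb <- as_points(b)
  d2 <- .nn_sqdist(pa, pb)$d2
  if (symmetric) d2 <- c(d2, .nn_sqdist(pb, pa)$d2)
  sqrt(mean(d2))
}

as_points <- function(x) {
  if (inherits(x, "surface_mesh")) return(x$vertices)
  if (inherits(x, "seg_mask")) {
    bd <- boundary_voxels(x)
    return(voxel_centers(bd, mask_indices(bd)))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(x) == 0L) stop("point set is empty")
  storage.mode(x) <- "double"
  x
}

check_noncollinear <- function(p) {
  if (nrow(p) < 3L) stop("need at least 3 non-collinear points")
  s <- svd(sweep(p, 2, colMeans(p)))$d
  if (s[2] < 1e-9 * max(s[1], 1))
    stop("degenerate (collinear) point set")
  invisible(TRUE)
}
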