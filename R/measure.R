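#' Centres of the two boundary faces of a segmentation
#'
#' Each centre is the centroid (world mm) of the mask voxels lying within
#' half the maximum voxel spacing of the respective cut plane. This reduces
#' to the geometric face centre for axis-aligned cylinders and stays robust
#' for tilted planes.
#'
#' @param mask a non-empty [seg_mask()].
#' @param voi the [build_voi()] definition whose planes bound the mask.
#' @return `list(lateral_center, medial_center)` in world mm.
#' @export
boundary_centers <- function(mask, voi) {
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty")
  xyz <- voxel_centers(mask, idx)
  slab <- max(mask$spacing) / 2
  centers <- list()
  for (side in c("lateral", "medial")) {
    pl <- voi[[paste0(side, "_plane")]]
    d <- abs(as.numeric(sweep(xyz, 2, pl$point) %*% pl$normal))
    near <- d <= slab + 1e-9
    if (!any(near))
      stop("segmentation does not reach the ", side, " boundary")
    centers[[paste0(side, "_center")]] <- colMeans(xyz[near, , drop = FALSE])
  }
  centers
}

#' Measure a canal segmentation
#'
#' Computes the four canonical measurements of a canal-like segmentation:
#' \describe{
#'   \item{volume}{foreground voxel count times voxel volume (mm^3).}
#'   \item{length}{distance between the centres of the two boundary faces
#'     (see [boundary_centers()]).}
#'   \item{width}{the mask is resampled (nearest neighbour) on a plane
#'     orthogonal to the length direction through the length midpoint, with
#'     in-plane pixels of the minimum voxel spacing; the width is the longest
#'     chord through the in-plane midpoint over directions swept at 0.5
#'     degree resolution, measured between the two extreme mask pixels on the
#'     chord line.}
#'   \item{height}{the extent of the whole cross-section projected onto the
#'     in-plane direction perpendicular to the width chord.}
#' }
#'
#' @param mask a non-empty [seg_mask()].
#' @param voi the [build_voi()] definition whose planes bound the mask.
#' @param sweep_step angular sweep resolution in degrees (default 0.5).
#' @return object of class `measurement_report`: list with `volume`,
#'   `length`, `width`, `height`, `lateral_center`, `medial_center`,
#'   `midpoint`, `width_direction` (unit 3-vector, world mm).
#' @export
measure_canal <- function(mask, voi, sweep_step = 0.5) {
  vol <- mask_volume(mask)
  bc <- boundary_centers(mask, voi)
  lc <- bc$lateral_center; mc <- bc$medial_center
  len_vec <- mc - lc
  len <- sqrt(sum(len_vec^2))
  if (len <= 0) stop("degenerate segmentation: boundary centres coincide")
  u <- len_vec / len
  midpoint <- (lc + mc) / 2
  basis <- plane_basis(u, mask$direction)
  cs <- cross_section_pixels(mask, midpoint, basis)
  if (!cs$midpoint_in)
    stop("midpoint outside segmentation")
  chord <- longest_chord(cs$st, cs$pixel, sweep_step)
  wd <- chord$dir[1] * basis$e1 + chord$dir[2] * basis$e2
  perp <- c(-chord$dir[2], chord$dir[1])
  hproj <- cs$st %*% perp
  height <- max(hproj) - min(hproj)
  structure(list(volume = vol, length = len, width = chord$width,
                 height = height, lateral_center = lc, medial_center = mc,
                 midpoint = midpoint, width_direction = wd),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>\n")
  cat(sprintf("  volume: %.4g mm^3\n", x$volume))
  cat(sprintf("  length: %.4g mm\n", x$length))
  cat(sprintf("  width:  %.4g mm\n", x$width))
  cat(sprintf("  height: %.4g mm\n", x$height))
  invisible(x)
}

# Deterministic orthonormal in-plane basis for a unit normal u. The
# reference vector is taken from the grid's own direction axes (the one most
# orthogonal to u), so the in-plane sampling pattern co-rotates with the
# scene and measurements are invariant under joint rigid motion.
plane_basis <- function(u, direction = diag(3)) {
  dots <- abs(as.numeric(t(direction) %*% u))
  ref <- direction[, which.min(dots)]
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(u, e1)
  list(e1 = e1, e2 = e2)
}

# Sample the 3D mask on the cross-section plane through `midpoint` spanned by
# basis (e1, e2). Returns in-plane coordinates of foreground pixels (n x 2,
# mm relative to the midpoint), the pixel size, and whether the centre pixel
# is foreground.
cross_section_pixels <- function(mask, midpoint, basis) {
  px <- min(mask$spacing)
  # in-plane extent: bound by the mask's maximal distance from the midpoint
  idx <- mask_indices(mask)
  xyz <- voxel_centers(mask, idx)
  rel <- sweep(xyz, 2, midpoint)
  rmax <- sqrt(max(rowSums(rel^2))) + px
  s <- seq(-rmax, rmax, by = px)
  grid2 <- cbind(rep(s, times = length(s)), rep(s, each = length(s)))
  pts <- sweep(outer(grid2[, 1], basis$e1) + outer(grid2[, 2], basis$e2),
               2, midpoint, `+`)
  cidx <- round(world_to_index(mask, pts)) # nearest voxel, 0-based
  d <- dim(mask$data)
  ok <- cidx[, 1] >= 0 & cidx[, 1] < d[1] &
        cidx[, 2] >= 0 & cidx[, 2] < d[2] &
        cidx[, 3] >= 0 & cidx[, 3] < d[3]
  fg <- rep(FALSE, nrow(grid2))
  lin <- cidx[ok, 1] + d[1] * (cidx[ok, 2] + d[2] * cidx[ok, 3]) + 1
  fg[ok] <- mask$data[lin]
  centre <- which(abs(grid2[, 1]) < px / 2 & abs(grid2[, 2]) < px / 2)
  list(st = grid2[fg, , drop = FALSE], pixel = px,
       midpoint_in = length(centre) > 0 && any(fg[centre]))
}

# Longest chord through the in-plane origin over swept directions.
longest_chord <- function(st, pixel, sweep_step) {
  thetas <- seq(0, 180 - sweep_step, by = sweep_step) * pi / 180
  best <- -Inf
  best_dir <- c(1, 0)
  for (th in thetas) {
    dir <- c(cos(th), sin(th))
    along <- st %*% dir
    perp <- st %*% c(-dir[2], dir[1])
    on_line <- abs(perp) <= pixel / 2 + 1e-9
    if (!any(on_line)) next
    w <- max(along[on_line]) - min(along[on_line])
    if (w > best) { best <- w; best_dir <- dir }
  }
  if (!is.finite(best)) stop("midpoint outside segmentation")
  list(width = best, dir = best_dir)
}
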