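#' Segmentation parameters
#'
#' @param sigma Gaussian smoothing width in mm; `NULL` (default) uses the
#'   mean voxel spacing of the volume at run time, matching the convention of
#'   smoothing at the scale of one voxel.
#' @param threshold intensity threshold; `NULL` picks the midpoint of the 1st
#'   and 99th intensity percentiles inside the VOI (a deterministic stand-in
#'   for an interactive slider).
#' @param target `"air"` segments intensities `<= threshold`;
#'   `"soft_tissue"` segments the band `[lower_bound, threshold]`.
#' @param lower_bound lower intensity bound for `target = "soft_tissue"`.
#' @param voi_diameter VOI cylinder diameter in mm (default 20).
#' @return object of class `seg_params`. Connectivity is fixed at the
#'   6-neighbourhood.
#' @export
seg_params <- function(sigma = NULL, threshold = NULL,
                       target = c("air", "soft_tissue"),
                       lower_bound = -200, voi_diameter = 20) {
  target <- match.arg(target)
  if (!is.null(sigma) && (!is.finite(sigma) || sigma < 0))
    stop("'sigma' must be >= 0")
  if (voi_diameter <= 0) stop("'voi_diameter' must be > 0")
  structure(list(sigma = sigma, threshold = threshold, target = target,
                 lower_bound = lower_bound, connectivity = 6L,
                 voi_diameter = voi_diameter),
            class = "seg_params")
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian filter. `sigma` is given in mm and converted per axis
#' to voxel units as `sigma / spacing[axis]`, so anisotropic grids are
#' smoothed isotropically in world space. Boundaries are handled by
#' reflection, which preserves the global intensity sum of a symmetric
#' kernel to well under 0.1%. `sigma = 0` returns the input unchanged.
#'
#' @param volume an [image_volume()].
#' @param sigma smoothing width in mm (>= 0).
#' @return a smoothed `image_volume` on the same grid.
#' @export
smooth_volume <- function(volume, sigma) {
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(volume)
  data <- volume$data * 1.0
  for (ax in 1:3) {
    sv <- sigma / volume$spacing[ax]
    k <- gaussian_kernel(sv)
    if (length(k) > 1L) data <- convolve_axis_reflect(data, k, ax)
  }
  out <- volume
  out$data <- data
  out
}

# Sampled, renormalised Gaussian; radius covers 4 sigma.
gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along axis `ax` with reflective ("symmetric") boundaries,
# implemented as a weighted sum of index-shifted copies.
convolve_axis_reflect <- function(data, kernel, ax) {
  d <- dim(data)
  n <- d[ax]
  r <- (length(kernel) - 1L) %/% 2L
  # reflected index lookup: ... 2 1 | 1 2 ... n | n n-1 ...
  reflect <- function(i) {
    i <- abs(i - 1L) + 1L          # reflect at the low edge
    over <- i > n
    i[over] <- 2L * n + 1L - i[over] # reflect at the high edge
    i
  }
  out <- array(0, dim = d)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (s in (-r):r) {
    src <- ix
    src[[ax]] <- reflect(ix[[ax]] + s)
    out <- out + kernel[s + r + 1L] * data[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Threshold a smoothed volume inside the VOI
#'
#' For `target = "air"` the mask is `intensity <= threshold` restricted to
#' the VOI; for `target = "soft_tissue"` it is
#' `lower_bound <= intensity <= threshold` restricted to the VOI. An empty
#' result is allowed here and caught downstream by component selection.
#'
#' @param smoothed an [image_volume()].
#' @param voi_mask a [seg_mask()] on the same grid (the rasterised VOI).
#' @param params a [seg_params()] with a non-`NULL` threshold.
#' @return a [seg_mask()].
#' @export
threshold_in_voi <- function(smoothed, voi_mask, params) {
  if (!same_grid(smoothed, voi_mask)) stop("volume and VOI mask grids differ")
  thr <- params$threshold
  if (is.null(thr)) stop("'params$threshold' must be set (see default_threshold)")
  m <- if (params$target == "air") smoothed$data <= thr
       else smoothed$data >= params$lower_bound & smoothed$data <= thr
  seg_mask(m & voi_mask$data, grid = smoothed)
}

#' Deterministic default threshold
#'
#' Midpoint of the 1st and 99th intensity percentiles inside the VOI; with a
#' bimodal air/bone histogram this lands mid-way between the two tissue
#' classes.
#'
#' @param volume an [image_volume()].
#' @param voi_mask a [seg_mask()] restricting the histogram.
#' @return a scalar intensity.
#' @export
default_threshold <- function(volume, voi_mask) {
  vals <- volume$data[voi_mask$data]
  if (length(vals) == 0L) stop("VOI mask is empty")
  q <- quantile(vals, c(0.01, 0.99), names = FALSE, type = 7)
  mean(q)
}

#' 6-connected component labelling
#'
#' Face-adjacent foreground voxels share a label; labels run 1..K with 0 as
#' background.
#'
#' @param mask a [seg_mask()].
#' @return `list(labels = integer 3D array, count = K)`.
#' @export
label_components <- function(mask) {
  res <- .cc_label6(as.logical(mask$data), dim(mask$data))
  list(labels = array(res$labels, dim = dim(mask$data)),
       count = res$count)
}

#' Select the component nearest the A-B segment
#'
#' For each labelled component, the mean over its voxels of the Euclidean
#' distance (world mm) from the voxel centre to the closed segment A-B is
#' computed; the component with the smallest mean distance is selected. Ties
#' are broken by larger voxel count, then smaller label.
#'
#' @param labeled result of [label_components()].
#' @param grid the grid the labels live on (`image_volume` or `seg_mask`).
#' @param points a [control_points()] set.
#' @param voi optional [build_voi()] result; when supplied, each component is
#'   checked for contact with the curved VOI wall (radial distance within one
#'   max-spacing of the radius), a hint that the segmentation may have leaked
#'   out of the bony canal.
#' @return `list(mask = seg_mask of the selected component,
#'   reports = data.frame(label, voxel_count, mean_line_distance, selected,
#'   touches_voi_wall))`.
#' @export
select_component <- function(labeled, grid, points, voi = NULL) {
  K <- labeled$count
  if (K < 1L)
    stop("no candidate region; check threshold and control points")
  A <- points$A; B <- points$B
  ab <- B - A
  lab2 <- sum(ab^2)
  idx_by_label <- split(which(labeled$labels > 0L),
                        labeled$labels[labeled$labels > 0L])
  report <- data.frame(label = integer(K), voxel_count = integer(K),
                       mean_line_distance = numeric(K), selected = FALSE,
                       touches_voi_wall = FALSE)
  for (k in seq_len(K)) {
    idx <- idx_by_label[[as.character(k)]]
    xyz <- voxel_centers(grid, idx)
    w <- sweep(xyz, 2, A)
    t <- pmin(pmax(as.numeric(w %*% ab) / lab2, 0), 1)
    dvec <- w - outer(t, ab)
    dist <- sqrt(rowSums(dvec^2))
    report$label[k] <- k
    report$voxel_count[k] <- length(idx)
    report$mean_line_distance[k] <- mean(dist)
    if (!is.null(voi)) {
      u <- ab / sqrt(lab2)
      proj <- as.numeric(w %*% u)
      radial <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
      report$touches_voi_wall[k] <-
        any(radial >= voi$diameter / 2 - max(grid$spacing))
    }
  }
  ord <- order(report$mean_line_distance, -report$voxel_count, report$label)
  sel <- report$label[ord[1L]]
  report$selected <- report$label == sel
  mask <- seg_mask(labeled$labels == sel, grid = grid)
  list(mask = mask, reports = report)
}

#' Segment the external ear canal
#'
#' The full pipeline: build the truncated cylindrical VOI from the four
#' control points, rasterise it, smooth the volume (restricted to the VOI
#' bounding box plus a 4-sigma margin, which reproduces full-volume smoothing
#' inside the VOI to numerical precision), threshold inside the VOI, label
#' 6-connected components, and keep the component nearest the A-B segment.
#'
#' @param volume an [image_volume()].
#' @param points a [control_points()] set.
#' @param params a [seg_params()]; `NULL` fields are resolved to defaults.
#' @return object of class `eec_segmentation`:
#'   `list(mask, reports, voi, params)` where `params` carries the resolved
#'   sigma and threshold. A warning is emitted when the selected component
#'   touches the curved VOI wall.
#' @export
segment_eec <- function(volume, points, params = seg_params()) {
  voi <- build_voi(points, params$voi_diameter)
  voi_mask <- rasterize_voi(voi, volume)
  sigma <- params$sigma %||% mean(volume$spacing)
  # crop to the VOI bounding box + margin: smoothing is local, so values
  # inside the VOI are unaffected by the crop
  margin <- ceiling(4 * sigma / volume$spacing) + 1L
  box <- mask_bbox(voi_mask, margin)
  vol_c <- crop_volume(volume, box)
  voi_c <- crop_volume(voi_mask, box)
  smoothed <- smooth_volume(vol_c, sigma)
  threshold <- params$threshold %||% default_threshold(smoothed, voi_c)
  rp <- params
  rp$sigma <- sigma
  rp$threshold <- threshold
  thr_mask <- threshold_in_voi(smoothed, voi_c, rp)
  labeled <- label_components(thr_mask)
  sel <- select_component(labeled, thr_mask, points, voi = voi)
  mask <- uncrop_mask(sel$mask, box, volume)
  if (sel$reports$touches_voi_wall[sel$reports$selected])
    warning("selected component touches the VOI wall; ",
            "the segmentation may extend beyond the bony canal")
  structure(list(mask = mask, reports = sel$reports, voi = voi, params = rp),
            class = "eec_segmentation")
}

#' @export
print.eec_segmentation <- function(x, ...) {
  cat(sprintf(
    "<eec_segmentation> %d voxels (%.4g mm^3), threshold %.4g, sigma %.3g mm\n",
    sum(x$mask$data), sum(x$mask$data) * prod(x$mask$spacing),
    x$params$threshold, x$params$sigma))
  cat(sprintf("  %d candidate component(s); selected label %d\n",
              nrow(x$reports), x$reports$label[x$reports$selected]))
  invisible(x)
}

# Bounding box (list lo, hi of 1-based index triples) of a mask, expanded by
# `margin` voxels per axis and clipped to the grid.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("mask is empty")
  ijk <- arrayInd(idx, dim(mask$data))
  lo <- pmax(apply(ijk, 2, min) - margin, 1L)
  hi <- pmin(apply(ijk, 2, max) + margin, dim(mask$data))
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_volume <- function(vol, box) {
  data <- vol$data[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                   box$lo[3]:box$hi[3], drop = FALSE]
  origin <- as.numeric(vol$origin +
                         vol$direction %*% (vol$spacing * (box$lo - 1L)))
  if (inherits(vol, "seg_mask"))
    seg_mask(data, spacing = vol$spacing, origin = origin,
             direction = vol$direction)
  else
    image_volume(data, spacing = vol$spacing, origin = origin,
                 direction = vol$direction)
}

uncrop_mask <- function(mask, box, full_grid) {
  out <- array(FALSE, dim = dim(full_grid$data))
  out[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    mask$data
  seg_mask(out, grid = full_grid)
}
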