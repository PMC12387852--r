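#' Hollow a segmentation to a shell of given wall thickness
#'
#' Keeps the mask voxels whose Euclidean distance (world mm, anisotropy-
#' aware) to the centre of the nearest background voxel is at most `wall`.
#' The comparison is inclusive, which on voxel-aligned grids makes the
#' base-trimming arithmetic of [trim_bases()] exact.
#'
#' @param mask a non-empty [seg_mask()].
#' @param wall wall thickness in mm (> 0).
#' @return a [seg_mask()] shell, a subset of `mask`. A warning is emitted if
#'   the shell swallows the whole mask (wall thicker than half the lumen).
#' @export
hollow <- function(mask, wall) {
  if (!any(mask$data)) stop("mask is empty")
  if (!is.finite(wall) || wall <= 0) stop("'wall' must be > 0")
  bg <- seg_mask(!mask$data, grid = mask)
  d <- distance_transform(bg)
  shell <- mask$data & (d <= wall + 1e-9)
  if (all(shell == mask$data))
    warning("wall thickness exceeds half the lumen; shell equals the mask")
  seg_mask(shell, grid = mask)
}

#' Trim the base faces of a hollowed shell
#'
#' Removes shell voxels whose absolute distance to either cut plane is at
#' most `wall`, leaving only the cylindrical side walls. On a straight tube
#' with voxel-aligned planes this shortens the implant by exactly
#' `2 * wall` relative to the segmentation.
#'
#' @param shell a non-empty [seg_mask()] (typically from [hollow()]).
#' @param voi the [build_voi()] definition whose planes bound the shell.
#' @param wall trim depth in mm (the wall thickness).
#' @return a [seg_mask()].
#' @export
trim_bases <- function(shell, voi, wall) {
  idx <- mask_indices(shell)
  if (length(idx) == 0L) stop("shell is empty")
  xyz <- voxel_centers(shell, idx)
  keep <- rep(TRUE, length(idx))
  for (side in c("lateral_plane", "medial_plane")) {
    pl <- voi[[side]]
    d <- abs(as.numeric(sweep(xyz, 2, pl$point) %*% pl$normal))
    keep <- keep & d > wall + 1e-9
  }
  if (!any(keep))
    stop("implant vanished; wall too thick or segment too short")
  out <- array(FALSE, dim = dim(shell$data))
  out[idx[keep]] <- TRUE
  seg_mask(out, grid = shell)
}

#' Build the implant label map (and optionally its mesh) from a segmentation
#'
#' Composition of [hollow()] and [trim_bases()]; with `export_mesh = TRUE`
#' the implant surface is extracted ready for [write_stl()].
#'
#' @param mask the canal segmentation, a [seg_mask()].
#' @param voi the [build_voi()] definition used for the segmentation.
#' @param wall_thickness wall thickness in mm (default 0.5, giving the
#'   conventional 1 mm total length reduction).
#' @param export_mesh also extract the implant surface mesh.
#' @return object of class `implant`: `list(label_map, mesh or NULL,
#'   wall_thickness)`. The label map is always a subset of `mask`.
#' @export
make_implant <- function(mask, voi, wall_thickness = 0.5, export_mesh = FALSE) {
  shell <- hollow(mask, wall_thickness)
  trimmed <- trim_bases(shell, voi, wall_thickness)
  mesh <- if (export_mesh) extract_surface(trimmed) else NULL
  structure(list(label_map = trimmed, mesh = mesh,
                 wall_thickness = wall_thickness),
            class = "implant")
}

#' @export
print.implant <- function(x, ...) {
  cat(sprintf("<implant> wall %.3g mm, %d voxels (%.4g mm^3)%s\n",
              x$wall_thickness, sum(x$label_map$data),
              sum(x$label_map$data) * prod(x$label_map$spacing),
              if (is.null(x$mesh)) "" else
                sprintf(", mesh with %d faces", nrow(x$mesh$faces))))
  invisible(x)
}

#' Extent of a mask along a direction
#'
#' Span of the voxel centres projected on the (normalised) direction, plus
#' one voxel step along that direction — so an axis-aligned solid of `n`
#' voxels along the axis has extent `n * spacing` exactly.
#'
#' @param mask a non-empty [seg_mask()].
#' @param direction length-3 world-mm direction (normalised internally).
#' @return extent in mm.
#' @export
mask_extent <- function(mask, direction) {
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty")
  u <- direction / sqrt(sum(direction^2))
  proj <- voxel_centers(mask, idx) %*% u
  step <- sum(abs(as.numeric(t(mask$direction) %*% u)) * mask$spacing *
                abs(as.numeric(t(mask$direction) %*% u)))
  max(proj) - min(proj) + step
}
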