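#' Synthetic temporal-bone phantom specification
#'
#' Describes a block of bone traversed by an air-filled tubular canal that
#' opens laterally into free air and is closed medially by a thin
#' soft-tissue membrane (the tympanic-membrane analogue), with an air-filled
#' middle-ear-like cavity beyond the membrane. The canal centreline is a
#' straight line or a circular arc (constant `curvature`, in the x-z world
#' plane) and the lumen radius tapers linearly from the lateral to the
#' medial end. Intensities default to CT-like Hounsfield values (air -1000,
#' soft tissue 40, bone 1500); additive Gaussian noise is seeded and
#' reproducible.
#'
#' @param canal_radius_lateral,canal_radius_medial lumen radii, mm.
#' @param canal_length centreline arc length, mm.
#' @param curvature centreline curvature in 1/mm (0 = straight).
#' @param bone_intensity,air_intensity,tissue_intensity intensity values.
#' @param membrane_thickness membrane thickness along the centreline, mm.
#' @param middle_ear_radius radius of the air cavity beyond the membrane, mm.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param spacing isotropic voxel spacing, mm (default 0.25).
#' @param seed RNG seed for the noise field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(canal_radius_lateral = 3, canal_radius_medial = 3,
                         canal_length = 12, curvature = 0,
                         bone_intensity = 1500, air_intensity = -1000,
                         tissue_intensity = 40, membrane_thickness = 0.3,
                         middle_ear_radius = 4, noise_sd = 0,
                         spacing = 0.25, seed = 1L) {
  if (canal_radius_lateral <= 0 || canal_radius_medial <= 0)
    stop("canal radii must be > 0")
  if (canal_length <= 0) stop("'canal_length' must be > 0")
  if (curvature < 0) stop("'curvature' must be >= 0")
  if (spacing <= 0) stop("'spacing' must be > 0")
  if (!(bone_intensity > tissue_intensity && tissue_intensity > air_intensity))
    stop("intensities must satisfy bone > tissue > air")
  structure(as.list(environment()), class = "phantom_spec")
}

# Centreline of the canal: arc length s -> position and tangent.
# Straight: along +z from the world origin. Curved: circular arc of radius
# 1/curvature in the x-z plane, starting at the origin tangent to +z.
phantom_centerline <- function(spec) {
  if (spec$curvature == 0) {
    list(point = function(s) cbind(0 * s, 0 * s, s),
         tangent = function(s) cbind(0 * s, 0 * s, 1 + 0 * s))
  } else {
    R <- 1 / spec$curvature
    list(point = function(s) cbind(R * (1 - cos(s / R)), 0 * s, R * sin(s / R)),
         tangent = function(s) cbind(sin(s / R), 0 * s, cos(s / R)))
  }
}

# Arc parameter of the (extended) centreline closest to each point, plus the
# perpendicular distance to the centreline at that parameter.
phantom_arc_coords <- function(spec, xyz) {
  if (spec$curvature == 0) {
    s <- xyz[, 3]
    dperp <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  } else {
    R <- 1 / spec$curvature
    ux <- xyz[, 1] - R
    uz <- xyz[, 3]
    phi <- atan2(uz, -ux) # 0 at s = 0, increases with s
    s <- R * phi
    rin <- sqrt(ux^2 + uz^2)
    dperp <- sqrt((rin - R)^2 + xyz[, 2]^2)
  }
  list(s = s, dperp = dperp)
}

#' Generate a synthetic temporal-bone phantom
#'
#' Returns the volume together with the analytic ground truth: the lumen
#' mask between the suggested cut planes, suggested control points (A and B
#' on the centreline at the canal ends, C 5 mm lateral of A and D 5 mm
#' medial of B along the local tangents), a suggested threshold (midway
#' between air and bone), and the analytic lumen volume and length.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle`: `list(volume, truth_mask,
#'   suggested_points, suggested_threshold, analytic_volume, analytic_length,
#'   spec)`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  build_phantom(spec, decoy_offset = NULL)
}

#' Generate a phantom with a decoy cavity
#'
#' Adds a second, disconnected air cavity running parallel to the canal at
#' `decoy_offset` mm (offset along +y), fully enclosed in bone. Used to
#' exercise the component-selection rule: the cavity nearer the A-B segment
#' wins.
#'
#' @param spec a [phantom_spec()].
#' @param decoy_offset centre-to-centre offset in mm; must exceed twice the
#'   largest canal radius so the cavities cannot intersect.
#' @return a `phantom_bundle` with an extra `decoy_mask` element.
#' @export
generate_two_cavity_phantom <- function(spec = phantom_spec(), decoy_offset = 8) {
  rmax <- max(spec$canal_radius_lateral, spec$canal_radius_medial)
  if (decoy_offset <= 2 * rmax)
    stop("'decoy_offset' must exceed twice the largest canal radius (",
         2 * rmax, " mm); cavities would intersect")
  build_phantom(spec, decoy_offset = decoy_offset)
}

build_phantom <- function(spec, decoy_offset = NULL) {
  cl <- phantom_centerline(spec)
  L <- spec$canal_length
  mt <- spec$membrane_thickness
  me_r <- spec$middle_ear_radius
  rmax <- max(spec$canal_radius_lateral, spec$canal_radius_medial)
  # world-space bounding box of all structures + bone margin
  s_samp <- seq(0, L + mt + 2 * me_r, length.out = 200)
  pts <- cl$point(s_samp)
  margin <- rmax + 4
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  lo[3] <- -2 - spec$spacing # lateral free-air region
  if (!is.null(decoy_offset)) hi[2] <- hi[2] + decoy_offset
  # snap the grid so that voxel boundaries fall on integer world coordinates:
  # centres at (k + 1/2) * spacing, so the suggested planes (through lattice
  # points) never slice voxel centres
  lo <- floor(lo / spec$spacing) * spec$spacing + spec$spacing / 2
  dims <- unname(pmax(ceiling((hi - lo) / spec$spacing), 1))
  vol <- image_volume(array(spec$bone_intensity, dim = dims),
                      spacing = rep(spec$spacing, 3), origin = lo)
  xyz <- voxel_centers(vol)
  arc <- phantom_arc_coords(spec, xyz)
  taper <- function(s) spec$canal_radius_lateral +
    (spec$canal_radius_medial - spec$canal_radius_lateral) * pmin(pmax(s / L, 0), 1)
  A <- as.numeric(cl$point(0))
  B <- as.numeric(cl$point(L))
  tA <- as.numeric(cl$tangent(0))
  tB <- as.numeric(cl$tangent(L))
  plane_lat <- as.numeric(sweep(xyz, 2, A) %*% tA)  # >= 0 inside
  plane_med <- as.numeric(sweep(xyz, 2, B) %*% tB)  # <= 0 inside
  lumen <- arc$s >= 0 & arc$s <= L & arc$dperp <= taper(arc$s)
  membrane <- arc$s > L & arc$s <= L + mt & arc$dperp <= taper(L)
  me_center <- as.numeric(cl$point(L + mt)) + tB * me_r
  cavity <- sqrt(rowSums(sweep(xyz, 2, me_center)^2)) <= me_r
  lateral_air <- plane_lat < 0
  data <- vol$data
  data[lateral_air] <- spec$air_intensity
  data[lumen] <- spec$air_intensity
  data[membrane] <- spec$tissue_intensity
  data[cavity & !membrane] <- spec$air_intensity
  decoy <- NULL
  if (!is.null(decoy_offset)) {
    xyz_d <- xyz
    xyz_d[, 2] <- xyz_d[, 2] - decoy_offset
    arc_d <- phantom_arc_coords(spec, xyz_d)
    decoy <- arc_d$s >= 0 & arc_d$s <= L & arc_d$dperp <= taper(arc_d$s)
    if (any(decoy & (lumen | membrane | cavity | lateral_air)))
      stop("decoy cavity intersects another structure")
    data[decoy] <- spec$air_intensity
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    data <- data + rnorm(length(data), sd = spec$noise_sd)
  }
  vol$data <- array(data, dim = dims)
  truth <- lumen & plane_lat >= 0 & plane_med <= 0
  points <- control_points(A, B, C = A - 5 * tA, D = B + 5 * tB)
  r1 <- spec$canal_radius_lateral; r2 <- spec$canal_radius_medial
  bundle <- list(
    volume = vol,
    truth_mask = seg_mask(array(truth, dim = dims), grid = vol),
    suggested_points = points,
    suggested_threshold = (spec$air_intensity + spec$bone_intensity) / 2,
    analytic_volume = pi * L * (r1^2 + r1 * r2 + r2^2) / 3,
    analytic_length = L,
    spec = spec)
  if (!is.null(decoy))
    bundle$decoy_mask <- seg_mask(array(decoy, dim = dims), grid = vol)
  if (!any(truth)) stop("canal does not fit in the volume")
  structure(bundle, class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf(
    "<phantom_bundle> %s voxels at %g mm, canal length %g mm, truth %.4g mm^3\n",
    paste(dim(x$volume$data), collapse = "x"), x$spec$spacing,
    x$analytic_length, sum(x$truth_mask$data) * prod(x$truth_mask$spacing)))
  invisible(x)
}
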