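#' Run the full segmentation-to-implant pipeline
#'
#' Executes segment -> measure -> implant (-> optional comparison against a
#' reference mask), writing all artifacts to an output directory:
#' `mask.nii.gz` (EEC segmentation), `implant.nii.gz` (implant label map),
#' `implant.stl`, and `report.json` carrying the measurements, the
#' per-component selection report, the comparison metrics (when a reference
#' is given), and the fully resolved parameter set for provenance.
#' Identical configurations reproduce identical label maps byte-for-byte.
#'
#' @param config a named list (or path to a YAML file with flat keys):
#'   \describe{
#'     \item{volume}{path to the input volume (NIfTI/NRRD/DICOM dir). Required.}
#'     \item{points}{path to the control-point JSON. Required.}
#'     \item{out_dir}{output directory (created if missing). Required.}
#'     \item{threshold, sigma_mm, diameter_mm, target, lower_bound}{segmentation
#'       parameters; defaults as in [seg_params()].}
#'     \item{wall_mm}{implant wall thickness, default 0.5.}
#'     \item{reference_mask}{optional path to a ground-truth label map; when
#'       set, Dice and HD95 against the segmentation are reported.}
#'   }
#' @return invisibly, a list with the segmentation, measurement report,
#'   implant, metrics (or NULL), and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (key in c("volume", "points", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing required key '", key, "'")
  if (!file.exists(config$volume) && !dir.exists(config$volume))
    stop("volume path does not exist: ", config$volume)
  if (!file.exists(config$points))
    stop("points path does not exist: ", config$points)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  volume <- read_volume(config$volume)
  points <- read_control_points(config$points)
  params <- seg_params(sigma = config$sigma_mm,
                       threshold = config$threshold,
                       target = config$target %||% "air",
                       lower_bound = config$lower_bound %||% -200,
                       voi_diameter = config$diameter_mm %||% 20)
  seg <- segment_eec(volume, points, params)
  measurement <- measure_canal(seg$mask, seg$voi)
  wall <- config$wall_mm %||% 0.5
  implant <- make_implant(seg$mask, seg$voi, wall_thickness = wall,
                          export_mesh = TRUE)

  metrics <- NULL
  if (!is.null(config$reference_mask)) {
    ref_vol <- read_volume(config$reference_mask)
    ref <- seg_mask(ref_vol$data != 0, grid = ref_vol)
    metrics <- list(dice = dice(seg$mask, ref), hd95 = hd95(seg$mask, ref))
  }

  paths <- list(mask = file.path(config$out_dir, "mask.nii.gz"),
                implant = file.path(config$out_dir, "implant.nii.gz"),
                stl = file.path(config$out_dir, "implant.stl"),
                report = file.path(config$out_dir, "report.json"))
  write_volume(seg$mask, paths$mask)
  write_volume(implant$label_map, paths$implant)
  write_stl(implant$mesh, paths$stl)

  report <- list(
    measurements = measurement[c("volume", "length", "width", "height")],
    anchors = measurement[c("lateral_center", "medial_center", "midpoint",
                            "width_direction")],
    components = seg$reports,
    metrics = metrics,
    parameters = list(threshold = seg$params$threshold,
                      sigma_mm = seg$params$sigma,
                      target = seg$params$target,
                      lower_bound = seg$params$lower_bound,
                      diameter_mm = seg$params$voi_diameter,
                      wall_mm = wall,
                      volume = config$volume, points = config$points))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(segmentation = seg, measurement = measurement,
                 implant = implant, metrics = metrics, paths = paths))
}

#' Write phantom artifacts to a directory
#'
#' Convenience used by the command-line tool: writes `volume.nii.gz`,
#' `truth.nii.gz`, and `points.json` for a phantom preset.
#'
#' @param preset `"straight"`, `"curved"` (curvature 0.03/mm), or
#'   `"two-cavity"` (decoy 8 mm from the canal).
#' @param out_dir output directory.
#' @param spacing voxel spacing in mm.
#' @param noise_sd additive noise standard deviation.
#' @param seed RNG seed.
#' @return invisibly, the `phantom_bundle`.
#' @export
write_phantom <- function(preset = c("straight", "curved", "two-cavity"),
                          out_dir, spacing = 0.25, noise_sd = 0, seed = 1L) {
  preset <- match.arg(preset)
  spec <- phantom_spec(spacing = spacing, noise_sd = noise_sd, seed = seed,
                       curvature = if (preset == "curved") 0.03 else 0)
  bundle <- if (preset == "two-cavity")
    generate_two_cavity_phantom(spec, decoy_offset = 8)
  else generate_phantom(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$volume, file.path(out_dir, "volume.nii.gz"))
  write_volume(bundle$truth_mask, file.path(out_dir, "truth.nii.gz"))
  write_control_points(bundle$suggested_points,
                       file.path(out_dir, "points.json"))
  invisible(bundle)
}
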