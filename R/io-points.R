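#' The four anatomical control points
#'
#' Landmarks anchoring the truncated cylindrical VOI, in world mm (LPS).
#' A sits at the lateral (outer) end of the canal and B at the medial (inner)
#' end near the tympanic membrane; C lies lateral to A and D medial to B, and
#' the directions A->C and B->D define the outward normals of the two cut
#' planes.
#'
#' @param A,B,C,D length-3 numeric vectors, world mm (LPS).
#' @return object of class `control_points`.
#' @export
control_points <- function(A, B, C, D) {
  pts <- list(A = as.numeric(A), B = as.numeric(B),
              C = as.numeric(C), D = as.numeric(D))
  for (nm in names(pts)) {
    if (length(pts[[nm]]) != 3L || any(!is.finite(pts[[nm]])))
      stop("control point ", nm, " must be 3 finite numbers")
  }
  if (all(pts$A == pts$B)) stop("control points A and B must differ")
  if (all(pts$C == pts$A)) stop("control points C and A must differ")
  if (all(pts$D == pts$B)) stop("control points D and B must differ")
  structure(pts, class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  cat("<control_points> (LPS mm)\n")
  for (nm in c("A", "B", "C", "D"))
    cat(sprintf("  %s: (%s)\n", nm, paste(signif(x[[nm]], 6), collapse = ", ")))
  invisible(x)
}

#' Read control points from JSON
#'
#' Two dialects are supported. `plain_json` is a top-level object with keys
#' `"A"`–`"D"` holding 3-number arrays and an optional `"frame"` of `"LPS"`
#' (default) or `"RAS"`. `slicer_markups` is the 3D Slicer fiducial format
#' (`.mrk.json`); fiducial labels must map to A–D (case-insensitive, an
#' optional list prefix such as `"F-"` is ignored) and the file's declared
#' `coordinateSystem` (RAS unless stated) is converted to LPS.
#'
#' @param path JSON file.
#' @param dialect `"auto"` (default; `.mrk.json` or a `markups` key selects
#'   the Slicer dialect), `"plain_json"`, or `"slicer_markups"`.
#' @return a [control_points()] set in LPS mm.
#' @export
read_control_points <- function(path,
                                dialect = c("auto", "plain_json", "slicer_markups")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mrk\\.json$", path) || !is.null(doc$markups))
      "slicer_markups" else "plain_json"
  if (dialect == "plain_json") parse_plain_points(doc) else parse_slicer_points(doc)
}

parse_plain_points <- function(doc) {
  found <- intersect(c("A", "B", "C", "D"), names(doc))
  missing <- setdiff(c("A", "B", "C", "D"), found)
  if (length(missing) > 0L)
    stop("missing control point ", paste(missing, collapse = ", "),
         " (found: ", paste(found, collapse = ", "), ")")
  frame <- toupper(doc$frame %||% "LPS")
  pts <- lapply(doc[c("A", "B", "C", "D")], function(v) as.numeric(unlist(v)))
  if (frame == "RAS") pts <- lapply(pts, ras_lps)
  else if (frame != "LPS") stop("unknown frame: ", frame)
  control_points(pts$A, pts$B, pts$C, pts$D)
}

parse_slicer_points <- function(doc) {
  if (is.null(doc$markups)) stop("not a Slicer markups file: no 'markups' key")
  pts <- list()
  frames <- list()
  for (mk in doc$markups) {
    frame <- toupper(mk$coordinateSystem %||% "RAS")
    for (cp in mk$controlPoints) {
      label <- toupper(trimws(sub("^.*[-_ ]", "", cp$label %||% "")))
      if (label %in% c("A", "B", "C", "D")) {
        pts[[label]] <- as.numeric(unlist(cp$position))
        frames[[label]] <- frame
      }
    }
  }
  missing <- setdiff(c("A", "B", "C", "D"), names(pts))
  if (length(missing) > 0L)
    stop("missing control point ", paste(missing, collapse = ", "),
         " (found labels: ", paste(names(pts), collapse = ", "), ")")
  for (nm in names(pts))
    if (frames[[nm]] == "RAS") pts[[nm]] <- ras_lps(pts[[nm]])
  control_points(pts$A, pts$B, pts$C, pts$D)
}

#' Write control points as plain JSON
#'
#' @param points a [control_points()] set (internally LPS).
#' @param path output file.
#' @param frame `"LPS"` (default) or `"RAS"`; the file declares its frame.
#' @return `path`, invisibly.
#' @export
write_control_points <- function(points, path, frame = c("LPS", "RAS")) {
  frame <- match.arg(frame)
  pts <- points[c("A", "B", "C", "D")]
  if (frame == "RAS") pts <- lapply(pts, ras_lps)
  doc <- c(pts, list(frame = frame))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
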