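#' Read a 3D scalar volume
#'
#' Reads NIfTI, NRRD, or a DICOM series directory into an [image_volume()].
#' World coordinates are normalised to the internal LPS convention: NIfTI
#' affines (RAS) are sign-flipped on x and y; NRRD respects its declared
#' `space` field; DICOM is LPS natively. Integer voxel values are preserved
#' losslessly.
#'
#' @param path file (NIfTI/NRRD) or directory (DICOM series).
#' @param format one of `"nifti"`, `"nrrd"`, `"dicom_dir"`; the default
#'   `"auto"` guesses from the path (directory -> DICOM, extension otherwise).
#' @return an `image_volume` (world frame LPS).
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
    else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
    else "nifti"
  }
  if (format != "dicom_dir" && !file.exists(path))
    stop("file does not exist: ", path)
  switch(format,
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         dicom_dir = read_dicom_series(path))
}

#' Write a volume or label map
#'
#' @param vol an `image_volume` or `seg_mask`.
#' @param path output path; extension selects the format unless `format`
#'   is given (`.nii`/`.nii.gz` -> NIfTI, `.nrrd` -> NRRD).
#' @param format `"auto"`, `"nifti"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (format == "nifti") write_nifti_volume(vol, path) else write_nrrd_volume(vol, path)
  invisible(path)
}

## ---- NIfTI (RNifti; RAS native) ------------------------------------------

lps_affine <- function(vol) {
  rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file '",
                                           path, "': ", conditionMessage(e)))
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop("NIfTI volume is not 3D (field 'dim' = ",
         paste(dim(img), collapse = "x"), ")")
  aff <- RNifti::xform(img) # RAS affine
  M <- aff[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("NIfTI affine has zero-length column (field 'srow')")
  dir_ras <- M %*% diag(1 / spacing)
  flip <- diag(c(-1, -1, 1))
  image_volume(a, spacing = spacing,
               origin = as.numeric(flip %*% aff[1:3, 4]),
               direction = flip %*% dir_ras)
}

write_nifti_volume <- function(vol, path) {
  flip <- diag(c(-1, -1, 1))
  aff <- lps_affine(vol)
  aff[1:3, ] <- flip %*% aff[1:3, ]
  data <- vol$data
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::`qform<-`(img, structure(aff, code = 1L))
  img <- RNifti::asNifti(img)
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- NRRD (raw little-endian encoding) -----------------------------------

# Minimal NRRD reader: detached headers, block types and non-raw encodings
# are not supported. 'space' must be a recognised 3D anatomical frame.
read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file (bad magic): ", path)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header not terminated by blank line")
    if (line == "") break
    if (!grepl("^#", line)) header <- c(header, line)
  }
  fields <- list()
  for (line in header) {
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing field '", f, "'")
    fields[[f]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("NRRD field 'dimension' must be 3")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- tolower(need("encoding"))
  if (!enc %in% c("raw")) stop("NRRD field 'encoding' unsupported: ", enc)
  endian <- tolower(fields[["endian"]] %||% "little")
  space <- tolower(fields[["space"]] %||% "left-posterior-superior")
  sgn <- switch(space,
                "left-posterior-superior" = , "lps" = c(1, 1, 1),
                "right-anterior-superior" = , "ras" = c(-1, -1, 1),
                stop("NRRD field 'space' unsupported: ", space))
  vecs <- parse_nrrd_vectors(need("space directions"))
  origin <- parse_nrrd_vector(fields[["space origin"]] %||% "(0,0,0)")
  M <- sgn * do.call(cbind, vecs) # to LPS
  origin <- sgn * origin
  spacing <- sqrt(colSums(M^2))
  direction <- M %*% diag(1 / spacing)
  rtype <- switch(type,
                  "signed char" = , "int8" = list(what = integer(), size = 1L, signed = TRUE),
                  "uchar" = , "unsigned char" = , "uint8" = list(what = integer(), size = 1L, signed = FALSE),
                  "short" = , "signed short" = , "int16" = list(what = integer(), size = 2L, signed = TRUE),
                  "ushort" = , "unsigned short" = , "uint16" = list(what = integer(), size = 2L, signed = FALSE),
                  "int" = , "signed int" = , "int32" = list(what = integer(), size = 4L, signed = TRUE),
                  "float" = list(what = numeric(), size = 4L, signed = TRUE),
                  "double" = list(what = numeric(), size = 8L, signed = TRUE),
                  stop("NRRD field 'type' unsupported: ", type))
  n <- prod(sizes)
  vals <- readBin(con, rtype$what, n = n, size = rtype$size,
                  signed = rtype$signed, endian = endian)
  if (length(vals) != n) stop("NRRD data truncated: expected ", n,
                              " values, got ", length(vals))
  image_volume(array(vals, dim = sizes), spacing = spacing,
               origin = origin, direction = direction)
}

parse_nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", trimws(s)), ",")[[1]])
}

parse_nrrd_vectors <- function(s) {
  toks <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  if (length(toks) != 3L) stop("NRRD field 'space directions' must have 3 vectors")
  lapply(toks, parse_nrrd_vector)
}

write_nrrd_volume <- function(vol, path) {
  data <- vol$data
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  is_int <- is.integer(data) ||
    (all(is.finite(data)) && all(data == round(data)) &&
       max(abs(data)) < .Machine$integer.max)
  type <- if (is_int) "int" else "double"
  M <- vol$direction %*% diag(vol$spacing)
  vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  header <- c(
    "NRRD0004",
    "# generated by canalseg",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(data)[1], dim(data)[2], dim(data)[3]),
    "space: left-posterior-superior",
    sprintf("space directions: %s %s %s", vec(M[, 1]), vec(M[, 2]), vec(M[, 3])),
    sprintf("space origin: %s", vec(vol$origin)),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (is_int) {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
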