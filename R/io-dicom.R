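# Minimal DICOM series reader: single-frame grayscale CT-like slices,
# explicit or implicit VR little endian, uncompressed PixelData. Enough to
# ingest the scanner exports this pipeline targets; not a general toolkit.

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(read_dicom_slice(f), error = function(e) NULL)
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (length(slices) == 0L) stop("no readable DICOM slices in ", dir)
  rows <- unique(vapply(slices, `[[`, 0L, "rows"))
  cols <- unique(vapply(slices, `[[`, 0L, "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("DICOM series has inconsistent Rows/Columns across slices")
  iop <- slices[[1L]]$iop
  for (s in slices)
    if (max(abs(s$iop - iop)) > 1e-4)
      stop("DICOM series has inconsistent ImageOrientationPatient")
  col_dir <- iop[1:3] # direction of increasing column index
  row_dir <- iop[4:6] # direction of increasing row index
  normal <- c(col_dir[2] * row_dir[3] - col_dir[3] * row_dir[2],
              col_dir[3] * row_dir[1] - col_dir[1] * row_dir[3],
              col_dir[1] * row_dir[2] - col_dir[2] * row_dir[1])
  pos <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(pos)
    if (any(dz <= 0)) stop("DICOM series has duplicate slice positions")
    if (max(dz) - min(dz) > 1e-3)
      stop("DICOM series has inconsistent slice spacing: ",
           paste(signif(range(dz), 6), collapse = " vs "))
    slice_spacing <- mean(dz)
  } else {
    slice_spacing <- slices[[1L]]$slice_thickness %||% 1
  }
  ps <- slices[[1L]]$pixel_spacing # (between rows, between columns)
  for (s in slices)
    if (max(abs(s$pixel_spacing - ps)) > 1e-6)
      stop("DICOM series has inconsistent PixelSpacing")
  data <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    # PixelData is row-major (column index fastest) -> matrix [col, row]
    data[, , k] <- matrix(s$pixels * s$slope + s$intercept, nrow = cols)
  }
  if (all(data == round(data))) data <- array(as.integer(data), dim = dim(data))
  image_volume(data,
               spacing = c(ps[2], ps[1], slice_spacing),
               origin = slices[[1L]]$ipp,
               direction = cbind(col_dir, row_dir, normal))
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file")
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2L,
                               signed = FALSE, endian = "little")
  # 32-bit lengths; values >= 2^31 (only the undefined-length sentinel in
  # practice) wrap to negative and are handled explicitly
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4L,
                               endian = "little")
  # file meta group is always explicit VR little endian
  pos <- 132L
  transfer <- "1.2.840.10008.1.2.1"
  meta_end <- NA_integer_
  repeat {
    if (!is.na(meta_end) && pos >= meta_end) break
    group <- u16(pos); elem <- u16(pos + 2L)
    if (is.na(meta_end) && group != 0x0002L) break
    vr <- rawToChar(raw[pos + 5:6])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    body <- pos + hdr
    if (group == 0x0002L && elem == 0x0000L) meta_end <- body + len + u32(body)
    if (group == 0x0002L && elem == 0x0010L) {
      b <- raw[body + seq_len(len)]
      transfer <- rawToChar(b[b != as.raw(0)])
    }
    pos <- body + len
  }
  explicit <- transfer != "1.2.840.10008.1.2"
  if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax: ", transfer)
  tags <- list()
  n <- length(raw)
  while (pos + 8L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (is.na(len) || len < 0L) # undefined length (0xFFFFFFFF)
      stop("undefined-length DICOM element (", sprintf("%04x,%04x", group, elem),
           ") not supported")
    body <- pos + hdr
    if (body + len > n) stop("truncated DICOM element")
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% c("00200032", "00200037", "00280010", "00280011", "00280030",
                   "00280100", "00280103", "00281052", "00281053", "00180050",
                   "7fe00010"))
      tags[[key]] <- list(vr = vr, bytes = raw[body + seq_len(len)])
    pos <- body + len
  }
  ds <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    b <- t$bytes[t$bytes != as.raw(0)]
    as.numeric(strsplit(trimws(rawToChar(b)), "\\\\")[[1]])
  }
  us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
  }
  rows <- us("00280010"); cols <- us("00280011")
  ipp <- ds("00200032"); iop <- ds("00200037"); psp <- ds("00280030")
  bits <- us("00280100") %||% 16L
  signed <- (us("00280103") %||% 1L) == 1L
  pix <- tags[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(ipp) || is.null(iop) ||
      is.null(psp) || is.null(pix))
    stop("DICOM slice missing required geometry/pixel tags")
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  npix <- as.integer(rows) * as.integer(cols)
  pixels <- readBin(pix$bytes, "integer", n = npix, size = bits %/% 8L,
                    signed = if (bits == 8L) signed else signed,
                    endian = "little")
  if (length(pixels) < npix) stop("PixelData shorter than Rows x Columns")
  list(rows = as.integer(rows), cols = as.integer(cols), ipp = ipp, iop = iop,
       pixel_spacing = psp,
       slope = (ds("00281053") %||% 1)[1], intercept = (ds("00281052") %||% 0)[1],
       slice_thickness = (ds("00180050") %||% NULL)[1],
       pixels = pixels)
}
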