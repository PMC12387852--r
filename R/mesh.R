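#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix, world mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh` with per-face outward normals.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0L && max(faces) > nrow(vertices))
    stop("face index exceeds vertex count")
  if (nrow(faces) > 0L && min(faces) < 1L) stop("face indices are 1-based")
  nrm <- face_normals(vertices, faces)
  area <- sqrt(rowSums(nrm^2))
  keep <- area > 1e-12
  faces <- faces[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE] / area[keep]
  structure(list(vertices = vertices, faces = faces, normals = nrm),
            class = "surface_mesh")
}

face_normals <- function(v, f) {
  if (nrow(f) == 0L) return(matrix(0, 0, 3))
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a `surface_mesh`; must be closed for the result to be a volume.
#' @return volume in mm^3 (positive for outward-oriented closed meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Number of edge-connected components of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(0L)
  parent <- seq_len(nrow(mesh$vertices))
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (col in list(f[, 1:2], f[, 2:3], f[, c(3, 1)])) {
    for (r in seq_len(nrow(col))) {
      ra <- find(col[r, 1]); rb <- find(col[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  used <- unique(as.vector(f))
  length(unique(vapply(used, find, 0L)))
}

#' Extract the surface of a binary mask as a triangle mesh
#'
#' Produces the closed, outward-oriented boundary surface of the voxel set:
#' every face between a foreground voxel and a background (or out-of-volume)
#' neighbour contributes two triangles, with vertices at voxel corners mapped
#' through the grid transform to world mm. The enclosed volume of the mesh is
#' exactly the voxel volume of the mask, and disconnected voxel components
#' yield disconnected mesh components.
#'
#' @param mask a non-empty [seg_mask()].
#' @param level isosurface level, retained for interface compatibility; the
#'   binary surface is independent of it for levels in (0,1).
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(mask, level = 0.5) {
  m <- mask$data
  if (!any(m)) stop("nothing to mesh: mask is empty")
  d <- dim(m)
  quads <- list() # each: n x 4 matrix of corner keys + axis/sign
  corner_key <- function(i, j, k) # lattice points 0..d, 1-based encode
    (i) + (d[1] + 1) * ((j) + (d[2] + 1) * (k))
  out <- vector("list", 6L)
  qi <- 0L
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- shift_array(m, ax, -sgn) # neighbour on the sgn side
      face <- m & !nb
      idx <- which(face)
      if (length(idx) == 0L) next
      ijk <- arrayInd(idx, d) - 1L # 0-based voxel index
      # corner lattice coordinates of the exposed face
      base <- ijk
      base[, ax] <- base[, ax] + (sgn + 1L) %/% 2L
      o1 <- c(2L, 1L, 1L)[ax] # in-plane axes
      o2 <- c(3L, 3L, 2L)[ax]
      c00 <- base
      c10 <- base; c10[, o1] <- c10[, o1] + 1L
      c11 <- base; c11[, o1] <- c11[, o1] + 1L; c11[, o2] <- c11[, o2] + 1L
      c01 <- base; c01[, o2] <- c01[, o2] + 1L
      k4 <- cbind(corner_key(c00[, 1], c00[, 2], c00[, 3]),
                  corner_key(c10[, 1], c10[, 2], c10[, 3]),
                  corner_key(c11[, 1], c11[, 2], c11[, 3]),
                  corner_key(c01[, 1], c01[, 2], c01[, 3]))
      qi <- qi + 1L
      out[[qi]] <- list(keys = k4, axis = ax, sgn = sgn)
    }
  }
  out <- out[seq_len(qi)]
  all_keys <- sort(unique(unlist(lapply(out, `[[`, "keys"))))
  # world coordinates of the used lattice corners
  kk <- all_keys
  ci <- kk %% (d[1] + 1)
  cj <- (kk %/% (d[1] + 1)) %% (d[2] + 1)
  ck <- kk %/% ((d[1] + 1) * (d[2] + 1))
  corner0 <- cbind(ci, cj, ck) - 0.5 # corner in 0-based voxel coords
  verts <- sweep(sweep(corner0, 2, mask$spacing, `*`) %*% t(mask$direction),
                 2, mask$origin, `+`)
  faces <- list()
  fi <- 0L
  for (q in out) {
    v4 <- matrix(match(q$keys, all_keys), ncol = 4)
    # outward world normal of this face family
    nrm <- mask$direction[, q$axis] * q$sgn
    t1 <- v4[, c(1, 2, 3), drop = FALSE]
    t2 <- v4[, c(1, 3, 4), drop = FALSE]
    # orient: computed normal of t1 must align with nrm
    p1 <- verts[t1[1, 1], ]; p2 <- verts[t1[1, 2], ]; p3 <- verts[t1[1, 3], ]
    cr <- crossprod3(p2 - p1, p3 - p1)
    if (sum(cr * nrm) < 0) {
      t1 <- t1[, c(1, 3, 2), drop = FALSE]
      t2 <- t2[, c(1, 3, 2), drop = FALSE]
    }
    fi <- fi + 1L; faces[[fi]] <- t1
    fi <- fi + 1L; faces[[fi]] <- t2
  }
  surface_mesh(verts, do.call(rbind, faces))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Write a mesh as STL
#'
#' Binary STL: 80-byte header, uint32 triangle count, then 50 bytes per
#' triangle (normal + 3 vertices as little-endian float32, 2-byte attribute),
#' so the file size is exactly 84 + 50 x faces bytes. ASCII STL follows the
#' usual `solid`/`facet` grammar.
#'
#' @param mesh a [surface_mesh()] with at least one face.
#' @param path output file.
#' @param encoding `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, encoding = c("binary", "ascii")) {
  encoding <- match.arg(encoding)
  if (nrow(mesh$faces) == 0L) stop("mesh has zero faces; nothing to write")
  v <- mesh$vertices; f <- mesh$faces; nrm <- mesh$normals
  if (encoding == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("canalseg binary STL", width = -80))
    length(header) <- 80L
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    m <- nrow(f)
    tri <- t(cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE])) # 12 x m, column per triangle
    fbytes <- writeBin(as.numeric(tri), raw(), size = 4L, endian = "little")
    rec <- rbind(matrix(fbytes, nrow = 48L), matrix(as.raw(0), 2L, m))
    writeBin(as.raw(rec), con)
  } else {
    lines <- character(2L + 7L * nrow(f))
    lines[1] <- "solid canalseg"
    li <- 1L
    for (i in seq_len(nrow(f))) {
      lines[li + 1L] <- sprintf("  facet normal %.9g %.9g %.9g",
                                nrm[i, 1], nrm[i, 2], nrm[i, 3])
      lines[li + 2L] <- "    outer loop"
      for (j in 1:3) {
        p <- v[f[i, j], ]
        lines[li + 2L + j] <- sprintf("      vertex %.9g %.9g %.9g",
                                      p[1], p[2], p[3])
      }
      lines[li + 6L] <- "    endloop"
      lines[li + 7L] <- "  endfacet"
      li <- li + 7L
    }
    lines[li + 1L] <- "endsolid canalseg"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices shared between triangles are merged exactly by coordinates.
#' @param path STL file.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  is_ascii <- length(raw) >= 5L && identical(rawToChar(raw[1:5]), "solid") &&
    !is_binary_stl(raw)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(raw)
  nv <- nrow(tri)
  key <- apply(tri, 1, function(p) paste(p, collapse = "/"))
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  surface_mesh(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

is_binary_stl <- function(raw) {
  if (length(raw) < 84L) return(FALSE)
  n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  isTRUE(length(raw) == 84 + 50 * as.numeric(n))
}

read_stl_binary <- function(raw) {
  if (length(raw) < 84L) stop("truncated binary STL")
  n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (length(raw) < 84L + 50L * n) stop("binary STL shorter than declared")
  if (n == 0L) stop("binary STL contains no triangles")
  rec <- matrix(raw[84L + seq_len(50L * n)], nrow = 50L)
  vals <- readBin(as.raw(rec[1:48, ]), "numeric", n = 12L * n, size = 4L,
                  endian = "little")
  vals <- matrix(vals, nrow = 12L) # per-triangle columns: normal + 3 vertices
  tri <- matrix(0, nrow = 3L * n, ncol = 3)
  tri[seq(1L, 3L * n, 3L), ] <- t(vals[4:6, , drop = FALSE])
  tri[seq(2L, 3L * n, 3L), ] <- t(vals[7:9, , drop = FALSE])
  tri[seq(3L, 3L * n, 3L), ] <- t(vals[10:12, , drop = FALSE])
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) == 0L || length(vx) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  vals <- lapply(strsplit(trimws(vx), "\\s+"), function(t) as.numeric(t[2:4]))
  do.call(rbind, vals)
}
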