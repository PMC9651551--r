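#' Read a surface mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected). STL stores every facet with its
#' own three vertices, so shared vertices are duplicated in the file; on read
#' they are welded: points within `weld_tolerance` are merged into a single
#' index, recovering mesh connectivity. Face winding is preserved. Coordinates
#' are taken as millimetres.
#'
#' @param path path to an STL file.
#' @param weld_tolerance points whose coordinates agree within this distance
#'   (mm) collapse to one vertex (default 1e-6).
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path, weld_tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("truncated STL '%s': only %d bytes", path, size))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  is_binary <- FALSE
  if (size >= 84) {
    nfac <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(nfac) && nfac >= 0 && size == 84 + 50 * as.numeric(nfac))
      is_binary <- TRUE
  }
  tri <- if (is_binary) {
    read_stl_binary(con, nfac, path)
  } else {
    if (!identical(rawToChar(header[1:5]), "solid"))
      stop(sprintf("'%s' is neither a valid binary STL (size mismatch at byte 84) nor ASCII ('solid' missing at byte 0)", path))
    close(con)
    on.exit()
    read_stl_ascii(path)
  }
  weld_triangles(tri, weld_tolerance)
}

read_stl_binary <- function(con, nfac, path) {
  # 50 bytes per facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  raw <- readBin(con, "raw", 50L * nfac)
  if (length(raw) != 50L * nfac)
    stop(sprintf("truncated binary STL '%s' at byte %d (expected %d facets)",
                 path, 84 + length(raw), nfac))
  m <- matrix(raw, nrow = 50L)
  vals <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", 12L * nfac,
                  size = 4L, endian = "little")
  vals <- matrix(vals, nrow = 12L)  # col = facet; rows 4:12 are the 3 vertices
  t(vals[4:12, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) %% 3L != 0L)
    stop(sprintf("ASCII STL '%s': vertex count %d is not a multiple of 3 (last vertex at line %d)",
                 path, length(vl), if (length(vl)) vl[length(vl)] else 0L))
  if (length(vl) == 0L) stop(sprintf("ASCII STL '%s' contains no vertices", path))
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(lengths(toks) != 4L)
  if (length(bad))
    stop(sprintf("malformed vertex at line %d of '%s'", vl[bad[1]], path))
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz)))
    stop(sprintf("non-numeric vertex at line %d of '%s'",
                 vl[which(!is.finite(rowSums(xyz)))[1]], path))
  matrix(t(xyz), ncol = 9L, byrow = TRUE)
}

# tri: n x 9 matrix (v1 v2 v3 per facet); weld duplicate points
weld_triangles <- function(tri, tol) {
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol),
               round(pts[, 3] / tol), sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- pts[first, , drop = FALSE]
  nfac <- nrow(tri)
  faces <- cbind(idx[seq_len(nfac)],
                 idx[nfac + seq_len(nfac)],
                 idx[2L * nfac + seq_len(nfac)])
  surface_mesh(verts, faces)
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [surface_mesh()] with at least one face.
#' @param path output path.
#' @param dialect `"binary"` (80-byte header, little-endian float32) or
#'   `"ascii"`.
#' @return invisibly, `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (n_faces(mesh) == 0L) stop("refusing to write a mesh with no faces")
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  fn <- cr / len
  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"), error = function(e)
      stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    # interleave: normal, v1, v2, v3 as float32 rows, then 2 attribute bytes
    block <- cbind(fn, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7L * nrow(f) + 2L)
    out[1] <- "solid mesh"
    pos <- 2L
    for (i in seq_len(nrow(f))) {
      out[pos] <- paste("facet normal", fmt(fn[i, 1]), fmt(fn[i, 2]), fmt(fn[i, 3]))
      out[pos + 1L] <- "  outer loop"
      for (k in 1:3) {
        vv <- v[f[i, k], ]
        out[pos + 1L + k] <- paste("    vertex", fmt(vv[1]), fmt(vv[2]), fmt(vv[3]))
      }
      out[pos + 5L] <- "  endloop"
      out[pos + 6L] <- "endfacet"
      pos <- pos + 7L
    }
    out[pos] <- "endsolid mesh"
    tryCatch(writeLines(out, path), error = function(e)
      stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  }
  invisible(path)
}

#' Export a mesh with a per-vertex colour map as ASCII PLY
#'
#' Writes a colour contour of a scalar field (typically signed distances) over
#' a mesh, viewable in standard mesh viewers. Values map linearly from blue
#' (`limits[1]`) through white to red (`limits[2]`).
#'
#' @param mesh a [surface_mesh()].
#' @param values numeric vector, one per vertex.
#' @param path output path.
#' @param limits colour range; defaults to symmetric about 0.
#' @return invisibly, `path`.
#' @export
write_ply_colormap <- function(mesh, values, path, limits = NULL) {
  stopifnot(length(values) == n_vertices(mesh))
  if (is.null(limits)) {
    m <- max(abs(values))
    if (m == 0) m <- 1
    limits <- c(-m, m)
  }
  t01 <- pmin(1, pmax(0, (values - limits[1]) / (limits[2] - limits[1])))
  col <- grDevices::colorRamp(c("blue", "white", "red"))(t01)
  v <- mesh$vertices
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           sprintf("element face %d", n_faces(mesh)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.6g %.6g %.6g %d %d %d", v[, 1], v[, 2], v[, 3],
                round(col[, 1]), round(col[, 2]), round(col[, 3]))
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
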