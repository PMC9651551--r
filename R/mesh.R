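#' Triangulated surface mesh
#'
#' Constructs a `surface_mesh`, the container used throughout the pipeline for
#' facial scans and respirator geometry. Coordinates are in millimetres by
#' convention (STL carries no units; all downstream distance thresholds assume
#' mm).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param normals optional numeric matrix of per-vertex outward unit normals;
#'   recomputed on demand by [vertex_normals()] when absent.
#' @param validate check invariants (finite coordinates, indices in range).
#' @return an object of class `surface_mesh` with elements `vertices`, `faces`
#'   and optionally `normals`.
#' @seealso [read_stl()], [clean_mesh()], [vertex_area_weights()]
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate) {
    if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
    if (nrow(faces) > 0L &&
        (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face indices out of range [1, vertex count]")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3L)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("\n  extent [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

# unnormalised face normals (cross products); norm = 2 * triangle area
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Triangle areas of a mesh
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex area weights
#'
#' Each vertex receives one third of the summed areas of its incident
#' triangles, so the weights sum to the total surface area. These weights turn
#' per-vertex distance bands into "percentage of respirator area" statistics.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector (mm^2), one entry per vertex.
#' @export
vertex_area_weights <- function(mesh) {
  a3 <- rep(face_areas(mesh) / 3, 3L)
  idx <- as.vector(mesh$faces)
  w <- numeric(n_vertices(mesh))
  acc <- rowsum(a3, idx)
  w[as.integer(rownames(acc))] <- acc[, 1]
  w
}

#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#' Orientation follows the face winding, so a consistently wound mesh yields
#' consistently outward (or inward) normals.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  cr <- face_cross(mesh)
  idx <- as.vector(mesh$faces)
  n <- matrix(0, n_vertices(mesh), 3L)
  for (j in 1:3) {
    acc <- rowsum(rep(cr[, j], 3L), idx)
    n[as.integer(rownames(acc)), j] <- acc[, 1]
  }
  len <- sqrt(rowSums(n^2))
  if (any(len == 0 & tabulate(idx, n_vertices(mesh)) > 0L))
    stop("mesh has vertices with degenerate (non-orientable) normals")
  len[len == 0] <- 1
  n / len
}

#' Clean a surface mesh
#'
#' Removes exactly duplicated faces (regardless of winding order), zero-area
#' faces, connected components whose total area is a small fraction of the
#' largest component (floating debris left by segmentation), and unreferenced
#' vertices; vertices are reindexed. The operation is idempotent.
#'
#' @param mesh a [surface_mesh()].
#' @param min_component_fraction components with total area below this fraction
#'   of the largest component's area are dropped (default 0.01).
#' @return a cleaned [surface_mesh()].
#' @export
clean_mesh <- function(mesh, min_component_fraction = 0.01) {
  f <- mesh$faces
  if (nrow(f) == 0L) stop("mesh is empty after cleaning")
  # duplicate faces: same vertex set irrespective of rotation/winding
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "_"))
  keep <- !duplicated(key)
  f <- f[keep, , drop = FALSE]
  a <- face_areas(surface_mesh(mesh$vertices, f, validate = FALSE))
  f <- f[a > 0, , drop = FALSE]
  a <- a[a > 0]
  if (nrow(f) == 0L) stop("mesh is empty after cleaning")
  comp <- face_components(f, n_vertices(mesh))
  carea <- rowsum(a, comp)
  thr <- min_component_fraction * max(carea)
  good <- as.integer(rownames(carea))[carea[, 1] >= thr]
  f <- f[comp %in% good, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh is empty after cleaning")
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3L),
               normals = if (!is.null(mesh$normals)) mesh$normals[used, , drop = FALSE])
}

# label faces by connected component (vertex-shared connectivity), via
# union-find over vertices
face_components <- function(faces, nv) {
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(faces))) {
    a <- find(faces[r, 1]); b <- find(faces[r, 2]); c <- find(faces[r, 3])
    parent[b] <- a
    parent[find(c)] <- a
  }
  roots <- vapply(faces[, 1], find, integer(1))
  match(roots, unique(roots))
}

#' Rotate a mesh about a coordinate axis
#'
#' Scan preparation step: scans are brought to a common frame (face looking
#' along +z) by an exact axis rotation about the origin before registration.
#'
#' @param mesh a [surface_mesh()].
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle rotation angle in degrees (right-handed).
#' @return the rotated [surface_mesh()].
#' @export
pre_rotate <- function(mesh, axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  R <- axis_rotation(axis, angle)
  apply_transform(mesh, rigid_transform(R, c(0, 0, 0)))
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex v to `R v + t`; normals, when present, are rotated by `R`.
#'
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed [surface_mesh()].
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2L, transform$translation, "+")
  nrm <- if (!is.null(mesh$normals)) mesh$normals %*% t(transform$rotation)
  surface_mesh(v, mesh$faces, normals = nrm, validate = FALSE)
}

#' Merge two meshes into one
#'
#' Concatenates vertex and face lists (no welding across the inputs). Used to
#' assemble composite scenes such as a reference head with the respirator in
#' situ.
#'
#' @param a,b [surface_mesh()] objects.
#' @return a single [surface_mesh()].
#' @export
merge_meshes <- function(a, b) {
  nv <- n_vertices(a)
  nrm <- if (!is.null(a$normals) && !is.null(b$normals)) rbind(a$normals, b$normals)
  surface_mesh(rbind(a$vertices, b$vertices),
               rbind(a$faces, b$faces + nv),
               normals = nrm, validate = FALSE)
}
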