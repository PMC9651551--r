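#' Stiffness ladder for the deformation levels
#'
#' Maps the deformation index `k` (1..8) to a dimensionless stiffness on a
#' geometric ladder, `0.05 * 4^(k-1)`. Level 1 is nearly unconstrained (the
#' respirator surface conforms closely to the face) and level 8 is so stiff
#' that the result is near rigid; stiffness is strictly increasing in `k`.
#'
#' @param k integer deformation index in 1..8.
#' @return positive stiffness scalar.
#' @export
stiffness_schedule <- function(k) {
  if (!all(k %in% 1:8)) stop("deformation index k must be in 1..8")
  0.05 * 4^(k - 1)
}

#' Deformation level
#'
#' A point on the stiffness ladder, or the special `"rigid"` level meaning no
#' deformation at all (rigid ICP output only).
#'
#' @param k integer 1..8, or the string `"rigid"`.
#' @return object of class `deformation_level` with fields `index`,
#'   `stiffness` and `rigid`.
#' @export
deformation_level <- function(k) {
  if (identical(k, "rigid"))
    return(structure(list(index = NA_integer_, stiffness = Inf, rigid = TRUE,
                          label = "rigid"),
                     class = "deformation_level"))
  k <- as.integer(k)
  structure(list(index = k, stiffness = stiffness_schedule(k), rigid = FALSE,
                 label = sprintf("delta%d", k)),
            class = "deformation_level")
}

#' Default level list: delta 1..8 plus rigid
#' @return list of [deformation_level()] objects.
#' @export
default_levels <- function() {
  c(lapply(1:8, deformation_level), list(deformation_level("rigid")))
}

#' @export
print.deformation_level <- function(x, ...) {
  if (x$rigid) cat("deformation_level: rigid (no deformation)\n")
  else cat(sprintf("deformation_level: delta%d, stiffness %.4g\n",
                   x$index, x$stiffness))
  invisible(x)
}

#' Vertex adjacency of a mesh
#'
#' Sparse symmetric 0/1 adjacency over the mesh edges, used by the Laplacian
#' regulariser.
#'
#' @param mesh a [surface_mesh()].
#' @return a sparse `Matrix::sparseMatrix`.
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_vertices(mesh), n_vertices(mesh)))
  a@x[] <- 1  # collapse duplicate edge entries to unit weight
  a
}

#' Laplacian smoothing of a displacement field
#'
#' Each pass replaces every vertex's displacement by
#' `(1 - blend) * own + blend * mean(neighbours)`. Constant fields are fixed
#' points, isolated vertices are left unchanged, and the field's Dirichlet
#' (neighbour-difference) energy is non-increasing per pass for
#' `blend` in `[0, 1]`.
#'
#' @param field n x 3 numeric matrix of per-vertex displacements (mm).
#' @param adjacency a [surface_mesh()], a sparse adjacency matrix from
#'   [mesh_adjacency()], or a 2-column edge index matrix.
#' @param passes number of smoothing passes.
#' @param blend blending weight toward the neighbour mean, in `[0, 1]`.
#' @return the smoothed field, same dimensions.
#' @export
laplacian_smooth_field <- function(field, adjacency, passes = 1L, blend = 0.5) {
  field <- as.matrix(field)
  stopifnot(blend >= 0, blend <= 1, passes >= 0)
  A <- if (inherits(adjacency, "surface_mesh")) {
    mesh_adjacency(adjacency)
  } else if (is.matrix(adjacency) && ncol(adjacency) == 2L) {
    n <- nrow(field)
    a <- Matrix::sparseMatrix(i = c(adjacency[, 1], adjacency[, 2]),
                              j = c(adjacency[, 2], adjacency[, 1]),
                              x = 1, dims = c(n, n))
    a@x[] <- 1
    a
  } else adjacency
  stopifnot(nrow(A) == nrow(field))
  deg <- Matrix::rowSums(A)
  isolated <- deg == 0
  deg[isolated] <- 1
  for (p in seq_len(passes)) {
    nb_mean <- as.matrix(A %*% field) / deg
    new <- (1 - blend) * field + blend * nb_mean
    new[isolated, ] <- field[isolated, , drop = FALSE]
    field <- new
  }
  field
}

#' Dirichlet energy of a per-vertex field
#'
#' Sum of squared differences across mesh edges; the quantity the Laplacian
#' regulariser drives down.
#'
#' @inheritParams laplacian_smooth_field
#' @return non-negative scalar.
#' @export
field_energy <- function(field, adjacency) {
  A <- if (inherits(adjacency, "surface_mesh")) mesh_adjacency(adjacency) else adjacency
  e <- Matrix::which(Matrix::triu(A, 1) != 0, arr.ind = TRUE)
  d <- field[e[, 1], , drop = FALSE] - field[e[, 2], , drop = FALSE]
  sum(d^2)
}

#' Stiffness-regularised non-rigid ICP
#'
#' Aligns and deforms a source surface (the respirator internal geometry)
#' toward a target (a facial scan). A rigid ICP alignment is performed first;
#' at the `"rigid"` level that is the entire result. Otherwise the surface is
#' iteratively pulled toward its nearest target vertices, with the per-vertex
#' displacement field regularised by stiffness-dependent Laplacian smoothing:
#' higher stiffness means more smoothing passes, a stronger blend toward the
#' neighbourhood mean, and a smaller per-iteration step, so the deformed
#' surface grades continuously from fully conformed (level 1) to near rigid
#' (level 8). All vertices share one stiffness. The iteration is fully
#' deterministic.
#'
#' Iteration stops when the maximum per-iteration vertex motion falls below
#' `motion_tolerance` or after `max_deform_iterations`.
#'
#' @param source,target [surface_mesh()] objects.
#' @param level a [deformation_level()].
#' @param settings an [icp_settings()] for the rigid stage.
#' @param max_deform_iterations cap on deformation iterations (default 50).
#' @param motion_tolerance convergence threshold on per-iteration vertex
#'   motion (mm, default 0.01).
#' @return list of class `nonrigid_result`: `mesh` (deformed
#'   [surface_mesh()]), `field` (n x 3 displacement from the rigid-aligned
#'   mesh, mm), `transform` (the rigid [rigid_transform()]), `rigid_mesh`
#'   (rigid-aligned source), `iterations`, `level`.
#' @export
nonrigid_icp <- function(source, target, level, settings = icp_settings(),
                         max_deform_iterations = 50L, motion_tolerance = 0.01) {
  stopifnot(inherits(level, "deformation_level"))
  rigid <- icp_align(source, target, settings)
  rigid_mesh <- apply_transform(source, rigid$transform)
  if (level$rigid) {
    return(structure(list(mesh = rigid_mesh,
                          field = matrix(0, n_vertices(source), 3L),
                          transform = rigid$transform, rigid_mesh = rigid_mesh,
                          iterations = 0L, level = level),
                     class = "nonrigid_result"))
  }
  s <- level$stiffness
  step <- 1 / (1 + s)
  blend <- s / (1 + s)
  passes <- max(1L, ceiling(log2(1 + s)))
  A <- mesh_adjacency(source)
  v <- rigid_mesh$vertices
  tgt <- target$vertices
  it <- 0L
  for (i in seq_len(max_deform_iterations)) {
    it <- i
    nn <- nearest_points(v, tgt)
    raw <- tgt[nn$index, , drop = FALSE] - v
    sm <- laplacian_smooth_field(raw, A, passes = passes, blend = blend)
    delta <- step * sm
    v <- v + delta
    if (max(sqrt(rowSums(delta^2))) < motion_tolerance) break
  }
  mesh <- surface_mesh(v, source$faces, validate = FALSE)
  structure(list(mesh = mesh, field = v - rigid_mesh$vertices,
                 transform = rigid$transform, rigid_mesh = rigid_mesh,
                 iterations = it, level = level),
            class = "nonrigid_result")
}

#' @export
print.nonrigid_result <- function(x, ...) {
  mag <- sqrt(rowSums(x$field^2))
  cat(sprintf("nonrigid_result (%s): %d deformation iterations, mean |u| %.3f mm, max |u| %.3f mm\n",
              x$level$label, x$iterations, mean(mag), max(mag)))
  invisible(x)
}
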