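#' Parameters for a synthetic face/respirator scene
#'
#' Controls the deterministic generator that emulates the study inputs: a
#' smooth face-like height-field surface (base dome + Gaussian nose ridge +
#' cheek mounds), a respirator internal shell cut from the nose/mouth region
#' and offset from the skin with a sealing rim, a "loaded" face with a
#' prescribed indentation and lateral bulges, a canonical reference head, and
#' a known rigid misalignment between the subject scans and the reference
#' frame. All lengths in mm.
#'
#' @param face_width,face_height extent of the face patch (default 140 x 180).
#' @param base_depth amplitude of the smooth facial dome (default 25).
#' @param nose_height,nose_width,nose_length,nose_y Gaussian nose ridge:
#'   peak height, cross-ridge sigma, along-ridge sigma, ridge centre y.
#' @param cheek_amplitude,cheek_x,cheek_y,cheek_sigma cheek mounds at
#'   `(+/-cheek_x, cheek_y)`.
#' @param mask_xlim,mask_ylim rectangular nose/mouth region the respirator
#'   internal surface is cut from.
#' @param mask_offset normal offset of the internal surface from the skin
#'   (mm; positive = gapped, 0 = coincident, negative = pre-indented;
#'   default 2).
#' @param rim_offset offset at the sealing rim (default 0, i.e. touching).
#' @param rim_width width of the rim taper band at the region boundary
#'   (default 8).
#' @param shell_thickness offset between internal surface and outer shell at
#'   the rim (default 4).
#' @param dome_height extra height of the outer shell cup over the region
#'   centre (default 12), emulating the semi-rigid dome of an FFP3 shell.
#' @param indent_depth peak depth of the prescribed loaded-face indentation
#'   under the lower rim (default 5; the observed per-subject range is about
#'   3-6).
#' @param indent_center,indent_radius indentation footprint (plateau +
#'   cosine falloff).
#' @param bulge_height peak height of the lateral soft-tissue bulges
#'   (default 4; observed range about 3-6).
#' @param bulge_x,bulge_y,bulge_radius bulge footprints at `(+/-bulge_x,
#'   bulge_y)`.
#' @param resolution vertices per axis of the face grid (>= 20, default 80).
#' @param perturbation a [rigid_transform()] applied to the subject meshes to
#'   emulate scanner frame misalignment; default 8 degrees about a skew axis
#'   plus ~11 mm translation.
#' @param noise_sd standard deviation of seeded Gaussian vertex noise on the
#'   loaded face (default 0).
#' @param alar_half,bio_ocular_half,exocanthion_y,sellion_y,subnasale_y,menton_y
#'   analytic landmark placement (x half-separations and y positions).
#' @param seed integer RNG seed for the noise (default 1).
#' @return object of class `scene_params` (a named list).
#' @export
scene_params <- function(face_width = 140, face_height = 180, base_depth = 25,
                         nose_height = 18, nose_width = 9, nose_length = 25,
                         nose_y = 10,
                         cheek_amplitude = 8, cheek_x = 38, cheek_y = 0,
                         cheek_sigma = 18,
                         mask_xlim = c(-40, 40), mask_ylim = c(-65, 25),
                         mask_offset = 2, rim_offset = 0, rim_width = 8,
                         shell_thickness = 4, dome_height = 12,
                         indent_depth = 5, indent_center = c(0, -58),
                         indent_radius = 25,
                         bulge_height = 4, bulge_x = 55, bulge_y = -10,
                         bulge_radius = 22,
                         resolution = 80L,
                         perturbation = rigid_transform(
                           axis_angle_rotation(c(0.2, 0.3, 1), 8),
                           c(6, -4, 9)),
                         noise_sd = 0,
                         alar_half = 17.5, bio_ocular_half = 45,
                         exocanthion_y = 35, sellion_y = 40,
                         subnasale_y = -16, menton_y = -78,
                         seed = 1L) {
  if (resolution < 20L) stop("resolution must be at least 20 vertices per axis")
  stopifnot(indent_depth >= 0, bulge_height >= 0, noise_sd >= 0,
            inherits(perturbation, "rigid_transform"))
  p <- as.list(environment())
  structure(p, class = "scene_params")
}

# face height field and its analytic evaluation
face_height_field <- function(x, y, p) {
  base <- p$base_depth * cos(pi * x / (1.1 * p$face_width)) *
    cos(pi * y / (1.3 * p$face_height))
  nose <- p$nose_height * exp(-(x / p$nose_width)^2 -
                                ((y - p$nose_y) / p$nose_length)^2)
  cheeks <- p$cheek_amplitude *
    (exp(-((x - p$cheek_x)^2 + (y - p$cheek_y)^2) / p$cheek_sigma^2) +
       exp(-((x + p$cheek_x)^2 + (y - p$cheek_y)^2) / p$cheek_sigma^2))
  base + nose + cheeks
}

# triangulate an nx x ny grid (x fastest); winding gives +z normals
grid_faces <- function(nx, ny) {
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- (j - 1L) * nx + i
  b <- a + 1L
  c_ <- b + nx
  d <- a + nx
  rbind(cbind(a, b, c_), cbind(a, c_, d))
}

#' Generate a synthetic face surface with landmarks
#'
#' Height-field face `z = f(x, y)` (smooth dome + nose ridge + cheek mounds)
#' triangulated on a regular grid, with landmarks placed analytically on the
#' surface. Deterministic: the same parameters always give a bit-identical
#' mesh.
#'
#' @param params a [scene_params()].
#' @return list with `mesh` (a [surface_mesh()]) and `landmarks` (a
#'   [landmark_set()]).
#' @export
make_face <- function(params = scene_params()) {
  p <- params
  n <- p$resolution
  xs <- seq(-p$face_width / 2, p$face_width / 2, length.out = n)
  ys <- seq(-p$face_height / 2, p$face_height / 2, length.out = n)
  g <- expand.grid(x = xs, y = ys)
  # irregular sampling, as in real scan meshes: deterministic quasi-random
  # jitter of interior grid nodes (boundary kept so the extent is exact)
  i <- rep(seq_len(n), n)
  j <- rep(seq_len(n), each = n)
  interior <- i > 1L & i < n & j > 1L & j < n
  amp <- 0.3
  g$x <- g$x + interior * amp * diff(xs[1:2]) * sin(7.3 * i + 1.7 * j)
  g$y <- g$y + interior * amp * diff(ys[1:2]) * sin(3.1 * i - 2.3 * j + 0.5)
  z <- face_height_field(g$x, g$y, p)
  mesh <- surface_mesh(cbind(g$x, g$y, z), grid_faces(n, n))
  lm_pt <- function(x, y) c(x, y, face_height_field(x, y, p))
  landmarks <- landmark_set(list(
    exocanthion_left = lm_pt(-p$bio_ocular_half, p$exocanthion_y),
    exocanthion_right = lm_pt(p$bio_ocular_half, p$exocanthion_y),
    alare_left = lm_pt(-p$alar_half, p$nose_y - 6),
    alare_right = lm_pt(p$alar_half, p$nose_y - 6),
    sellion = lm_pt(0, p$sellion_y),
    pronasale = lm_pt(0, p$nose_y),
    subnasale = lm_pt(0, p$subnasale_y),
    menton = lm_pt(0, p$menton_y)))
  list(mesh = mesh, landmarks = landmarks)
}

# drop faces fully inside the rectangle: a surface scan of the head with the
# respirator in situ shows the respirator, not the skin it covers
crop_region <- function(mesh, xlim, ylim) {
  v <- mesh$vertices
  inside <- v[, 1] >= xlim[1] & v[, 1] <= xlim[2] &
    v[, 2] >= ylim[1] & v[, 2] <= ylim[2]
  keep <- !(inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
              inside[mesh$faces[, 3]])
  clean_mesh(surface_mesh(v, mesh$faces[keep, , drop = FALSE],
                          validate = FALSE), 0)
}

# plateau(0..radius): 1 on the inner 70%, cosine falloff to 0 at the edge
plateau <- function(r, radius) {
  t <- r / radius
  ifelse(t <= 0.7, 1, ifelse(t >= 1, 0, 0.5 * (1 + cos(pi * (t - 0.7) / 0.3))))
}

#' Generate the respirator internal surface and whole geometry
#'
#' Cuts the nose/mouth region from a synthetic face and offsets it along the
#' vertex normals: the interior by `mask_offset`, tapering to `rim_offset`
#' within `rim_width` of the region boundary (the sealing rim). The whole
#' geometry is the internal surface plus an outer shell offset by
#' `shell_thickness`.
#'
#' @param face a face mesh from [make_face()].
#' @param params a [scene_params()].
#' @return list with `internal` and `whole` ([surface_mesh()] objects).
#' @export
make_mask <- function(face, params = scene_params()) {
  p <- params
  v <- face$vertices
  if (p$mask_xlim[1] < min(v[, 1]) || p$mask_xlim[2] > max(v[, 1]) ||
      p$mask_ylim[1] < min(v[, 2]) || p$mask_ylim[2] > max(v[, 2]))
    stop("mask region extends outside the face extent")
  nrm <- vertex_normals(face)
  inside <- v[, 1] >= p$mask_xlim[1] & v[, 1] <= p$mask_xlim[2] &
    v[, 2] >= p$mask_ylim[1] & v[, 2] <= p$mask_ylim[2]
  keep_face <- inside[face$faces[, 1]] & inside[face$faces[, 2]] &
    inside[face$faces[, 3]]
  used <- sort(unique(as.vector(face$faces[keep_face, , drop = FALSE])))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  faces <- matrix(remap[face$faces[keep_face, , drop = FALSE]], ncol = 3L)
  vv <- v[used, , drop = FALSE]
  nn <- nrm[used, , drop = FALSE]
  # distance to the region boundary drives the rim taper
  db <- pmin(vv[, 1] - p$mask_xlim[1], p$mask_xlim[2] - vv[, 1],
             vv[, 2] - p$mask_ylim[1], p$mask_ylim[2] - vv[, 2])
  t <- pmin(1, pmax(0, db / p$rim_width))
  s <- t * t * (3 - 2 * t)  # smoothstep
  offset <- p$rim_offset + (p$mask_offset - p$rim_offset) * s
  internal <- surface_mesh(vv + offset * nn, faces)
  # the outer shell is a pronounced cup (semi-rigid FFP3 dome), not a plain
  # offset: the dome both matches real respirator geometry and gives the
  # whole scan a distinctive shape for registration
  t2 <- pmin(1, db / (3 * p$rim_width))
  dome <- p$dome_height * t2 * t2 * (3 - 2 * t2)
  outer <- surface_mesh(internal$vertices + (p$shell_thickness + dome) * nn,
                        faces, validate = FALSE)
  list(internal = internal, whole = merge_meshes(internal, outer))
}

#' Generate the loaded face with a prescribed displacement field
#'
#' Displaces the unloaded face along its vertex normals by a prescribed
#' field: an indentation plateau of peak depth `indent_depth` under the lower
#' respirator rim, and lateral bulge plateaus of peak height `bulge_height`
#' on the cheeks. The 2.5th/97.5th area-weighted percentiles of the
#' prescribed field are recorded as analytic ground truth, independent of any
#' registration. Optional Gaussian vertex noise is seeded and reproducible.
#'
#' @param face a face mesh from [make_face()].
#' @param params a [scene_params()].
#' @return list with `mesh` (the loaded [surface_mesh()]), `field` (the
#'   prescribed per-vertex normal displacement, mm), and `percentiles`
#'   (named `p_low`, `p_high`).
#' @export
make_loaded_face <- function(face, params = scene_params()) {
  p <- params
  v <- face$vertices
  nrm <- vertex_normals(face)
  r_ind <- sqrt((v[, 1] - p$indent_center[1])^2 + (v[, 2] - p$indent_center[2])^2)
  r_bl <- sqrt((v[, 1] + p$bulge_x)^2 + (v[, 2] - p$bulge_y)^2)
  r_br <- sqrt((v[, 1] - p$bulge_x)^2 + (v[, 2] - p$bulge_y)^2)
  s <- -p$indent_depth * plateau(r_ind, p$indent_radius) +
    p$bulge_height * (plateau(r_bl, p$bulge_radius) +
                        plateau(r_br, p$bulge_radius))
  vv <- v + s * nrm
  if (p$noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(p$seed)
    vv <- vv + matrix(stats::rnorm(length(vv), sd = p$noise_sd), ncol = 3L)
  }
  w <- vertex_area_weights(face)
  q <- weighted_quantile(s, w, c(0.025, 0.975))
  list(mesh = surface_mesh(vv, face$faces),
       field = s,
       percentiles = c(p_low = q[1], p_high = q[2]))
}

#' Generate a complete synthetic scene
#'
#' Composes [make_face()], [make_mask()] and [make_loaded_face()] into the
#' six meshes the pipeline consumes. The reference head is the canonical
#' (unperturbed) face, and the reference head with respirator is that face
#' merged with the respirator whole geometry in its seated pose; the subject
#' meshes (unloaded face, loaded face, respirator whole and internal) are
#' displaced by the known `perturbation` transform, which is recorded as
#' ground truth along with the prescribed displacement field, its analytic
#' percentiles, and the landmark set.
#'
#' @param params a [scene_params()].
#' @return object of class `synthetic_scene` with the six meshes
#'   (`unloaded_face`, `loaded_face`, `respirator_whole`,
#'   `respirator_internal`, `reference_head`,
#'   `reference_head_with_respirator`) and `ground_truth` (list:
#'   `perturbation`, `displacement_field`, `percentiles`, `landmarks`,
#'   `params`).
#' @export
make_scene <- function(params = scene_params()) {
  p <- params
  face <- make_face(p)
  mask <- make_mask(face$mesh, p)
  loaded <- make_loaded_face(face$mesh, p)
  pert <- p$perturbation
  structure(list(
    unloaded_face = apply_transform(face$mesh, pert),
    loaded_face = apply_transform(loaded$mesh, pert),
    respirator_whole = apply_transform(mask$whole, pert),
    respirator_internal = apply_transform(mask$internal, pert),
    reference_head = face$mesh,
    reference_head_with_respirator = merge_meshes(
      crop_region(face$mesh, p$mask_xlim, p$mask_ylim), mask$whole),
    ground_truth = list(perturbation = pert,
                        displacement_field = loaded$field,
                        percentiles = loaded$percentiles,
                        landmarks = face$landmarks,
                        params = p)),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d-vertex face grid, mask offset %g mm, indentation %g mm, bulge %g mm\n",
              n_vertices(x$reference_head), x$ground_truth$params$mask_offset,
              x$ground_truth$params$indent_depth,
              x$ground_truth$params$bulge_height))
  invisible(x)
}

#' Write a scene to disk as STL plus a ground-truth sidecar
#'
#' Writes the six meshes as binary STL files and the ground truth (applied
#' transform, analytic percentiles, landmarks, parameters, seed) as JSON.
#'
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("unloaded_face", "loaded_face", "respirator_whole",
          "respirator_internal", "reference_head",
          "reference_head_with_respirator")
  for (m in nm) write_stl(scene[[m]], file.path(dir, paste0(m, ".stl")))
  gt <- scene$ground_truth
  p <- gt$params
  p$perturbation <- NULL
  jsonlite::write_json(
    list(perturbation = list(rotation = gt$perturbation$rotation,
                             translation = gt$perturbation$translation),
         percentiles = as.list(gt$percentiles),
         landmarks = lapply(unclass(gt$landmarks), identity),
         params = p[!vapply(p, is.null, logical(1))]),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
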