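# fixture builders shared across the test files; everything is generated in
# code, nothing read from disk

cube_mesh <- function(side = 1) {
  v <- side * as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward winding
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = 1
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = 1
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = 1
  surface_mesh(v, f)
}

uv_sphere <- function(radius = 1, nlat = 24L, nlon = 48L) {
  th <- pi * seq_len(nlat - 1L) / nlat
  ph <- 2 * pi * (seq_len(nlon) - 1L) / nlon
  g <- expand.grid(ph = ph, th = th)
  v <- radius * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  np <- nrow(v) + 1L
  sp <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  idx <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  quads <- do.call(rbind, lapply(seq_len(nlat - 2L), function(i) {
    j <- seq_len(nlon)
    rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
          cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }))
  j <- seq_len(nlon)
  caps <- rbind(cbind(np, idx(1L, j), idx(1L, j + 1L)),
                cbind(sp, idx(nlat - 1L, j + 1L), idx(nlat - 1L, j)))
  surface_mesh(v, rbind(quads, caps), normals = v / radius)
}

plane_mesh <- function(z = 0, n = 20L, width = 10) {
  xs <- seq(-width / 2, width / 2, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  f <- respfit:::grid_faces(n, n)
  surface_mesh(cbind(g$x, g$y, rep(z, nrow(g))), f)
}

expect_mesh_equal <- function(a, b, tolerance = 1e-9) {
  expect_equal(a$faces, b$faces)
  expect_lte(max(abs(a$vertices - b$vertices)), tolerance)
}

# default scene and its alignment cascade, built once per test run
.scene_cache <- new.env(parent = emptyenv())

default_scene <- function() {
  if (is.null(.scene_cache$scene)) .scene_cache$scene <- make_scene(scene_params())
  .scene_cache$scene
}

default_cascade <- function() {
  if (is.null(.scene_cache$cascade)) {
    sc <- default_scene()
    .scene_cache$cascade <- align_cascade(
      sc$unloaded_face, sc$loaded_face, sc$respirator_whole,
      sc$respirator_internal, sc$reference_head,
      sc$reference_head_with_respirator)
  }
  .scene_cache$cascade
}

max_vertex_error <- function(a, b) max(abs(a - b))

default_cascade_for <- function(sc) {
  align_cascade(sc$unloaded_face, sc$loaded_face, sc$respirator_whole,
                sc$respirator_internal, sc$reference_head,
                sc$reference_head_with_respirator)
}
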