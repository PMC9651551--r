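test_that("surface_mesh validates its invariants", {
  expect_error(surface_mesh(matrix(c(0, 0, NaN), 1), matrix(1:3, 1)),
               "non-finite")
  expect_error(surface_mesh(diag(3), matrix(c(1, 2, 4), 1)), "out of range")
  m <- cube_mesh()
  expect_s3_class(m, "surface_mesh")
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
})

test_that("vertex area weights split triangle area and conserve total area", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0)),
                      matrix(1:3, 1))
  expect_equal(vertex_area_weights(tri), rep(2, 3))  # area 6, a third each
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(sum(vertex_area_weights(sq)), 1)
  cube <- cube_mesh(2)
  expect_equal(sum(vertex_area_weights(cube)), 6 * 4, tolerance = 1e-12)
})

test_that("sphere mesh area converges to the analytic value with refinement", {
  r <- 50
  err <- vapply(c(12L, 24L, 48L), function(nlat) {
    s <- uv_sphere(r, nlat, 2L * nlat)
    abs(sum(vertex_area_weights(s)) - 4 * pi * r^2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # monotone convergence
  expect_lt(err[3] / (4 * pi * r^2), 0.01) # within 1% at the finest level
})

test_that("clean_mesh removes duplicates, debris and unreferenced vertices", {
  m <- cube_mesh()
  # idempotence on an already-clean mesh
  expect_mesh_equal(clean_mesh(m), m)
  expect_mesh_equal(clean_mesh(clean_mesh(m)), clean_mesh(m))
  # one exactly duplicated face drops the face count by one
  dup <- surface_mesh(m$vertices, rbind(m$faces, m$faces[1, ]))
  expect_equal(nrow(clean_mesh(dup)$faces), nrow(m$faces))
  # a tiny floating triangle below the component-area threshold is removed,
  # along with its now-unreferenced vertices
  tiny <- surface_mesh(
    rbind(m$vertices, c(10, 10, 10), c(10.01, 10, 10), c(10, 10.01, 10)),
    rbind(m$faces, c(9, 10, 11)))
  cleaned <- clean_mesh(tiny, min_component_fraction = 0.01)
  expect_equal(nrow(cleaned$faces), 12L)
  expect_equal(nrow(cleaned$vertices), 8L)
  # zero-area faces go too
  degen <- surface_mesh(m$vertices, rbind(m$faces, c(1, 1, 2)))
  expect_equal(nrow(clean_mesh(degen)$faces), 12L)
  expect_error(clean_mesh(surface_mesh(m$vertices, m$faces[0, , drop = FALSE])),
               "empty after cleaning")
})

test_that("pre_rotate applies exact axis rotations", {
  pt <- surface_mesh(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1)),
                     matrix(1:3, 1))
  expect_mesh_equal(pre_rotate(pt, "x", 0), pt, tolerance = 1e-15)
  r <- pre_rotate(pt, "z", 90)
  expect_lt(max(abs(r$vertices[1, ] - c(0, 1, 0))), 1e-12)
  # two successive 90 degree x-rotations equal one 180 degree x-rotation
  expect_mesh_equal(pre_rotate(pre_rotate(pt, "x", 90), "x", 90),
                    pre_rotate(pt, "x", 180), tolerance = 1e-12)
})

test_that("apply_transform is an isometry and composes with its inverse", {
  m <- default_scene()$reference_head
  tr <- rigid_transform(respfit:::axis_angle_rotation(c(1, 2, 3), 37),
                        c(5, 2, -3))
  moved <- apply_transform(m, tr)
  # identity
  expect_mesh_equal(apply_transform(m, rt_identity()), m, tolerance = 0)
  # inverse restores the original
  expect_mesh_equal(apply_transform(moved, rt_invert(tr)), m, tolerance = 1e-9)
  # pure translation shifts the centroid exactly
  shifted <- apply_transform(m, rigid_transform(diag(3), c(5, 2, -3)))
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices), c(5, 2, -3))
  # pairwise distances preserved on a vertex subset
  idx <- seq(1, n_vertices(m), by = 499)
  d0 <- dist(m$vertices[idx, ])
  d1 <- dist(moved$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("rigid transforms are closed under composition and inversion", {
  a <- rigid_transform(respfit:::axis_angle_rotation(c(0, 1, 1), 25), c(1, 2, 3))
  b <- rigid_transform(respfit:::axis_angle_rotation(c(1, 0, 0), -40), c(-2, 0, 7))
  ab <- rt_compose(a, b)
  p <- matrix(rnorm(30), 10)
  expect_equal(rt_apply(ab, p), rt_apply(a, rt_apply(b, p)), tolerance = 1e-12)
  inv <- rt_invert(ab)
  expect_equal(rt_apply(rt_compose(inv, ab), p), p, tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl, c(0, 0, 0)), "proper")
})
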