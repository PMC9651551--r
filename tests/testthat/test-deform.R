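test_that("stiffness schedule is the documented geometric ladder", {
  expect_equal(stiffness_schedule(1), 0.05)
  expect_equal(stiffness_schedule(8), 0.05 * 4^7)
  s <- stiffness_schedule(1:8)
  expect_true(all(diff(s) > 0))
  expect_error(stiffness_schedule(0), "1..8")
  expect_error(stiffness_schedule(9), "1..8")
  expect_true(deformation_level("rigid")$rigid)
  expect_length(default_levels(), 9L)
})

test_that("laplacian smoothing fixes constants and spreads a point source", {
  # 5-vertex path graph, single nonzero displacement at vertex 3, blend 1:
  # hand-computed one pass: v2 and v4 become c/2, v3 becomes 0
  edges <- cbind(1:4, 2:5)
  f <- matrix(0, 5, 3)
  f[3, ] <- c(1, 2, -2)
  out <- laplacian_smooth_field(f, edges, passes = 1L, blend = 1)
  expect_equal(out[2, ], f[3, ] / 2)
  expect_equal(out[4, ], f[3, ] / 2)
  expect_equal(out[3, ], c(0, 0, 0))
  expect_equal(out[1, ], f[3, ] / 2 * 0)  # neighbour (v2) was zero before
  # constant field is a fixed point for any number of passes
  const <- matrix(rep(c(3, -1, 2), each = 5), 5)
  expect_equal(laplacian_smooth_field(const, edges, passes = 7L, blend = 0.8),
               const)
  # isolated vertex keeps its displacement
  f6 <- rbind(f, c(9, 9, 9))
  out6 <- laplacian_smooth_field(f6, edges, passes = 3L, blend = 1)
  expect_equal(out6[6, ], c(9, 9, 9))
})

test_that("smoothing never increases the Dirichlet energy of random fields", {
  mesh <- plane_mesh(n = 12L)
  A <- mesh_adjacency(mesh)
  set.seed(7)
  for (blend in c(0.3, 0.7, 1)) {
    f <- matrix(rnorm(3 * n_vertices(mesh)), ncol = 3)
    e0 <- field_energy(f, A)
    for (p in 1:4) {
      f <- laplacian_smooth_field(f, A, passes = 1L, blend = blend)
      e1 <- field_energy(f, A)
      expect_lte(e1, e0 + 1e-12)
      e0 <- e1
    }
  }
})

test_that("nonrigid ICP yields zero field on coincident surfaces", {
  face <- make_face(scene_params(resolution = 40))$mesh
  for (k in c(1, 8)) {
    r <- nonrigid_icp(face, face, deformation_level(k),
                      icp_settings(centroid_init = FALSE))
    expect_lt(max(abs(r$field)), 1e-9)
  }
})

test_that("planar gap closes at level 1 and survives at level 8", {
  src <- plane_mesh(z = 2, n = 25L, width = 40)
  tgt <- plane_mesh(z = 0, n = 25L, width = 40)
  s <- icp_settings(centroid_init = FALSE)
  r1 <- nonrigid_icp(src, tgt, deformation_level(1), s)
  expect_lt(max(abs(r1$mesh$vertices[, 3])), 0.05)
  r8 <- nonrigid_icp(src, tgt, deformation_level(8), s)
  dev <- sqrt(rowSums((r8$mesh$vertices - r8$rigid_mesh$vertices)^2))
  expect_lt(mean(dev), 0.5)
})

test_that("a curved target separates the soft and stiff ends of the ladder", {
  # a rigid motion cannot map the plane onto the wavy sheet, so conformity
  # here is genuinely the deformation's doing
  n <- 25L
  src <- plane_mesh(z = 1, n = n, width = 40)
  wav <- plane_mesh(z = 0, n = n, width = 40)
  wav$vertices[, 3] <- 2 * sin(wav$vertices[, 1] / 6) * cos(wav$vertices[, 2] / 7)
  s <- icp_settings(centroid_init = FALSE)
  r1 <- nonrigid_icp(src, wav, deformation_level(1), s)
  m1 <- signed_distances(r1$mesh, wav)
  expect_lt(sum(m1$weight * abs(m1$distance)) / sum(m1$weight), 0.2)
  r8 <- nonrigid_icp(src, wav, deformation_level(8), s)
  dev <- sqrt(rowSums((r8$mesh$vertices - r8$rigid_mesh$vertices)^2))
  expect_lt(mean(dev), 0.5)
})

test_that("the rigid level reproduces rigid ICP output bit for bit", {
  sc <- default_scene()
  cas <- default_cascade()
  s <- icp_settings(centroid_init = FALSE)
  r <- nonrigid_icp(cas$meshes$respirator_internal, cas$meshes$unloaded_face,
                    deformation_level("rigid"), s)
  icp <- icp_align(cas$meshes$respirator_internal, cas$meshes$unloaded_face, s)
  ref <- apply_transform(cas$meshes$respirator_internal, icp$transform)
  expect_identical(r$mesh$vertices, ref$vertices)
  expect_true(all(r$field == 0))
})

test_that("deformation preserves mesh topology", {
  cas <- default_cascade()
  src <- cas$meshes$respirator_internal
  r <- nonrigid_icp(src, cas$meshes$unloaded_face, deformation_level(3),
                    icp_settings(centroid_init = FALSE))
  expect_identical(r$mesh$faces, src$faces)
  expect_equal(n_vertices(r$mesh), n_vertices(src))
})
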