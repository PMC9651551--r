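rot <- respfit:::axis_angle_rotation

test_that("kabsch_fit recovers exact transforms and rejects degenerate input", {
  set.seed(11)
  p <- matrix(rnorm(12, sd = 10), 4)   # 4 non-coplanar points
  # identical sets give the identity
  id <- kabsch_fit(p, p)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-12)
  # known rotation + translation recovered to 1e-10
  R <- respfit:::axis_rotation("z", 90)
  q <- sweep(p %*% t(R), 2, c(1, 1, 1), "+")
  fit <- kabsch_fit(p, q)
  expect_lt(max(abs(fit$rotation - R)), 1e-10)
  expect_lt(max(abs(fit$translation - c(1, 1, 1))), 1e-10)
  # pure translation: rotation stays identity, translation is centroid shift
  fit2 <- kabsch_fit(p, sweep(p, 2, c(5, -2, 3), "+"))
  expect_lt(max(abs(fit2$rotation - diag(3))), 1e-12)
  expect_equal(fit2$translation, c(5, -2, 3), tolerance = 1e-12)
  # collinear configuration is singular
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_fit(line, line), "singular")
  expect_error(kabsch_fit(p[1:2, ], q[1:2, ]), "at least 3")
})

test_that("icp_align is exact on identical meshes and recovers known transforms", {
  sc <- default_scene()
  ref <- sc$reference_head
  # source == target: identity at once, RMS 0 from iteration 1
  r0 <- icp_align(ref, ref)
  expect_lt(max(abs(r0$transform$rotation - diag(3))), 1e-12)
  expect_equal(r0$rms_history[1], 0)
  expect_true(r0$converged)
  # known perturbation (10 degrees about z + translation), noiseless
  tr <- rigid_transform(respfit:::axis_rotation("z", 10), c(5, 2, -3))
  moved <- apply_transform(ref, tr)
  r <- icp_align(moved, ref)
  rms_err <- sqrt(mean(rowSums(
    (rt_apply(r$transform, moved$vertices) - ref$vertices)^2)))
  expect_lt(rms_err, 1e-6)
  expect_error(icp_align(surface_mesh(ref$vertices[0, , drop = FALSE],
                                      ref$faces[0, , drop = FALSE]), ref),
               "non-empty")
})

test_that("ICP RMS history is monotone non-increasing", {
  sc <- default_scene()
  r <- icp_align(sc$unloaded_face, sc$reference_head)
  expect_true(all(diff(r$rms_history) <= 1e-9))
})

test_that("trimming improves recovery when a fifth of the source is outliers", {
  sc <- default_scene()
  ref <- sc$reference_head
  tr <- rigid_transform(rot(c(0.1, 0.2, 1), 6), c(4, -2, 5))
  moved <- apply_transform(ref, tr)
  set.seed(21)
  v <- moved$vertices
  bad <- sample(nrow(v), round(0.2 * nrow(v)))
  # directional artefact cluster (stray reflections), the case where the
  # untrimmed least-squares fit is badly biased
  v[bad, ] <- v[bad, ] +
    matrix(rep(c(25, 18, 30), each = length(bad)), ncol = 3) +
    matrix(rnorm(3 * length(bad), sd = 3), ncol = 3)
  noisy <- surface_mesh(v, moved$faces)
  err_for <- function(trim) {
    r <- icp_align(noisy, ref, icp_settings(trim_fraction = trim))
    # error against the known ground truth on the clean vertices
    clean <- setdiff(seq_len(nrow(v)), bad)
    sqrt(mean(rowSums((rt_apply(r$transform, moved$vertices[clean, ]) -
                         ref$vertices[clean, ])^2)))
  }
  expect_lt(err_for(0.25), err_for(0))
})

test_that("icp_align is equivariant under source pre-transformation", {
  sc <- default_scene()
  ref <- sc$reference_head
  tr <- rigid_transform(rot(c(0, 0.4, 1), 9), c(3, 1, -6))
  src <- apply_transform(ref, tr)
  s <- icp_settings(max_iterations = 600, rms_tolerance = 1e-11)
  base <- icp_align(src, ref, s)$transform
  extra <- rigid_transform(rot(c(1, 0.5, 0), 7), c(-4, 2, 3))
  pre <- apply_transform(src, extra)
  got <- icp_align(pre, ref, s)$transform
  want <- rt_compose(base, rt_invert(extra))
  expect_lt(max(abs(got$rotation - want$rotation)), 1e-6)
  expect_lt(max(abs(got$translation - want$translation)), 1e-6)
})

test_that("align_cascade recovers scene perturbations and composes step 3", {
  # identity perturbation (and no loading deformation, so the loaded scan is
  # the reference geometry too): every transform is the identity
  sc_id <- make_scene(scene_params(resolution = 70, indent_depth = 0,
                                   bulge_height = 0,
                                   perturbation = rt_identity()))
  cas_id <- align_cascade(sc_id$unloaded_face, sc_id$loaded_face,
                          sc_id$respirator_whole, sc_id$respirator_internal,
                          sc_id$reference_head,
                          sc_id$reference_head_with_respirator)
  for (tr in cas_id$transforms) {
    expect_lt(max(abs(tr$rotation - diag(3))), 1e-6)
    expect_lt(max(abs(tr$translation)), 1e-5)
  }
  # known perturbation: recovered as its inverse (checked in vertex space);
  # the scene has no loading deformation so the loaded scan recovers exactly
  sc <- make_scene(scene_params(resolution = 70, indent_depth = 0,
                                bulge_height = 0))
  cas <- default_cascade_for(sc)
  gt <- sc$ground_truth$perturbation
  for (nm in c("unloaded_face", "loaded_face", "respirator_internal")) {
    canon <- apply_transform(sc[[nm]], rt_invert(gt))
    expect_lt(max_vertex_error(cas$meshes[[nm]]$vertices, canon$vertices),
              1e-5)
  }
  # step 3 is definitionally the step-2 transform applied to the internal mesh
  expect_identical(cas$meshes$respirator_internal$vertices,
                   apply_transform(sc$respirator_internal,
                                   cas$transforms$respirator)$vertices)
})
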