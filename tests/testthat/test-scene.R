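test_that("scene generation is deterministic, including seeded noise", {
  p <- scene_params(resolution = 40, noise_sd = 0.2, seed = 7L)
  a <- make_scene(p)
  b <- make_scene(p)
  for (nm in c("unloaded_face", "loaded_face", "respirator_whole",
               "respirator_internal", "reference_head",
               "reference_head_with_respirator"))
    expect_identical(a[[nm]]$vertices, b[[nm]]$vertices, label = nm)
  expect_identical(a$ground_truth$percentiles, b$ground_truth$percentiles)
  # a different seed changes the noisy loaded face only
  c_ <- make_scene(scene_params(resolution = 40, noise_sd = 0.2, seed = 8L))
  expect_identical(a$unloaded_face$vertices, c_$unloaded_face$vertices)
  expect_false(identical(a$loaded_face$vertices, c_$loaded_face$vertices))
})

test_that("a face without a nose ridge is bilaterally symmetric", {
  p <- scene_params(resolution = 40, nose_height = 0)
  f <- make_face(p)
  v <- f$mesh$vertices
  # the surface (not the sampling) is symmetric: each mirrored vertex lies
  # back on the height field
  z_mirror <- respfit:::face_height_field(-v[, 1], v[, 2], p)
  expect_lt(max(abs(z_mirror - v[, 3])), 1e-9)
})

test_that("landmarks sit on the surface at their parameterized separations", {
  p <- scene_params()
  f <- make_face(p)
  lm <- f$landmarks
  prof <- measure_profile(lm)
  expect_equal(unname(prof["alar_width"]), 2 * p$alar_half)
  expect_equal(unname(prof["bio_ocular_width"]), 2 * p$bio_ocular_half)
  for (nm in names(lm)) {
    pt <- lm[[nm]]
    expect_equal(pt[3], respfit:::face_height_field(pt[1], pt[2], p),
                 label = nm)
  }
})

test_that("mask offsets translate directly into signed distances and bands", {
  p0 <- scene_params(perturbation = rt_identity())
  face <- make_face(p0)$mesh
  # uniform -1 mm offset: every distance is -1, the whole area seals
  pm <- scene_params(mask_offset = -1, rim_offset = -1,
                     perturbation = rt_identity())
  m <- make_mask(face, pm)
  sd0 <- signed_distances(m$internal, face)
  expect_equal(max(abs(sd0$distance + 1)), 0, tolerance = 1e-6)
  expect_equal(gof_metrics(sd0)$pct_seal, 100)
  # uniform +2 mm offset: all gap
  pg <- scene_params(mask_offset = 2, rim_offset = 2,
                     perturbation = rt_identity())
  g <- make_mask(face, pg)
  sdg <- signed_distances(g$internal, face)
  expect_equal(max(abs(sdg$distance - 2)), 0, tolerance = 1e-6)
  expect_equal(gof_metrics(sdg)$pct_gap, 100)
  # region outside the face extent is rejected
  expect_error(make_mask(face, scene_params(mask_xlim = c(-200, 40))),
               "outside the face extent")
})

test_that("the loaded face realises the prescribed displacement field", {
  p <- scene_params(resolution = 60, perturbation = rt_identity())
  face <- make_face(p)$mesh
  lf <- make_loaded_face(face, p)
  # depth 0 / bulge 0 / noise 0 leaves the face untouched
  p0 <- scene_params(resolution = 60, indent_depth = 0, bulge_height = 0,
                     perturbation = rt_identity())
  lf0 <- make_loaded_face(face, p0)
  expect_identical(lf0$mesh$vertices, face$vertices)
  expect_equal(unname(lf0$percentiles), c(0, 0))
  # analytic percentiles hit the prescribed plateau extremes
  expect_equal(unname(lf$percentiles["p_low"]), -p$indent_depth,
               tolerance = 0.1)
  expect_equal(unname(lf$percentiles["p_high"]), p$bulge_height,
               tolerance = 0.1)
  # prescribed field bounds are respected by construction
  expect_true(all(lf$field >= -p$indent_depth - 1e-12))
  expect_true(all(lf$field <= p$bulge_height + 1e-12))
})

test_that("scenes write to STL plus sidecar and read back identically", {
  dir <- withr::local_tempdir()
  sc <- make_scene(scene_params(resolution = 40))
  write_scene(sc, dir)
  files <- list.files(dir)
  expect_length(grep("\\.stl$", files), 6L)
  expect_true("ground_truth.json" %in% files)
  back <- read_stl(file.path(dir, "reference_head.stl"))
  expect_equal(nrow(back$vertices), n_vertices(sc$reference_head))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(gt$percentiles),
               c(p_low = unname(sc$ground_truth$percentiles["p_low"]),
                 p_high = unname(sc$ground_truth$percentiles["p_high"])))
  expect_equal(gt$params$resolution, 40)
})
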