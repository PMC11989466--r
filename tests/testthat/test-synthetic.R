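test_that("synthetic scapulae are watertight with the entry point on the face", {
  sp <- fixture_scapula()
  expect_gt(mesh_volume(sp$mesh), 0)
  # entry lies on the fitted baseplate plane
  expect_lt(abs(sum((sp$frame$entry - colMeans(sp$landmarks$face_points)) *
                      sp$frame$lateral)), 1e-6)
  # all face points are coplanar with zero residual
  pl <- fit_plane(sp$landmarks$face_points)
  expect_lt(pl$rms, 1e-9)
})

test_that("scapula generation is deterministic per seed and varies across seeds", {
  a <- generate_scapula(scapula_params(seed = 8))
  b <- generate_scapula(scapula_params(seed = 8))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  d <- generate_scapula(scapula_params(seed = 9))
  expect_false(identical(a$mesh$vertices, d$mesh$vertices))
})

test_that("a wider pillar recession strictly enlarges the inferior joint volume", {
  v <- vapply(c(90, 120), function(ang) {
    sp <- generate_scapula(scapula_params(pillar_angle = ang, seed = 3))
    compute_joint_volumes(sp$mesh, sp$frame, "36+0", n_samples = 4e5,
                          seed = 6)$inferior
  }, numeric(1))
  expect_lt(v[1], v[2])
})

test_that("parameter validation rejects out-of-range anatomies", {
  expect_error(scapula_params(pillar_angle = 70),
               class = "glenovol_invalid_input")
  expect_error(scapula_params(glenoid_face_radius = -1),
               class = "glenovol_invalid_input")
})

test_that("geometric cohorts alternate sides and reproduce under a seed", {
  specs <- generate_cohort_meshes(6, seed = 2)
  expect_length(specs, 6)
  sides <- vapply(specs, function(s) s$landmarks$side, character(1))
  expect_equal(sum(sides == "right"), 3)
  specs2 <- generate_cohort_meshes(6, seed = 2)
  expect_identical(specs[[3]]$mesh$vertices, specs2[[3]]$mesh$vertices)
})

test_that("truncated-normal calibration matches the reference means exactly in expectation", {
  tab <- table1_reference()
  for (i in seq_len(nrow(tab))) {
    sd_i <- (tab$inferior_max[i] - tab$inferior_min[i]) / 4
    mu <- glenovol:::truncnorm_location(tab$inferior_mean[i], sd_i,
                                        tab$inferior_min[i],
                                        tab$inferior_max[i])
    expect_equal(glenovol:::truncnorm_mean(mu, sd_i, tab$inferior_min[i],
                                           tab$inferior_max[i]),
                 tab$inferior_mean[i], tolerance = 1e-6)
  }
})

test_that("the parametric cohort is calibrated to the reference table", {
  cohort <- generate_statistical_cohort(34, generative_model_params(seed = 1))
  expect_equal(nrow(cohort), 34 * 7)
  tab <- table1_reference()
  cfgs <- glenosphere_configs()$name
  m <- tapply(cohort$inferior, factor(cohort$config, levels = cfgs), mean)
  expect_true(all(abs(m / tab$inferior_mean - 1) < 0.10))
  # volumes respect the printed min-max envelopes
  for (i in seq_along(cfgs)) {
    v <- cohort$inferior[cohort$config == cfgs[i]]
    expect_true(all(v >= tab$inferior_min[i] & v <= tab$inferior_max[i]))
  }
  expect_true(all(cohort$anteroinferior > 0 & cohort$posteroinferior > 0))
  expect_equal(cohort$anteroinferior + cohort$posteroinferior,
               cohort$inferior, tolerance = 1e-12)
})

test_that("a zero link slope decouples mobility from volume", {
  params <- generative_model_params(link_slope = 0, seed = 3)
  cohort <- generate_statistical_cohort(34, params)
  r <- cor(cohort$inferior, cohort$ER1)
  expect_lt(abs(r), 0.15)
})

test_that("a positive link orders per-config mobility means by volume", {
  cohort <- generate_statistical_cohort(34, generative_model_params(seed = 4))
  cfgs <- glenosphere_configs()$name
  vol <- tapply(cohort$inferior, factor(cohort$config, levels = cfgs), mean)
  er <- tapply(cohort$ER1, factor(cohort$config, levels = cfgs), mean)
  expect_true(all(diff(er[order(vol)]) > 0))
})

test_that("cohorts are reproducible per seed and differ across seeds", {
  a <- generate_statistical_cohort(10, generative_model_params(seed = 5))
  b <- generate_statistical_cohort(10, generative_model_params(seed = 5))
  expect_identical(a, b)
  d <- generate_statistical_cohort(10, generative_model_params(seed = 6))
  expect_false(identical(a$inferior, d$inferior))
})
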