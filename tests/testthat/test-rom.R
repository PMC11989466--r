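test_that("collision detects overlap, misses disjoint solids, and is symmetric", {
  a <- mesh_cuboid(c(0, 0, 0), c(1, 1, 1))
  b <- mesh_cuboid(c(11, 0, 0), c(12, 1, 1))
  expect_false(collision(a, b))
  expect_true(collision(a, mesh_cuboid(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8))))
  c1 <- mesh_cuboid(c(0.5, 0.5, 0.5), c(2, 2, 2))
  expect_true(collision(a, c1))
  expect_true(collision(c1, a))
  open_mesh <- triangle_mesh(a$vertices, a$faces[-1, ], validate = FALSE)
  expect_error(collision(open_mesh, b), class = "glenovol_open_mesh")
})

test_that("sphere-pair collisions match the analytic center-distance rule", {
  s1 <- mesh_icosphere(5, c(0, 0, 0), 3)
  s2t <- mesh_icosphere(5, c(9.9, 0, 0), 3)   # sum of radii - 0.1
  s2f <- mesh_icosphere(5, c(10.1, 0, 0), 3)  # sum of radii + 0.1
  expect_true(collision(s1, s2t))
  expect_false(collision(s1, s2f))
})

test_that("unobstructed sweeps reach the scan limits", {
  fr <- test_frame()
  far <- mesh_cuboid(c(200, 200, 200), c(210, 210, 210))
  rot <- max_rotation(far, fr, "36+0")
  expect_equal(rot$angle, 150)
  expect_equal(rot$limiting_contact, "none")
  add <- max_adduction(far, fr, "36+0")
  expect_equal(add$adduction, 40)
  expect_equal(add$limiting_contact, "none")
})

test_that("a constructed obstacle limits external rotation at its known contact angle", {
  fr <- test_frame()
  cfg <- config_by_name("36+0")
  hc <- glenovol:::default_hconfig(cfg)
  ctr <- sphere_center(fr, cfg)
  hm0 <- humeral_mesh(hc, ctr, 20, 0, fr)
  axes <- glenovol:::pose_axes(fr, 20, 0, hc$neck_shaft_angle)
  # external rotation (right side) rotates vertices by +theta about the
  # shaft axis; verify the sense before relying on it
  rot5 <- glenovol:::rotation_about(axes$shaft, 5 * pi / 180)
  hm5 <- humeral_mesh(hc, ctr, 20, 5, fr)
  expect_equal(sweep(sweep(hm0$vertices, 2, ctr) %*% t(rot5), 2, ctr, "+"),
               hm5$vertices, tolerance = 1e-9)
  ob <- ball_obstacle(hm0$vertices, ctr, axes$shaft, 40)
  res <- max_rotation(ob$mesh, fr, cfg, hc, "external")
  expect_lt(abs(res$angle - ob$theta), 0.5)
})

test_that("a constructed obstacle limits adduction at its known contact angle", {
  fr <- test_frame()
  cfg <- config_by_name("36+0")
  hc <- glenovol:::default_hconfig(cfg)
  ctr <- sphere_center(fr, cfg)
  hm0 <- humeral_mesh(hc, ctr, 20, 0, fr)
  # Adduction (decreasing abduction) is a positive rigid rotation about
  # the anterior axis through the sphere center; verify the sense first.
  axis <- fr$anterior
  hm19 <- humeral_mesh(hc, ctr, 19, 0, fr)
  rot1 <- glenovol:::rotation_about(axis, 1 * pi / 180)
  expect_equal(sweep(sweep(hm0$vertices, 2, ctr) %*% t(rot1), 2, ctr, "+"),
               hm19$vertices, tolerance = 1e-9)
  ob <- ball_obstacle(hm0$vertices, ctr, axis, 30)
  res <- max_adduction(ob$mesh, fr, cfg, hc)
  # contact at alpha = 20 - theta, reported as adduction -(20 - theta)
  expect_lt(abs(res$adduction - (ob$theta - 20)), 0.5)
})

test_that("rotation and adduction limits are reproducible and labelled", {
  sp <- fixture_scapula()
  a <- measure_rom(sp$mesh, sp$frame, "36+2")
  b <- measure_rom(sp$mesh, sp$frame, "36+2")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$limiting_contact %in%
                    c("inferior", "anterior", "posterior", "none")))
  expect_gte(a$ER1, 0)
  expect_gte(a$IR1, 0)
})

test_that("removing bone never decreases range of motion", {
  sp <- fixture_scapula()
  full <- measure_rom(sp$mesh, sp$frame, "36+0")
  # a distant cuboid is a strict subset of obstructing bone
  far <- mesh_cuboid(c(300, 300, 300), c(310, 310, 310))
  free <- measure_rom(far, sp$frame, "36+0")
  expect_gte(free$ER1, full$ER1)
  expect_gte(free$IR1, full$IR1)
  expect_gte(free$adduction, full$adduction)
})

test_that("rotations at 20 degrees abduction do not exceed those at 52 degrees", {
  sp <- fixture_scapula()
  for (cf in c("36+0", "42+0")) {
    lo <- max_rotation(sp$mesh, sp$frame, cf, abduction = 20)
    hi <- max_rotation(sp$mesh, sp$frame, cf, abduction = 52)
    expect_lte(lo$angle, hi$angle)
  }
})
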