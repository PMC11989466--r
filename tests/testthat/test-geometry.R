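test_that("plane fit recovers exact planes and orients toward the reference", {
  pts <- rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2), c(3, -1, 2))
  pl <- fit_plane(pts, ref_point = c(0, 0, -5))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$rms, 0, tolerance = 1e-9)
  expect_lt(sum(pl$normal * (c(0, 0, -5) - pl$point)), 0)

  tri <- rbind(c(0, 0, 0), c(2, 0, 1), c(0, 3, -1))
  pl3 <- fit_plane(tri)
  expect_equal(abs(as.numeric(tri %*% pl3$normal) -
                     sum(pl3$point * pl3$normal)),
               rep(0, 3), tolerance = 1e-9)
})

test_that("plane fit on noisy samples matches the eigen-decomposition oracle", {
  set.seed(31)
  n <- 200
  true_n <- c(1, 2, -1) / sqrt(6)
  basis <- svd(matrix(true_n))$u
  e1 <- svd(diag(3) - true_n %*% t(true_n))$u[, 1]
  e2 <- glenovol:::cross3(true_n, e1)
  uv <- matrix(runif(2 * n, -20, 20), ncol = 2)
  pts <- uv[, 1] %o% e1 + uv[, 2] %o% e2 +
    matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
  pl <- fit_plane(pts)
  # oracle: smallest eigenvector of the centered covariance
  cc <- cov(scale(pts, scale = FALSE))
  oracle_n <- eigen(cc)$vectors[, 3]
  expect_lt(acos(min(1, abs(sum(pl$normal * oracle_n)))) * 180 / pi, 1e-6)
  expect_lt(acos(min(1, abs(sum(pl$normal * true_n)))) * 180 / pi, 1)
})

test_that("plane fit is equivariant under rigid motions", {
  set.seed(5)
  pts <- cbind(runif(40, -10, 10), runif(40, -10, 10), rnorm(40, sd = 0.2))
  rot <- glenovol:::rotation_about(c(2, 1, 1), 0.7)
  tr <- c(4, -2, 9)
  pl1 <- fit_plane(pts)
  pl2 <- fit_plane(sweep(pts %*% t(rot), 2, tr, "+"))
  expect_equal(abs(sum(pl2$normal * (rot %*% pl1$normal))), 1,
               tolerance = 1e-9)
  expect_equal(pl1$rms, pl2$rms, tolerance = 1e-9)
})

test_that("degenerate plane inputs error", {
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "glenovol_invalid_input")
  line <- outer(seq_len(5), c(1, 2, 3))
  expect_error(fit_plane(line), class = "glenovol_invalid_input")
})

test_that("frames project the superior hint and honor the side flag", {
  pl <- plane(c(0, 0, 0), c(0, 0, 1))
  fr <- build_frame(pl, c(0, 0, 0), c(0, 1, 0), "right")
  expect_equal(fr$superior, c(0, 1, 0))
  expect_equal(fr$anterior, c(-1, 0, 0))
  fr_l <- build_frame(pl, c(0, 0, 0), c(0, 1, 0), "left")
  expect_equal(fr_l$anterior, c(1, 0, 0))
  # out-of-plane hint is projected
  fr2 <- build_frame(pl, c(0, 0, 0), c(0, 1, 1), "right")
  expect_equal(fr2$superior, c(0, 1, 0), tolerance = 1e-12)
  expect_error(build_frame(pl, c(0, 0, 0), c(0, 0, 2)),
               class = "glenovol_invalid_input")
})

test_that("random frames are orthonormal to 1e-9", {
  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    nrm <- rnorm(3)
    hint <- rnorm(3)
    if (sqrt(sum(glenovol:::cross3(nrm, hint)^2)) < 1e-3) next
    fr <- build_frame(plane(rnorm(3), nrm), rnorm(3), hint,
                      sample(c("right", "left"), 1))
    worst <- max(worst,
                 abs(sum(fr$lateral * fr$superior)),
                 abs(sum(fr$lateral * fr$anterior)),
                 abs(sum(fr$superior * fr$anterior)),
                 abs(sqrt(sum(fr$anterior^2)) - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("spherical cap volume matches closed forms and Monte Carlo", {
  expect_equal(spherical_cap_volume(18, 18), 2 / 3 * pi * 18^3,
               tolerance = 1e-12)
  expect_equal(spherical_cap_volume(7, 0), 0)
  # independent Monte Carlo integration oracle
  set.seed(404)
  n <- 1e6
  p <- cbind(runif(n, -18, 18), runif(n, -18, 18), runif(n, 7, 18))
  hit <- rowSums(p^2) < 324   # cap of height h = 11: z > r - h = 7
  mc <- 36 * 36 * 11 * mean(hit)
  se <- 36 * 36 * 11 * sd(hit) / sqrt(n)
  expect_lt(abs(spherical_cap_volume(18, 11) - mc), 3 * se)
  expect_equal(spherical_cap_volume(18, 11), 5448.6, tolerance = 1e-4)
  expect_error(spherical_cap_volume(10, 21),
               class = "glenovol_invalid_input")
})

test_that("cap complements add to the full ball", {
  for (h in c(0.3, 5, 9, 13.2, 17)) {
    expect_equal(spherical_cap_volume(9, h) + spherical_cap_volume(9, 18 - h),
                 ball_volume(9), tolerance = 1e-9)
  }
})

test_that("point membership agrees with the analytic ball", {
  cube <- mesh_cuboid()
  expect_true(point_in_mesh(cube, c(0.5, 0.5, 0.5)))
  expect_false(point_in_mesh(cube, c(2, 0, 0)))
  ico <- fixture_icosphere(18)
  set.seed(88)
  p <- matrix(runif(3 * 1e4, -19, 19), ncol = 3)
  agree <- mean(point_in_mesh(ico, p) == (sqrt(rowSums(p^2)) < 18))
  expect_gte(agree, 0.999)
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, ],
                             validate = FALSE)
  expect_error(point_in_mesh(open_mesh, c(0, 0, 0)),
               class = "glenovol_open_mesh")
})

test_that("Monte Carlo region volumes hit analytic targets within 3 SE", {
  always <- mc_region_volume(function(p) rep(TRUE, nrow(p)),
                             c(0, 0, 0), c(1, 1, 1), 1e4, seed = 1)
  expect_equal(always$volume, 1.0)
  expect_equal(always$se, 0)

  ball <- mc_region_volume(function(p) rowSums(p^2) < 18^2,
                           rep(-18, 3), rep(18, 3), 1e6, seed = 2)
  expect_lt(abs(ball$volume - ball_volume(18)), 3 * ball$se)

  half <- mc_region_volume(function(p) rowSums(p^2) < 18^2 & p[, 3] < 0,
                           rep(-18, 3), rep(18, 3), 1e6, seed = 3)
  expect_lt(abs(half$volume - ball_volume(18) / 2), 3 * half$se)

  expect_error(mc_region_volume(function(p) TRUE, c(0, 0, 0), c(1, 0, 1),
                                1e4), class = "glenovol_invalid_input")
})

test_that("Monte Carlo volumes are bit-for-bit reproducible under a seed", {
  f <- function(p) rowSums(p^2) < 4
  a <- mc_region_volume(f, rep(-2, 3), rep(2, 3), 1e5, seed = 9)
  b <- mc_region_volume(f, rep(-2, 3), rep(2, 3), 1e5, seed = 9)
  expect_identical(a$volume, b$volume)
  d <- mc_region_volume(f, rep(-2, 3), rep(2, 3), 1e5, seed = 10)
  expect_false(identical(a$volume, d$volume))
})
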