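test_that("descriptive summaries use inclusive linear-interpolation quartiles", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(unlist(s),
               c(minimum = 1, q1 = 2, median = 3, q3 = 4, mean = 3,
                 maximum = 5))
  sc <- summarize_values(rep(7, 10))
  expect_true(all(unlist(sc) == 7))
  expect_true(all(diff(unlist(s[c("minimum", "q1", "median", "q3",
                                  "maximum")])) >= 0))
  set.seed(15)
  sn <- summarize_values(rnorm(1000))
  expect_lt(abs(sn$median), 0.1)
  expect_error(summarize_values(numeric(0)),
               class = "glenovol_invalid_input")
})

test_that("the U statistic matches wilcox.test and identical groups give p near 1", {
  set.seed(2)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  res <- mann_whitney_mc(x, y, n_iter = 500, seed = 1)
  expect_equal(res$statistic,
               unname(suppressWarnings(wilcox.test(x, y)$statistic)))
  same <- mann_whitney_mc(c(1, 2, 3, 4), c(1, 2, 3, 4), n_iter = 2000,
                          seed = 2)
  expect_gte(same$p_value, 0.99)
  expect_error(mann_whitney_mc(1, c(2, 3)), class = "glenovol_invalid_input")
})

test_that("Monte Carlo Mann-Whitney p matches the exhaustive permutation oracle", {
  x <- c(1, 2, 3)
  y <- c(10, 11, 12)
  # exhaustive oracle over all 20 assignments of the pooled ranks
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- 3 * 3 / 2
  obs <- abs(sum(r[1:3]) - 6 - mu)
  sets <- combn(6, 3)
  devs <- apply(sets, 2, function(ix) abs(sum(r[ix]) - 6 - mu))
  p_exact <- mean(devs >= obs - 1e-9)
  expect_equal(p_exact, 0.10)
  res <- mann_whitney_mc(x, y, n_iter = 10000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 10001)
})

test_that("Kruskal-Wallis H matches kruskal.test and the exhaustive oracle", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis_mc(g, n_iter = 4000, seed = 4)
  expect_equal(res$statistic,
               unname(kruskal.test(unlist(g),
                                   rep(1:3, each = 2))$statistic),
               tolerance = 1e-12)
  # exhaustive oracle: all 6!/(2!2!2!) = 90 assignments of ranks to groups
  r <- rank(unlist(g))
  lab0 <- rep(1:3, each = 2)
  perms <- list()
  for (a in combn(6, 2, simplify = FALSE)) {
    rest <- setdiff(1:6, a)
    for (b in combn(rest, 2, simplify = FALSE)) {
      lab <- integer(6)
      lab[a] <- 1L; lab[b] <- 2L; lab[setdiff(rest, b)] <- 3L
      perms[[length(perms) + 1L]] <- lab
    }
  }
  expect_length(perms, 90)
  h_obs <- glenovol:::kw_h(r, factor(lab0))
  h_all <- vapply(perms, function(lb) glenovol:::kw_h(r, factor(lb)),
                  numeric(1))
  p_exact <- mean(h_all >= h_obs - 1e-9)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 4001)

  same <- kruskal_wallis_mc(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
                            n_iter = 2000, seed = 5)
  expect_gte(same$p_value, 0.99)
  expect_error(kruskal_wallis_mc(list(1:3, 4:6)),
               class = "glenovol_invalid_input")
})

test_that("Monte Carlo p-values are reproducible under a fixed seed", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10, 1)
  a <- mann_whitney_mc(x, y, n_iter = 1000, seed = 7)
  b <- mann_whitney_mc(x, y, n_iter = 1000, seed = 7)
  expect_identical(a$p_value, b$p_value)
})

test_that("pairwise matrices have unit diagonals and detect strong contrasts", {
  cohort <- generate_statistical_cohort(20, generative_model_params(seed = 8))
  m <- pairwise_matrix(cohort, "ER1", n_iter = 600, seed = 11)
  expect_true(all(diag(m) == 1))
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  expect_lt(m["36+0", "42+0"], 0.05)
  expect_true(all(is.na(m[lower.tri(m)])))
  expect_equal(attr(m, "adjust"), "holm")
  raw <- pairwise_matrix(cohort, "ER1", adjust = FALSE, n_iter = 600,
                         seed = 11)
  expect_true(all(raw[upper.tri(raw)] <= m[upper.tri(m)] + 1e-12))
  small <- cohort[cohort$config != "42+7", ]
  err <- expect_error(pairwise_matrix(small, "ER1", n_iter = 100),
                      class = "glenovol_invalid_input")
  expect_match(conditionMessage(err), "42\\+7")
})

test_that("volume gains round half away from zero", {
  expect_identical(volume_gain(2855.6, 2419.9), 18L)
  expect_identical(volume_gain(5453.5, 2419.9), 125L)
  expect_identical(volume_gain(150, 100), 50L)
  expect_identical(volume_gain(100, 100), 0L)
  expect_identical(volume_gain(1005, 1000), 1L)   # 0.5 rounds away
  expect_identical(volume_gain(900, 1000), -10L)
  expect_error(volume_gain(5, 0), class = "glenovol_invalid_input")
})

test_that("gains tables cover requested configurations and self-reference is zero", {
  g <- gains_table(reference = "36+0", configs = c("36+0", "36+2"))
  expect_true(all(g[, "36+0"] == 0L))
  expect_equal(dim(gains_table(reference = "42+0")), c(3, 6))
  expect_error(gains_table(reference = "39+0"),
               class = "glenovol_invalid_input")
})

test_that("threshold detection lands in the gap between separated clusters", {
  set.seed(19)
  volumes <- c(runif(30, 1000, 4000), runif(30, 6000, 9000))
  rom <- c(rnorm(30, 20, 5), rnorm(30, 90, 5))
  th <- find_threshold(volumes, rom, n_iter = 2000, seed = 20)
  # the selected split separates the two clusters perfectly
  expect_true(all(volumes[1:30] <= th$threshold_raw))
  expect_true(all(volumes[31:60] > th$threshold_raw))
  expect_lt(th$p_value, 0.05)
  expect_equal(th$threshold, round(th$threshold_raw / 500) * 500,
               tolerance = 250)
})

test_that("threshold detection is equivariant to affine rescaling of mobility", {
  set.seed(23)
  volumes <- runif(60, 1000, 9000)
  rom <- 10 + 0.01 * volumes + rnorm(60, 0, 8)
  a <- find_threshold(volumes, rom, n_iter = 500, seed = 24)
  b <- find_threshold(volumes, 3.2 * rom - 40, n_iter = 500, seed = 24)
  expect_identical(a$threshold_raw, b$threshold_raw)
  expect_identical(a$p_value, b$p_value)
})

test_that("a null cohort yields no significant threshold", {
  params <- generative_model_params(link_slope = 0, seed = 26)
  cohort <- generate_statistical_cohort(34, params)
  th <- find_threshold(cohort$inferior, cohort$ER1, n_iter = 2000,
                       seed = 27)
  expect_gt(th$p_value, 0.05)
})

test_that("threshold preconditions are enforced", {
  expect_error(find_threshold(1:5, 1:5), class = "glenovol_invalid_input")
  expect_error(find_threshold(rep(1000, 12), rnorm(12)),
               class = "glenovol_invalid_input")
})
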