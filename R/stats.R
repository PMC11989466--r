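#' Descriptive summary
#'
#' Minimum, quartiles (Q1, median, Q3), mean and maximum of a numeric
#' vector.  Quartiles use the inclusive linear-interpolation convention
#' (type 7 in [stats::quantile()]).
#'
#' @param values non-empty numeric vector.
#' @return data frame with columns `minimum`, `q1`, `median`, `q3`, `mean`,
#'   `maximum`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop_glenovol("invalid_input", "values must be non-empty and non-missing")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  data.frame(minimum = min(values), q1 = q[1], median = q[2], q3 = q[3],
             mean = mean(values), maximum = max(values))
}

# Internal: rank-sum machinery shared by the permutation tests.
mw_u <- function(r, n1) sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

stat_result <- function(statistic, p_value, n_iterations, seed, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_iterations = n_iterations, seed = seed, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%d Monte Carlo iterations)\n",
              x$method, x$statistic, x$p_value, x$n_iterations))
  invisible(x)
}

#' Mann-Whitney test with Monte Carlo permutation p-value
#'
#' Rank-sum U statistic (midranks for ties) with a two-sided p-value
#' estimated by random label permutations: the proportion of permutations
#' whose `|U - E[U]|` is at least the observed one, with the
#' `(b + 1) / (n_iter + 1)` small-sample correction.
#'
#' @param x,y numeric groups, each with at least 2 values.
#' @param n_iter permutation count (default 10000).
#' @param seed optional integer seed.
#' @return a `stat_result`.
#' @export
mann_whitney_mc <- function(x, y, n_iter = 10000, seed = NULL) {
  if (length(x) < 2L || length(y) < 2L)
    stop_glenovol("invalid_input", "both groups need at least 2 values")
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u <- mw_u(r, n1)
  mu <- n1 * (n - n1) / 2
  obs <- abs(u - mu)
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_iter), function(i) {
      abs(sum(r[sample.int(n, n1)]) - n1 * (n1 + 1) / 2 - mu) >= obs - 1e-9
    }, logical(1)))
  })
  stat_result(u, (b + 1) / (n_iter + 1), n_iter, seed,
              "Mann-Whitney U (Monte Carlo permutation)")
}

# Normal-approximation two-sided p for the U statistic, with tie-corrected
# variance.  Deterministic; used to rank candidate thresholds.
mw_normal_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  u <- mw_u(r, n1)
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(p = 1, z = 0, u = u))
  z <- (u - mu) / sqrt(sig2)
  list(p = 2 * pnorm(-abs(z)), z = z, u = u)
}

kw_h <- function(r, g) {
  n <- length(r)
  sums <- tapply(r, g, sum)
  sizes <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  h
}

#' Kruskal-Wallis test with Monte Carlo permutation p-value
#'
#' Tie-corrected H statistic over three or more groups, with the p-value
#' estimated by random permutations of the group labels (same estimator and
#' small-sample correction as [mann_whitney_mc()]).
#'
#' @param groups list of >= 3 numeric vectors, each with >= 2 values.
#' @inheritParams mann_whitney_mc
#' @return a `stat_result`.
#' @export
kruskal_wallis_mc <- function(groups, n_iter = 10000, seed = NULL) {
  if (length(groups) < 3L)
    stop_glenovol("invalid_input", "need at least 3 groups")
  if (any(lengths(groups) < 2L))
    stop_glenovol("invalid_input", "each group needs at least 2 values")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  r <- rank(unlist(groups, use.names = FALSE))
  h <- kw_h(r, g)
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_iter), function(i) {
      kw_h(r, g[sample.int(length(g))]) >= h - 1e-9
    }, logical(1)))
  })
  stat_result(h, (b + 1) / (n_iter + 1), n_iter, seed,
              "Kruskal-Wallis H (Monte Carlo permutation)")
}

#' Pairwise configuration comparison matrix
#'
#' All 21 pairwise Mann-Whitney Monte Carlo comparisons of one variable
#' across the seven glenosphere configurations, arranged as a 7 x 7
#' upper-triangular matrix with unit diagonal.  By default the 21 p-values
#' receive a Holm step-down adjustment (capped at 1); set `adjust = FALSE`
#' for raw permutation p-values.  The adjustment choice is recorded in the
#' result's attributes.
#'
#' @param cohort a `cohort_records` data frame (see
#'   [generate_statistical_cohort()]), or any data frame with `config` and
#'   the requested variable.
#' @param variable one of `"adduction"`, `"ER1"`, `"IR1"`, `"inferior"`,
#'   `"anteroinferior"`, `"posteroinferior"`.
#' @param adjust apply Holm adjustment over the 21 pairs (default `TRUE`).
#' @inheritParams mann_whitney_mc
#' @return matrix of class `pairwise_matrix`; lower triangle is `NA`.
#' @export
pairwise_matrix <- function(cohort,
                            variable = c("adduction", "ER1", "IR1",
                                         "inferior", "anteroinferior",
                                         "posteroinferior"),
                            adjust = TRUE, n_iter = 10000, seed = NULL) {
  variable <- match.arg(variable)
  cfgs <- glenosphere_configs()$name
  missing_cfg <- setdiff(cfgs, unique(cohort$config))
  if (length(missing_cfg))
    stop_glenovol("invalid_input", sprintf(
      "cohort is missing configuration(s): %s",
      paste(missing_cfg, collapse = ", ")))
  vals <- split(cohort[[variable]], factor(cohort$config, levels = cfgs))
  pairs <- combn(7, 2)
  seeds <- if (is.null(seed)) rep(list(NULL), ncol(pairs)) else
    as.list(seed + seq_len(ncol(pairs)))
  praw <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    mann_whitney_mc(vals[[i]], vals[[j]], n_iter = n_iter,
                    seed = seeds[[k]])$p_value
  }, numeric(1))
  padj <- if (adjust) pmin(1, p.adjust(praw, method = "holm")) else praw
  m <- matrix(NA_real_, 7, 7, dimnames = list(cfgs, cfgs))
  diag(m) <- 1
  for (k in seq_len(ncol(pairs))) m[pairs[1, k], pairs[2, k]] <- padj[k]
  structure(m, class = c("pairwise_matrix", "matrix"),
            variable = variable,
            adjust = if (adjust) "holm" else "none",
            n_iterations = n_iter, seed = seed)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentage volume gain between two configuration means
#'
#' `100 * (mean_test / mean_ref - 1)`, rounded half away from zero to an
#' integer percentage.
#'
#' @param mean_test,mean_ref mean volumes (mm^3); `mean_ref` must be
#'   positive.
#' @return integer percentage.
#' @export
volume_gain <- function(mean_test, mean_ref) {
  if (any(mean_ref <= 0))
    stop_glenovol("invalid_input", "reference mean must be positive")
  as.integer(round_half_away(100 * (mean_test - mean_ref) / mean_ref))
}

#' Volume-gain table relative to a reference configuration
#'
#' For each requested configuration, the integer percentage gain of the
#' inferior, anteroinferior and posteroinferior mean volumes over the
#' reference configuration's means.
#'
#' @param means data frame like [table1_reference()] (needs `config` and
#'   the three `*_mean` volume columns).
#' @param reference reference configuration name.
#' @param configs configurations to compare (default: all non-reference).
#' @return integer matrix, rows `inferior`, `anteroinferior`,
#'   `posteroinferior`; one column per configuration.
#' @export
gains_table <- function(means = table1_reference(), reference = "36+0",
                        configs = NULL) {
  if (!reference %in% means$config)
    stop_glenovol("invalid_input",
                  sprintf("reference '%s' not in means table", reference))
  configs <- configs %||% setdiff(means$config, reference)
  missing_cfg <- setdiff(configs, means$config)
  if (length(missing_cfg))
    stop_glenovol("invalid_input", sprintf(
      "means table is missing configuration(s): %s",
      paste(missing_cfg, collapse = ", ")))
  vars <- c(inferior = "inferior_mean", anteroinferior = "anteroinferior_mean",
            posteroinferior = "posteroinferior_mean")
  ref <- means[means$config == reference, ]
  out <- sapply(configs, function(cf) {
    row <- means[means$config == cf, ]
    vapply(vars, function(v) volume_gain(row[[v]], ref[[v]]), integer(1))
  })
  out <- matrix(as.integer(out), nrow = length(vars),
                dimnames = list(names(vars), configs))
  out
}

#' Mobility threshold on a volume/mobility scatter
#'
#' Scans candidate joint-volume thresholds on a regular grid and, at each
#' candidate, compares the mobility of the below-threshold and
#' above-threshold groups with a tie-corrected standardized Mann-Whitney
#' statistic.  The candidate with the largest |Z| is selected (exact ties
#' broken toward the smallest threshold).  The achieved significance is a
#' scan-corrected Monte Carlo permutation p-value: volume/mobility pairings
#' are permuted and the maximal |Z| over the whole candidate grid is
#' recomputed each time, so the reported p accounts for the threshold
#' having been selected by the scan (a max-statistic permutation test); on
#' null data it is calibrated rather than optimistically small.  The
#' reported threshold is rounded to a clinically readable step (default
#' 500 mm^3).
#'
#' @param volumes,rom paired numeric vectors (>= 10 points).
#' @param grid_step candidate spacing (mm^3, default 100).
#' @param round_to rounding of the reported threshold (mm^3, default 500).
#' @param min_group smallest group size allowed on either side of a
#'   candidate split (default 2).
#' @inheritParams mann_whitney_mc
#' @return a `threshold_result`: `threshold` (rounded), `threshold_raw`,
#'   `p_value` (scan-corrected Monte Carlo), `statistic` (max |Z|),
#'   `group_means` (below/above), `grid_step`, `round_to`, `n_candidates`,
#'   `seed`.
#' @export
find_threshold <- function(volumes, rom, grid_step = 100, round_to = 500,
                           n_iter = 10000, seed = NULL, min_group = 2) {
  if (length(volumes) != length(rom))
    stop_glenovol("invalid_input", "volumes and rom must be paired")
  n <- length(volumes)
  if (n < 10L)
    stop_glenovol("invalid_input", "need at least 10 paired points")
  cand <- seq(ceiling(min(volumes) / grid_step) * grid_step,
              floor(max(volumes) / grid_step) * grid_step,
              by = grid_step)
  vs <- sort(volumes)
  n1 <- findInterval(cand, vs)           # below-group size per candidate
  keep <- n1 >= min_group & (n - n1) >= min_group
  cand <- cand[keep]
  n1 <- n1[keep]
  if (length(cand) == 0L)
    stop_glenovol("invalid_input",
                  "no candidate threshold leaves enough points on both sides")
  r <- rank(rom)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  n2 <- n - n1
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  # |Z| per candidate from cumulative rank sums in volume order
  s_obs <- cumsum(r[order(volumes)])
  u_obs <- s_obs[n1] - n1 * (n1 + 1) / 2
  z_obs <- abs(u_obs - mu) / sigma
  best_i <- which.max(z_obs)             # first index on exact ties
  best <- cand[best_i]
  obs <- z_obs[best_i]
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_iter), function(i) {
      s <- cumsum(sample(r))
      u <- s[n1] - n1 * (n1 + 1) / 2
      max(abs(u - mu) / sigma) >= obs - 1e-9
    }, logical(1)))
  })
  below <- volumes <= best
  structure(list(
    threshold = round_half_away(best / round_to) * round_to,
    threshold_raw = best,
    p_value = (b + 1) / (n_iter + 1),
    statistic = obs,
    group_means = c(below = mean(rom[below]), above = mean(rom[!below])),
    grid_step = grid_step,
    round_to = round_to,
    n_candidates = length(cand),
    n_iterations = n_iter,
    seed = seed
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %g mm^3 (grid value %g), p = %.4g\n  mobility means: %.1f below, %.1f above\n",
    x$threshold, x$threshold_raw, x$p_value,
    x$group_means[["below"]], x$group_means[["above"]]))
  invisible(x)
}
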