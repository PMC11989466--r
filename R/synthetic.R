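#' Reference per-configuration descriptive table
#'
#' The packaged per-configuration calibration constants of the emulated
#' cadaveric study: mean, minimum and maximum of adduction, ER1, IR1 and of
#' the inferior, anteroinferior and posteroinferior joint volumes, for each
#' of the seven glenosphere configurations.  Used to calibrate the
#' statistical cohort generator and to build the volume-gain tables.
#'
#' @return data frame, one row per configuration.
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1_descriptives.csv",
                      package = "glenovol", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic scapula parameters
#'
#' Parametric stand-in for a segmented scapula: a flat circular reamed
#' glenoid face, a bone blade of finite anteroposterior thickness, and below
#' the inferior glenoid rim a lateral pillar that recedes medially at
#' `pillar_angle` (the dihedral angle between the glenoid face plane and the
#' pillar surface) while narrowing to the pillar half-width.  Larger pillar
#' angles are the "favorable" morphologies that open inferior joint space.
#'
#' @param glenoid_face_radius radius of the reamed face (mm).
#' @param pillar_angle degrees, in `[80, 130]`.
#' @param pillar_offset vertical distance from the inferior glenoid rim over
#'   which the bone steps medially to the pillar (mm).
#' @param neck_recess medial depth of the scapular neck below the inferior
#'   rim -- how far the pillar surface sits medial to the reamed face (mm);
#'   short necks (small values) are the notching-prone anatomies.
#' @param neck_length superior extent of the neck/body block above the face
#'   center (mm).
#' @param body_extent medial depth and inferior extent of the bone (mm).
#' @param glenoid_halfwidth,pillar_halfwidth anteroposterior half-thickness
#'   of the bone at the glenoid face and along the pillar (mm).
#' @param blade_halfwidth half-thickness of the scapular blade medial to the
#'   glenoid vault (mm).
#' @param face_thickness depth of the full-width glenoid vault behind the
#'   face before the neck starts narrowing (mm).
#' @param neck_taper depth over which the vault narrows to the blade (mm).
#' @param side `"right"` or `"left"`.
#' @param seed integer seed controlling the specimen's rigid placement in
#'   space.
#' @export
scapula_params <- function(glenoid_face_radius = 13.5,
                           pillar_angle = 120,
                           pillar_offset = 5,
                           neck_recess = 7.5,
                           neck_length = 40,
                           body_extent = 60,
                           glenoid_halfwidth = 12,
                           pillar_halfwidth = 6,
                           blade_halfwidth = 6,
                           face_thickness = 4,
                           neck_taper = 6,
                           side = c("right", "left"),
                           seed = 1L) {
  side <- match.arg(side)
  if (pillar_angle < 80 || pillar_angle > 130)
    stop_glenovol("invalid_input", "pillar_angle must lie in [80, 130]")
  if (any(c(glenoid_face_radius, pillar_offset, neck_recess, neck_length,
            body_extent, glenoid_halfwidth, pillar_halfwidth,
            blade_halfwidth, face_thickness, neck_taper) <= 0))
    stop_glenovol("invalid_input", "all lengths must be positive")
  structure(list(glenoid_face_radius = glenoid_face_radius,
                 pillar_angle = pillar_angle,
                 pillar_offset = pillar_offset,
                 neck_recess = neck_recess,
                 neck_length = neck_length,
                 body_extent = body_extent,
                 glenoid_halfwidth = glenoid_halfwidth,
                 pillar_halfwidth = pillar_halfwidth,
                 blade_halfwidth = blade_halfwidth,
                 face_thickness = face_thickness,
                 neck_taper = neck_taper,
                 side = side,
                 seed = as.integer(seed)),
            class = "scapula_params")
}

# Bone cross-section at height y (local coords: x lateral, y superior,
# z anterior): a symmetric "vase" polygon -- a full-width slab behind the
# reamed face, a neck narrowing over `neck_taper`, then the thin blade.
# Below the inferior rim the lateral boundary recedes medially at the pillar
# angle and the section half-width tapers to the pillar half-width.
# Returns the 8 polygon corners in counterclockwise (x, z) order.
scapula_section <- function(params, y) {
  g <- params$glenoid_face_radius
  y_rim <- -g
  slope <- tan((params$pillar_angle - 90) * pi / 180)
  below <- max(0, y_rim - y)
  x_lat <- -params$neck_recess * min(1, below / params$pillar_offset) -
    below * slope
  # Above the rim the bone follows the pear-shaped glenoid outline: the
  # half-width narrows elliptically toward the inferior rim; below the rim
  # only the pillar half-width remains.
  wf <- if (y >= y_rim) {
    yy <- min(y, 0)
    max(params$pillar_halfwidth,
        params$glenoid_halfwidth * sqrt(max(0, 1 - (yy / g)^2)))
  } else {
    params$pillar_halfwidth
  }
  wb <- min(params$blade_halfwidth, wf)
  x_f <- x_lat - params$face_thickness
  x_n <- x_f - params$neck_taper
  x_b <- -params$body_extent
  cbind(x = c(x_b, x_n, x_f, x_lat, x_lat, x_f, x_n, x_b),
        z = c(-wb, -wb, -wf, -wf, wf, wf, wb, wb))
}

#' Generate a synthetic scapula
#'
#' Builds the watertight parametric bone solid, places it in space with a
#' seeded random rigid motion, and derives the glenoid frame the way a real
#' specimen would be processed: annotated face points are fit with a
#' total-least-squares plane, the normal oriented away from the bone
#' centroid, and the frame assembled from the entry point and a superior
#' hint.
#'
#' @param params a [scapula_params()].
#' @return list with `mesh` ([triangle_mesh()]), `frame`
#'   ([glenoid_frame()]), and `landmarks` (entry, face points, superior
#'   hint, side).
#' @export
generate_scapula <- function(params) {
  stopifnot(inherits(params, "scapula_params"))
  g <- params$glenoid_face_radius
  y_rim <- -g
  # Cross-section breakpoints: both boundary functions are piecewise linear
  # with breaks at the rim and at the end of the blade taper.
  ys <- sort(unique(c(-params$body_extent, y_rim - params$pillar_offset,
                      y_rim, y_rim * c(0.9, 0.75, 0.55, 0.3), 0,
                      params$neck_length)))
  k <- 8L
  rings <- lapply(ys, function(y) {
    s <- scapula_section(params, y)
    cbind(s[, "x"], y, s[, "z"])
  })
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  idx <- function(ring, corner) (ring - 1L) * k + corner
  faces <- list()
  nxt <- c(seq_len(k)[-1], 1L)
  for (ring in seq_len(nr - 1L)) for (cnr in seq_len(k)) {
    a <- idx(ring, cnr); b <- idx(ring, nxt[cnr])
    cc <- idx(ring + 1L, cnr); d <- idx(ring + 1L, nxt[cnr])
    faces[[length(faces) + 1L]] <- c(a, b, d)
    faces[[length(faces) + 1L]] <- c(a, d, cc)
  }
  # End caps: fixed triangulation of the (non-convex) vase octagon into the
  # tail, neck and head quadrilaterals; inferior cap wound opposite to the
  # superior one.
  cap <- rbind(c(1L, 2L, 7L), c(1L, 7L, 8L),
               c(2L, 3L, 6L), c(2L, 6L, 7L),
               c(3L, 4L, 5L), c(3L, 5L, 6L))
  for (tr in seq_len(nrow(cap))) {
    faces[[length(faces) + 1L]] <- idx(1L, cap[tr, c(1L, 3L, 2L)])
    faces[[length(faces) + 1L]] <- idx(nr, cap[tr, ])
  }
  f <- do.call(rbind, faces)
  local_mesh <- triangle_mesh(verts, f, validate = FALSE)
  vol <- tryCatch(mesh_volume(local_mesh),
                  glenovol_error = function(e) NA_real_)
  if (is.na(vol))
    local_mesh <- triangle_mesh(verts, f[, c(1, 3, 2)], validate = FALSE)

  # Face landmark points on the reamed glenoid (x = 0 disk), sunflower
  # layout, and a seeded rigid placement of the whole specimen.
  npts <- 25
  i <- seq_len(npts)
  rad <- 0.85 * min(g, params$glenoid_halfwidth) * sqrt(i / npts)
  ang <- i * 2.399963
  face_pts <- cbind(0, rad * cos(ang), rad * sin(ang))
  entry <- c(0, 0, 0)

  placement <- with_seed(params$seed, {
    axis <- normalize3(rnorm(3))
    list(rot = rotation_about(axis, runif(1, 0, 2 * pi)),
         tr = runif(3, -50, 50))
  })
  place <- function(p) {
    p <- p %*% t(placement$rot)
    sweep(p, 2, placement$tr, "+")
  }
  mesh <- triangle_mesh(place(local_mesh$vertices), local_mesh$faces,
                        validate = FALSE)
  face_pts <- place(face_pts)
  entry <- as.numeric(place(matrix(entry, ncol = 3)))
  hint <- as.numeric(placement$rot %*% c(0, 1, 0))

  pl <- fit_plane(face_pts, ref_point = colMeans(mesh$vertices))
  frame <- build_frame(pl, entry, hint, side = params$side)
  list(mesh = mesh,
       frame = frame,
       landmarks = list(entry = entry, face_points = face_pts,
                        superior_hint = hint, side = params$side))
}

#' Generate a geometric cohort of synthetic specimens
#'
#' Draws per-specimen anatomy from uniform ranges (glenoid face radius
#' 13--16 mm, pillar angle 95--120 degrees, pillar offset 2--5 mm), with
#' sides alternating right/left, and builds each specimen with
#' [generate_scapula()].  Reproducible for a fixed seed.
#'
#' @param n number of specimens (default 34).
#' @param seed integer seed.
#' @return list of specimen lists (`mesh`, `frame`, `landmarks`, `params`).
#' @export
generate_cohort_meshes <- function(n = 34, seed = 1L) {
  draws <- with_seed(seed, {
    data.frame(face = runif(n, 13, 16),
               angle = runif(n, 95, 120),
               offset = runif(n, 2, 5),
               recess = runif(n, 5, 8),
               pseed = sample.int(2^30, n))
  })
  lapply(seq_len(n), function(i) {
    p <- scapula_params(
      glenoid_face_radius = draws$face[i],
      pillar_angle = draws$angle[i],
      pillar_offset = draws$offset[i],
      neck_recess = draws$recess[i],
      side = if (i %% 2 == 1) "right" else "left",
      seed = draws$pseed[i])
    out <- generate_scapula(p)
    out$params <- p
    out$specimen_id <- sprintf("S%02d", i)
    out
  })
}

#' Generative model parameters for the statistical cohort
#'
#' Defaults are calibrated to the packaged reference table: per-config
#' inferior volumes follow a truncated normal with the reference mean,
#' standard deviation `(max - min) / 4`, truncated at the printed min--max;
#' each mobility variable follows a linear monotone link on the inferior
#' volume (`rom = a + b * volume + noise`) whose slope and intercept are the
#' least-squares fit through the seven reference (volume mean, mobility
#' mean) pairs; Gaussian noise with 15 degree standard deviation.
#'
#' @param volume_table data frame like [table1_reference()].
#' @param noise_sd mobility noise standard deviation (degrees).
#' @param link_slope,link_intercept optional named overrides (per variable
#'   `ER1`, `IR1`, `adduction`); `link_slope` may also be a single number
#'   applied to all three (use 0 for a null, no-link model).
#' @param share_sd noise on the anteroinferior share of the inferior volume.
#' @param seed integer seed.
#' @export
generative_model_params <- function(volume_table = table1_reference(),
                                    noise_sd = 15,
                                    link_slope = NULL,
                                    link_intercept = NULL,
                                    share_sd = 0.03,
                                    seed = 1L) {
  tab <- volume_table
  fits <- lapply(c(ER1 = "er1_mean", IR1 = "ir1_mean",
                   adduction = "adduction_mean"),
                 function(col) coef(lm(tab[[col]] ~ tab$inferior_mean)))
  slopes <- vapply(fits, `[[`, numeric(1), 2)
  intercepts <- vapply(fits, `[[`, numeric(1), 1)
  if (!is.null(link_slope)) {
    if (length(link_slope) == 1 && is.null(names(link_slope)))
      slopes[] <- link_slope
    else slopes[names(link_slope)] <- link_slope
  }
  if (!is.null(link_intercept))
    intercepts[names(link_intercept) %||% names(intercepts)] <- link_intercept
  if (any(slopes < 0))
    stop_glenovol("invalid_input",
                  "link slopes must be non-negative (monotone link)")
  structure(list(volume_table = tab,
                 noise_sd = noise_sd,
                 slopes = slopes,
                 intercepts = intercepts,
                 share_sd = share_sd,
                 seed = as.integer(seed)),
            class = "generative_model_params")
}

# Exact truncated-normal draws via inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# Location parameter for which the [lo, hi]-truncated normal has the target
# mean; the printed min-max envelopes are asymmetric about the printed
# means, so the raw location must be offset to match them.
truncnorm_location <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
                 lower = lo - 2 * sd, upper = hi + 2 * sd,
                 tol = 1e-8)$root
}

#' Generate a parametric statistical cohort
#'
#' Fast, geometry-free emulation of the study's measurement table: for each
#' specimen and configuration the inferior joint volume is drawn from the
#' config's truncated normal, split into anteroinferior/posteroinferior
#' parts by a noisy share, and the three mobility variables are produced by
#' the monotone linear link plus Gaussian noise, clamped to plausible
#' instrument bounds (rotations in `[0, 150]`, adduction in `[-40, 40]`
#' degrees).  Designed for threshold and test validation at thousands of
#' replicates.
#'
#' @param n_specimens specimens per configuration (default 34).
#' @param params a [generative_model_params()].
#' @return a `cohort_records` data frame: `specimen_id`, `side`, `config`,
#'   `inferior`, `anteroinferior`, `posteroinferior` (mm^3), `adduction`,
#'   `ER1`, `IR1` (degrees).
#' @export
generate_statistical_cohort <- function(n_specimens = 34,
                                        params = generative_model_params()) {
  tab <- params$volume_table
  out <- with_seed(params$seed, {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      cfg <- tab$config[i]
      sd_i <- (tab$inferior_max[i] - tab$inferior_min[i]) / 4
      mu_i <- truncnorm_location(tab$inferior_mean[i], sd_i,
                                 tab$inferior_min[i], tab$inferior_max[i])
      inf <- rtruncnorm(n_specimens, mu_i, sd_i,
                        tab$inferior_min[i], tab$inferior_max[i])
      share <- pmin(0.8, pmax(0.2, rnorm(
        n_specimens, tab$anteroinferior_mean[i] / tab$inferior_mean[i],
        params$share_sd)))
      ai <- share * inf
      pi_ <- inf - ai
      link <- function(var, lo, hi)
        pmin(hi, pmax(lo, params$intercepts[[var]] +
                        params$slopes[[var]] * inf +
                        rnorm(n_specimens, 0, params$noise_sd)))
      data.frame(specimen_id = sprintf("S%02d", seq_len(n_specimens)),
                 side = rep_len(c("right", "left"), n_specimens),
                 config = cfg,
                 inferior = inf,
                 anteroinferior = ai,
                 posteroinferior = pi_,
                 adduction = link("adduction", -40, 40),
                 ER1 = link("ER1", 0, 150),
                 IR1 = link("IR1", 0, 150),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  class(out) <- c("cohort_records", "data.frame")
  attr(out, "seed") <- params$seed
  out
}
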