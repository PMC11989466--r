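#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to a set
#' of annotated points (the reamed glenoid face).  The normal is taken from
#' the smallest principal direction of the centered point cloud and, when a
#' reference point is given (typically the bone centroid), oriented so that
#' the reference lies on the negative -- medial -- side.  The oriented normal
#' is the lateral direction of the glenoid frame.
#'
#' @param points numeric matrix (>= 3 rows) of 3D points (mm).
#' @param ref_point optional 3-vector; the fitted normal is flipped if needed
#'   so that `ref_point` has a negative signed distance.
#' @return a `plane` object: `point` (centroid), unit `normal`, and `rms`
#'   orthogonal residual.
#' @export
fit_plane <- function(points, ref_point = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop_glenovol("invalid_input", "plane fit needs at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop_glenovol("invalid_input", "points are collinear; plane is undefined")
  normal <- sv$v[, 3]
  if (!is.null(ref_point) && sum(normal * (ref_point - ctr)) > 0)
    normal <- -normal
  plane(ctr, normal, rms = sqrt(mean((x %*% sv$v[, 3])^2)))
}

#' Plane constructor
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized on construction.
#' @param rms optional orthogonal-fit residual (mm).
#' @export
plane <- function(point, normal, rms = NA_real_) {
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12)
    stop_glenovol("invalid_input", "plane normal must be nonzero")
  structure(list(point = as.numeric(point),
                 normal = as.numeric(normal) / nn,
                 rms = rms),
            class = "plane")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Glenoid reference frame
#'
#' Anatomical frame anchored at the baseplate entry point (the center of the
#' glenoid plate stud hole): `lateral` is the baseplate-plane normal pointing
#' away from the bone, `superior` and `anterior` lie in the baseplate plane.
#' All glenosphere offsets and the quadrant splitting planes are expressed in
#' this frame.  For right shoulders `(lateral, superior, anterior)` is
#' right-handed; for left shoulders the anterior axis is mirrored so that
#' anteroinferior/posteroinferior labels stay anatomically consistent.
#'
#' @param entry 3-vector (mm).
#' @param lateral,superior,anterior unit 3-vectors, mutually orthogonal.
#' @param side `"right"` or `"left"`.
#' @export
glenoid_frame <- function(entry, lateral, superior, anterior,
                          side = c("right", "left")) {
  side <- match.arg(side)
  fr <- structure(list(entry = as.numeric(entry),
                       lateral = normalize3(as.numeric(lateral)),
                       superior = normalize3(as.numeric(superior)),
                       anterior = normalize3(as.numeric(anterior)),
                       side = side),
                  class = "glenoid_frame")
  assert_frame(fr)
  fr
}

assert_frame <- function(frame, tol = 1e-9) {
  d <- c(abs(sum(frame$lateral * frame$superior)),
         abs(sum(frame$lateral * frame$anterior)),
         abs(sum(frame$superior * frame$anterior)))
  if (any(d > tol))
    stop_glenovol("invalid_input", sprintf(
      "frame axes not orthogonal (max |dot| = %.3g)", max(d)))
  invisible(frame)
}

#' Build a glenoid frame from a fitted baseplate plane
#'
#' `lateral` is the plane normal; `superior` is the in-plane projection of a
#' superior-direction hint; `anterior` completes the frame via the cross
#' product, mirrored for left shoulders.
#'
#' @param plane a [plane()] with normal pointing laterally (away from bone).
#' @param entry baseplate entry point (mm).
#' @param superior_hint approximate superior direction; must not be parallel
#'   to the plane normal.
#' @param side `"right"` or `"left"`.
#' @export
build_frame <- function(plane, entry, superior_hint,
                        side = c("right", "left")) {
  side <- match.arg(side)
  lateral <- plane$normal
  sup <- superior_hint - sum(superior_hint * lateral) * lateral
  if (sqrt(sum(sup^2)) < 1e-9 * sqrt(sum(superior_hint^2)))
    stop_glenovol("invalid_input",
                  "superior hint is parallel to the plane normal")
  sup <- normalize3(sup)
  ant <- cross3(lateral, sup)
  if (side == "left") ant <- -ant
  glenoid_frame(entry, lateral, sup, ant, side)
}

#' Spherical cap volume
#'
#' Closed-form volume `pi * h^2 * (3 r - h) / 3` of the cap of height `h` cut
#' from a ball of radius `r`; the analytic oracle for plane-cut spheres.
#'
#' @param r ball radius (mm).
#' @param h cap height (mm), in `[0, 2 r]`.
#' @return volume in mm^3.
#' @export
spherical_cap_volume <- function(r, h) {
  if (any(r < 0)) stop_glenovol("invalid_input", "radius must be >= 0")
  if (any(h < 0 | h > 2 * r))
    stop_glenovol("invalid_input", "cap height must lie in [0, 2r]")
  pi * h^2 * (3 * r - h) / 3
}

#' Point-in-mesh membership
#'
#' Ray-parity test against a watertight mesh.  Points within about 1e-6 mm of
#' the surface are in an undefined-behaviour band and may report either
#' value.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param points 3-vector or `n x 3` matrix (mm).
#' @return logical vector, `TRUE` for strictly interior points.
#' @export
point_in_mesh <- function(mesh, points) {
  assert_closed(mesh)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .cpp_points_in_mesh(mesh$vertices, mesh$faces, points)
}

#' Monte Carlo volume of an implicitly defined region
#'
#' Estimates the volume of `{p : indicator(p)}` inside an axis-aligned box by
#' uniform sampling: `volume = box_volume * hit_fraction`, with binomial
#' standard error `box_volume * sqrt(p (1 - p) / n)`.  This is the volumetric
#' backend for all joint-volume measurements: the regions of interest are
#' intersections of a ball, half-spaces and the complement of a bone mesh,
#' which compose robustly as predicates where exact mesh booleans are
#' fragile.
#'
#' @param indicator function taking an `n x 3` matrix, returning a logical
#'   vector.
#' @param lower,upper box corners (mm); the box must enclose the region.
#' @param n_samples number of uniform samples (>= 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list with `volume`, `se` (mm^3), `n_samples`, `seed`.
#' @export
mc_region_volume <- function(indicator, lower, upper, n_samples = 2e6,
                             seed = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(upper <= lower))
    stop_glenovol("invalid_input", "empty bounding box")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1000L)
    stop_glenovol("invalid_input", "n_samples must be >= 1000")
  box_vol <- prod(upper - lower)
  hits <- with_seed(seed, {
    p <- matrix(runif(3 * n_samples), ncol = 3)
    p <- sweep(sweep(p, 2, upper - lower, "*"), 2, lower, "+")
    sum(indicator(p))
  })
  frac <- hits / n_samples
  list(volume = box_vol * frac,
       se = box_vol * sqrt(frac * (1 - frac) / n_samples),
       n_samples = n_samples,
       seed = seed)
}

# Rodrigues rotation matrix about unit axis `u` by `theta` (radians).
rotation_about <- function(u, theta) {
  u <- normalize3(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
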