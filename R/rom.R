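#' Bony collision between two watertight meshes
#'
#' `TRUE` iff the meshes intersect: any edge of one crosses a face of the
#' other, or one mesh lies entirely inside the other.  Symmetric in its
#' arguments.  This is the impingement predicate: contact between the
#' humeral-component solid and the scapula ends a sweep.
#'
#' @param a,b closed [triangle_mesh()] objects.
#' @export
collision <- function(a, b) {
  assert_closed(a, "mesh a")
  assert_closed(b, "mesh b")
  .cpp_mesh_collision(a$vertices, a$faces, b$vertices, b$faces)
}

# Classify where the humeral component touches the scapula, in frame
# coordinates: inferior contact sits below the entry point, otherwise
# anterior/posterior by the sign of the anterior coordinate.
contact_label <- function(scapula, humeral, frame) {
  pts <- rbind(humeral$vertices, face_centroids(humeral))
  inside <- .cpp_points_in_mesh(scapula$vertices, scapula$faces, pts)
  if (!any(inside)) {
    pts <- rbind(scapula$vertices, face_centroids(scapula))
    inside <- .cpp_points_in_mesh(humeral$vertices, humeral$faces, pts)
  }
  if (!any(inside)) return("none")
  q <- colMeans(pts[inside, , drop = FALSE])
  d <- q - frame$entry
  s <- sum(d * frame$superior)
  a <- sum(d * frame$anterior)
  if (s < -abs(a)) "inferior" else if (a > 0) "anterior" else "posterior"
}

face_centroids <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Default humeral component matched to the glenosphere: the liner's
# polyethylene depth is fixed, so its angular coverage shrinks as the
# sphere grows (cos theta = 1 - depth / R).
default_hconfig <- function(config, cup_depth = 4) {
  humeral_config(config$radius,
                 cup_half_angle = acos(1 - cup_depth / config$radius) *
                   180 / pi)
}

posed_humeral <- function(frame, config, hconfig, abduction, rotation) {
  humeral_mesh(hconfig, sphere_center(frame, config), abduction, rotation,
               frame)
}

# Coarse scan + bisection over a monotone pose parameter.  `collides(x)`
# must be FALSE at `from`; returns the last collision-free value (within
# `tol`) plus the first colliding value, or `to` if the sweep is never
# limited.
sweep_limit <- function(collides, from, to, step, tol) {
  xs <- seq(from, to, by = if (to >= from) step else -step)
  if (xs[length(xs)] != to) xs <- c(xs, to)
  hit <- NA_real_
  free <- from
  for (x in xs[-1]) {
    if (collides(x)) { hit <- x; break }
    free <- x
  }
  if (is.na(hit)) return(list(free = to, hit = NA_real_))
  while (abs(hit - free) > tol) {
    mid <- (hit + free) / 2
    if (collides(mid)) hit <- mid else free <- mid
  }
  list(free = free, hit = hit)
}

#' Maximal elbow-at-side rotation before impingement
#'
#' Sweeps axial rotation of the posed humeral component from neutral (0) in
#' the internal or external direction at a fixed abduction (default 20
#' degrees -- a deliberately low elevation at which rotational conflicts with
#' the scapular pillar appear) until bony contact.  A 5 degree coarse scan
#' brackets the first collision; bisection refines the limit to 0.25
#' degrees.  Returns the scan ceiling (default 150) if never limited.
#'
#' @param scapula closed [triangle_mesh()].
#' @param frame a [glenoid_frame()].
#' @param config glenosphere configuration (object or name).
#' @param hconfig a [humeral_config()]; defaults to one matched to the
#'   glenosphere radius.
#' @param direction `"external"` or `"internal"`.
#' @param abduction degrees (default 20).
#' @param ceiling scan ceiling in degrees (default 150).
#' @param step,tol coarse step and bisection tolerance (degrees).
#' @return list: `angle` (degrees), `limiting_contact` label.
#' @export
max_rotation <- function(scapula, frame, config, hconfig = NULL,
                         direction = c("external", "internal"),
                         abduction = 20, ceiling = 150, step = 5,
                         tol = 0.25) {
  direction <- match.arg(direction)
  config <- as_sphere_config(config)
  hconfig <- hconfig %||% default_hconfig(config)
  assert_closed(scapula, "scapula")
  sgn <- if (direction == "external") 1 else -1
  collides <- function(theta)
    collision(scapula, posed_humeral(frame, config, hconfig, abduction,
                                     sgn * theta))
  if (collides(0)) {
    lab <- contact_label(scapula,
                         posed_humeral(frame, config, hconfig, abduction, 0),
                         frame)
    return(list(angle = 0, limiting_contact = lab))
  }
  lim <- sweep_limit(collides, 0, ceiling, step, tol)
  if (is.na(lim$hit)) return(list(angle = ceiling, limiting_contact = "none"))
  lab <- contact_label(scapula,
                       posed_humeral(frame, config, hconfig, abduction,
                                     sgn * lim$hit), frame)
  list(angle = lim$free, limiting_contact = lab)
}

#' Maximal adduction before inferior impingement
#'
#' Sweeps the humeral shaft downward in the scapular plane from a start
#' abduction (default 20 degrees) until bony contact.  The returned value
#' follows the cadaveric sign convention: negative when contact occurs while
#' the arm is still abducted (an adduction deficit), positive when the arm
#' adducts past vertical.  With no obstruction the sweep stops at the
#' configurable floor (40 degrees past vertical) and is flagged `"none"`.
#'
#' @inheritParams max_rotation
#' @param start_abduction sweep start (degrees).
#' @param floor sweep floor in abduction terms (degrees, default -40, i.e.
#'   40 degrees past vertical).
#' @return list: `adduction` (degrees, negative = deficit),
#'   `limiting_contact`.
#' @export
max_adduction <- function(scapula, frame, config, hconfig = NULL,
                          start_abduction = 20, floor = -40, step = 5,
                          tol = 0.25) {
  config <- as_sphere_config(config)
  hconfig <- hconfig %||% default_hconfig(config)
  assert_closed(scapula, "scapula")
  collides <- function(alpha)
    collision(scapula, posed_humeral(frame, config, hconfig, alpha, 0))
  if (collides(start_abduction)) {
    lab <- contact_label(
      scapula, posed_humeral(frame, config, hconfig, start_abduction, 0),
      frame)
    return(list(adduction = -start_abduction, limiting_contact = lab))
  }
  lim <- sweep_limit(collides, start_abduction, floor, step, tol)
  if (is.na(lim$hit))
    return(list(adduction = -floor, limiting_contact = "none"))
  lab <- contact_label(scapula,
                       posed_humeral(frame, config, hconfig, lim$hit, 0),
                       frame)
  list(adduction = -lim$free, limiting_contact = lab)
}

#' Impingement-limited range of motion for one configuration
#'
#' Bundles the adduction sweep and the elbow-at-side internal and external
#' rotation sweeps (at 20 degrees abduction) into one record, the software
#' analogue of protractor measurements on an articulated frame.
#'
#' @inheritParams max_rotation
#' @param abduction_at_test abduction for the rotation sweeps (degrees).
#' @return a `rom_result`: `adduction`, `ER1`, `IR1` (degrees),
#'   `abduction_at_test`, `limiting_contact` (named character vector).
#' @export
measure_rom <- function(scapula, frame, config, hconfig = NULL,
                        abduction_at_test = 20) {
  config <- as_sphere_config(config)
  hconfig <- hconfig %||% default_hconfig(config)
  add <- max_adduction(scapula, frame, config, hconfig,
                       start_abduction = abduction_at_test)
  er <- max_rotation(scapula, frame, config, hconfig, "external",
                     abduction = abduction_at_test)
  ir <- max_rotation(scapula, frame, config, hconfig, "internal",
                     abduction = abduction_at_test)
  structure(list(adduction = add$adduction,
                 ER1 = er$angle,
                 IR1 = ir$angle,
                 abduction_at_test = abduction_at_test,
                 limiting_contact = c(adduction = add$limiting_contact,
                                      ER1 = er$limiting_contact,
                                      IR1 = ir$limiting_contact),
                 config = config$name),
            class = "rom_result")
}

#' @export
print.rom_result <- function(x, ...) {
  cat(sprintf(
    "<rom_result %s> adduction %.2f  ER1 %.2f  IR1 %.2f (deg, at %g deg abduction)\n",
    x$config, x$adduction, x$ER1, x$IR1, x$abduction_at_test))
  invisible(x)
}

#' @export
as.data.frame.rom_result <- function(x, ...) {
  data.frame(config = x$config, adduction = x$adduction, ER1 = x$ER1,
             IR1 = x$IR1, abduction_at_test = x$abduction_at_test,
             limit_adduction = x$limiting_contact[["adduction"]],
             limit_ER1 = x$limiting_contact[["ER1"]],
             limit_IR1 = x$limiting_contact[["IR1"]],
             stringsAsFactors = FALSE)
}
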