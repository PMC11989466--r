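.config_table <- data.frame(
  name = c("36+0", "36+2", "36+5", "36+7", "42+0", "42+7", "42+10"),
  diameter = c(36, 36, 36, 36, 42, 42, 42),
  lateral_offset = c(0, 0, 5, 7, 0, 7, 10),
  inferior_offset = c(0, 2, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

#' The seven tested glenosphere configurations
#'
#' Four 36 mm designs (centered, 2 mm inferior eccentric, 5 mm and 7 mm
#' lateralized) and three 42 mm designs (centered, 7 mm and 10 mm
#' lateralized).
#'
#' @return data frame with columns `name`, `diameter`, `lateral_offset`,
#'   `inferior_offset` (mm).
#' @export
glenosphere_configs <- function() .config_table

#' Look up a glenosphere configuration by name
#'
#' @param name one of `"36+0"`, `"36+2"`, `"36+5"`, `"36+7"`, `"42+0"`,
#'   `"42+7"`, `"42+10"`.
#' @return a `sphere_config`: `name`, `diameter`, `radius`,
#'   `lateral_offset`, `inferior_offset` (mm).
#' @export
config_by_name <- function(name) {
  i <- match(name, .config_table$name)
  if (is.na(i))
    stop_glenovol("invalid_input", sprintf(
      "unknown glenosphere configuration '%s'; valid names: %s",
      name, paste(.config_table$name, collapse = ", ")))
  row <- .config_table[i, ]
  structure(list(name = row$name,
                 diameter = row$diameter,
                 radius = row$diameter / 2,
                 lateral_offset = row$lateral_offset,
                 inferior_offset = row$inferior_offset),
            class = "sphere_config")
}

as_sphere_config <- function(config) {
  if (inherits(config, "sphere_config")) config else config_by_name(config)
}

#' Glenosphere center for a configuration
#'
#' The sphere center starts at the baseplate entry point, is pushed along the
#' lateral axis by the lateralization and along minus-superior by the
#' inferior eccentricity:
#' `center = entry + lateral_offset * lateral - inferior_offset * superior`.
#'
#' @param frame a [glenoid_frame()].
#' @param config a `sphere_config` or configuration name.
#' @return 3-vector (mm).
#' @export
sphere_center <- function(frame, config) {
  config <- as_sphere_config(config)
  frame$entry + config$lateral_offset * frame$lateral -
    config$inferior_offset * frame$superior
}

#' Humeral component parameters
#'
#' A simplified parametric solid standing in for an inlay reversed humeral
#' implant: a shallow spherical socket whose inner surface is concentric
#' with the glenosphere (inner radius = sphere radius), subtending
#' `cup_half_angle` of polar coverage, with the +6 mm insert rise modelled
#' as additional coverage along the sphere surface (`rise / radius`
#' radians); the rim lip stands off the sphere radially by `rim_thickness`;
#' behind it a conical metaphysis tapers to a cylindrical stem stub.  The
#' 155 degree neck-shaft angle sets the tilt between the socket axis and
#' the humeral shaft.  Only rim/metaphysis geometry relevant to bony
#' impingement is modelled; all dimensions are configurable.
#'
#' @param sphere_radius glenosphere radius (mm); the socket inner radius.
#' @param neck_shaft_angle degrees (default 155).
#' @param insert_rise insert rim rise (mm, default 6), converted to extra
#'   polar coverage along the sphere.
#' @param cup_half_angle polar half-angle subtended by the socket shell
#'   before the insert rise (degrees, default 35; a shallow reversed
#'   liner).
#' @param rim_thickness radial stand-off of the rim lip (mm).
#' @param neck_length metaphysis cone length (mm).
#' @param stem_radius,stem_length stem stub dimensions (mm).
#' @param n_segments,arc_points tessellation density.
#' @export
humeral_config <- function(sphere_radius,
                           neck_shaft_angle = 155,
                           insert_rise = 6,
                           cup_half_angle = 35,
                           rim_thickness = 3,
                           neck_length = 25,
                           stem_radius = 8,
                           stem_length = 30,
                           n_segments = 48,
                           arc_points = 12) {
  stopifnot(sphere_radius > 0, insert_rise >= 0,
            cup_half_angle > 0, cup_half_angle < 90,
            neck_shaft_angle > 90, neck_shaft_angle < 180)
  structure(list(insert_inner_radius = sphere_radius,
                 neck_shaft_angle = neck_shaft_angle,
                 insert_rise = insert_rise,
                 cup_half_angle = cup_half_angle,
                 rim_thickness = rim_thickness,
                 neck_length = neck_length,
                 stem_radius = stem_radius,
                 stem_length = stem_length,
                 n_segments = as.integer(n_segments),
                 arc_points = as.integer(arc_points)),
            class = "humeral_config")
}

# Shaft (distal) direction and socket axis for a pose.  `abduction` is the
# angle of the humeral shaft from vertical in the scapular plane (the plane
# spanned by the superior and lateral axes); negative values are adduction
# past vertical.  `rotation` is the signed axial rotation about the shaft
# axis through the sphere center; positive = external rotation.  At neutral
# rotation the socket axis tilt lies in the scapular plane, pointing medial
# (the anatomic neck inclination).
pose_axes <- function(frame, abduction, rotation, neck_shaft_angle) {
  a <- abduction * pi / 180
  S <- frame$superior; L <- frame$lateral
  d <- -cos(a) * S + sin(a) * L            # shaft, pointing distally
  p <- -d                                  # proximal
  m <- -sin(a) * S - cos(a) * L            # in-plane medial, perpendicular to d
  delta <- (180 - neck_shaft_angle) * pi / 180
  w <- cos(delta) * p + sin(delta) * m     # socket opening direction
  u <- -w                                  # socket axis, into the bone
  if (rotation != 0) {
    sgn <- if (frame$side == "left") -1 else 1
    u <- as.numeric(rotation_about(d, sgn * rotation * pi / 180) %*% u)
  }
  list(shaft = d, axis = u)
}

#' Posed humeral component mesh
#'
#' Builds the simplified humeral solid as a closed surface of revolution
#' about the socket axis and poses it so the socket is concentric with the
#' glenosphere center, abducted by `abduction` in the scapular plane, then
#' axially rotated by `rotation` about the humeral shaft axis through the
#' sphere center (positive = external; mirrored for left shoulders).
#' Rotation is neutral (0) when the socket tilt lies in the scapular plane,
#' matching a forearm perpendicular to the scapular plane with the elbow bent
#' at 90 degrees.
#'
#' @param hconfig a [humeral_config()].
#' @param sphere_center glenosphere center (mm).
#' @param abduction degrees in `[-60, 90]`; negative values are adduction
#'   past vertical, needed for adduction sweeps.
#' @param rotation axial rotation, degrees.
#' @param frame a [glenoid_frame()].
#' @return a watertight [triangle_mesh()].
#' @export
humeral_mesh <- function(hconfig, sphere_center, abduction = 20,
                         rotation = 0, frame) {
  if (abduction < -60 || abduction > 90)
    stop_glenovol("invalid_input",
                  "abduction must lie in [-60, 90] degrees")
  ax <- pose_axes(frame, abduction, rotation, hconfig$neck_shaft_angle)
  u <- ax$axis
  R <- hconfig$insert_inner_radius
  # Effective socket coverage: shell half-angle plus the insert rise taken
  # as arc length along the sphere surface.
  theta <- hconfig$cup_half_angle * pi / 180 + hconfig$insert_rise / R
  if (theta >= pi / 2 - 1e-6)
    stop_glenovol("invalid_input",
                  "socket coverage must stay below a hemisphere")
  # Closed profile (z along the socket axis from the sphere center, r
  # radial): inner spherical cup from the pole to the rim, radial rim lip,
  # metaphysis cone, stem stub, closed on the axis.
  t <- seq(0, theta, length.out = hconfig$arc_points)
  lip <- R + hconfig$rim_thickness
  z_neck <- R * cos(theta) + hconfig$neck_length
  prof <- rbind(cbind(R * cos(t), R * sin(t)),
                c(lip * cos(theta), lip * sin(theta)),
                c(z_neck, hconfig$stem_radius),
                c(z_neck + hconfig$stem_length, hconfig$stem_radius),
                c(z_neck + hconfig$stem_length, 0))
  mesh <- revolve_profile(prof, hconfig$n_segments)
  # Place in the world: ez = socket axis; in-plane directions fixed by the
  # shaft so that the (axisymmetric) solid is posed deterministically.
  ez <- u
  ex <- normalize3(cross3(ax$shaft, u))
  ey <- cross3(ez, ex)
  Rm <- cbind(ex, ey, ez)
  v <- mesh$vertices[, c(2, 3, 1)]            # (r cos, r sin, z) -> world
  v <- v %*% t(Rm)
  v <- sweep(v, 2, sphere_center, "+")
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

# Revolve a closed (z, r) profile starting and ending on the axis (r = 0)
# about the z axis.  Returns a watertight mesh with vertices (z, x, y).
revolve_profile <- function(prof, n_segments) {
  stopifnot(abs(prof[1, 2]) < 1e-12, abs(prof[nrow(prof), 2]) < 1e-12)
  inner <- prof[2:(nrow(prof) - 1), , drop = FALSE]
  k <- nrow(inner)
  th <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  verts <- matrix(0, nrow = 2 + k * n_segments, ncol = 3)
  verts[1, ] <- c(prof[1, 1], 0, 0)
  verts[2, ] <- c(prof[nrow(prof), 1], 0, 0)
  idx <- function(ring, seg) 2L + (ring - 1L) * n_segments + seg
  for (ring in seq_len(k))
    verts[idx(ring, seq_len(n_segments)), ] <-
      cbind(inner[ring, 1], inner[ring, 2] * cos(th), inner[ring, 2] * sin(th))
  faces <- list()
  nxt <- function(s) if (s == n_segments) 1L else s + 1L
  for (s in seq_len(n_segments)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, s), idx(1L, nxt(s)))
    faces[[length(faces) + 1L]] <- c(2L, idx(k, nxt(s)), idx(k, s))
  }
  for (ring in seq_len(k - 1L)) for (s in seq_len(n_segments)) {
    a <- idx(ring, s); b <- idx(ring, nxt(s))
    cc <- idx(ring + 1L, s); d <- idx(ring + 1L, nxt(s))
    faces[[length(faces) + 1L]] <- c(a, cc, d)
    faces[[length(faces) + 1L]] <- c(a, d, b)
  }
  f <- do.call(rbind, faces)
  m <- triangle_mesh(verts, f, validate = FALSE)
  # Orient outward.
  vol <- tryCatch(mesh_volume(m), glenovol_error = function(e) NA_real_)
  if (is.na(vol)) {
    m <- triangle_mesh(verts, f[, c(1, 3, 2)], validate = FALSE)
  }
  m
}
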