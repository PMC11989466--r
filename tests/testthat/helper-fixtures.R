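# Shared fixtures, built in code at load time.

# Canonical identity frame: entry at the origin, lateral = +z,
# superior = +y, anterior = +x (right shoulder).
test_frame <- function(side = "right") {
  ant <- if (side == "right") c(1, 0, 0) else c(-1, 0, 0)
  glenoid_frame(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), ant, side)
}

# Bone as a half-space slab: everything medial of the baseplate plane
# (z < 0 in the identity frame), large enough to act as a half-space for
# any ball used in the tests.
halfspace_slab <- function(extent = 80) {
  mesh_cuboid(c(-extent, -extent, -extent), c(extent, extent, 0))
}

# Memoized icospheres (the subdivision-4 sphere is reused by several
# files and is mildly expensive to build).
.fixture_env <- new.env(parent = emptyenv())
fixture_icosphere <- function(radius, subdivisions = 4) {
  key <- sprintf("ico_%g_%d", radius, subdivisions)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- mesh_icosphere(radius, subdivisions = subdivisions)
  .fixture_env[[key]]
}

fixture_scapula <- function(seed = 11) {
  key <- sprintf("scap_%d", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_scapula(scapula_params(seed = seed))
  .fixture_env[[key]]
}

ball_volume <- function(r) 4 / 3 * pi * r^3

# Obstacle built by construction for sweep-accuracy tests: both rotation
# and adduction sweeps are rigid rotations about an axis through the
# sphere center, so every vertex moves on a circle of fixed radius and
# height.  A small ball placed on the path of the maximal-radius vertex,
# `target_deg` ahead of it, is an obstacle whose first-contact angle has a
# closed kinematic form: vertex v (radius r_v, height h_v, azimuth az_v)
# enters the ball of radius rho centered on the lead vertex's circle when
#   cos(az_v + theta - az0) = (r_v^2 + r0^2 + (h_v - h0)^2 - rho^2) /
#                              (2 r_v r0),
# and the predicted limit is the smallest positive entry angle over all
# vertices.
ball_obstacle <- function(verts, center, axis, target_deg, rho = 2) {
  axis <- glenovol:::normalize3(axis)
  rel <- sweep(verts, 2, center)
  h <- as.numeric(rel %*% axis)
  radial <- rel - h %o% axis
  r <- sqrt(rowSums(radial^2))
  lead <- which.max(r)
  e1 <- glenovol:::normalize3(radial[lead, ])
  e2 <- glenovol:::cross3(axis, e1)
  az <- atan2(as.numeric(rel %*% e2), as.numeric(rel %*% e1))
  az0 <- az[lead] + target_deg * pi / 180
  c0 <- center + r[lead] * (cos(az0) * e1 + sin(az0) * e2) + h[lead] * axis
  K <- (r^2 + r[lead]^2 + (h - h[lead])^2 - rho^2) / (2 * r * r[lead])
  ok <- K <= 1
  th <- (az0 - az[ok] - acos(pmax(-1, K[ok]))) * 180 / pi
  list(mesh = mesh_icosphere(rho, c0, 3), theta = min(th[th > 0]))
}
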