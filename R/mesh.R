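#' Triangle mesh container
#'
#' A watertight triangle surface: an `n x 3` matrix of vertex coordinates in
#' millimetres and an `m x 3` matrix of one-based vertex indices whose
#' triangles are consistently oriented with outward normals.  Scapulae and
#' humeral components are both represented this way.
#'
#' @param vertices numeric matrix, one vertex per row (mm).
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param validate check closedness, orientation and degeneracy (default
#'   `TRUE`).  Validation requires every edge to be shared by exactly two
#'   faces with opposite directions, and rejects zero-area triangles.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop_glenovol("invalid_input", "vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L)
    stop_glenovol("invalid_input", "faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_glenovol("invalid_input", "face indices out of range")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate && nrow(faces) > 0L) assert_closed(mesh)
  mesh
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Edge audit: a closed, consistently oriented mesh has every directed edge
# exactly once and its reverse exactly once.
mesh_edge_audit <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- (as.numeric(from) - 1) * n + as.numeric(to)
  rkey <- (as.numeric(to) - 1) * n + as.numeric(from)
  dup <- sum(duplicated(key))
  unmatched <- sum(is.na(match(key, rkey)))
  list(duplicated_directed = dup, unmatched_directed = unmatched)
}

assert_closed <- function(mesh, what = "mesh") {
  if (nrow(mesh$faces) == 0L)
    stop_glenovol("open_mesh", sprintf("%s has no faces", what))
  audit <- mesh_edge_audit(mesh)
  if (audit$duplicated_directed > 0L || audit$unmatched_directed > 0L)
    stop_glenovol("open_mesh", sprintf(
      "%s is not closed/consistently oriented: %d duplicated and %d unmatched directed edges",
      what, audit$duplicated_directed, audit$unmatched_directed))
  areas <- face_areas(mesh)
  if (any(areas < 1e-12))
    stop_glenovol("invalid_input",
                  sprintf("%s has %d degenerate (zero-area) faces",
                          what, sum(areas < 1e-12)))
  invisible(mesh)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed sum of tetrahedron volumes spanned by each face and the origin
#' (divergence theorem); for an outward-oriented closed surface the result is
#' the enclosed volume in cubic millimetres.
#'
#' @param mesh a [triangle_mesh()].
#' @return positive volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  assert_closed(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
             p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
             p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  if (vol <= 0)
    stop_glenovol("invalid_input",
                  "mesh orientation is inward (signed volume <= 0)")
  vol
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a [triangle_mesh()].
#' @return list with `lower` and `upper` 3-vectors (mm).
#' @export
mesh_bbox <- function(mesh) {
  list(lower = apply(mesh$vertices, 2, min),
       upper = apply(mesh$vertices, 2, max))
}

#' Rigidly transform a mesh
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @export
transform_mesh <- function(mesh, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

#' Axis-aligned cuboid mesh
#' @param lower,upper opposite corners (mm).
#' @return a closed 12-triangle [triangle_mesh()].
#' @export
mesh_cuboid <- function(lower = c(0, 0, 0), upper = c(1, 1, 1)) {
  l <- lower; u <- upper
  v <- rbind(c(l[1], l[2], l[3]), c(u[1], l[2], l[3]),
             c(u[1], u[2], l[3]), c(l[1], u[2], l[3]),
             c(l[1], l[2], u[3]), c(u[1], l[2], u[3]),
             c(u[1], u[2], u[3]), c(l[1], u[2], u[3]))
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (z = lo), outward -z
    c(5, 6, 7), c(5, 7, 8),   # top, outward +z
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(2, 3, 7), c(2, 7, 6),   # x = hi
    c(3, 4, 8), c(3, 8, 7),   # y = hi
    c(4, 1, 5), c(4, 5, 8))   # x = lo
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; the standard test solid
#' for volumetric oracles.
#'
#' @param radius sphere radius (mm).
#' @param center length-3 center (mm).
#' @param subdivisions midpoint subdivision rounds (0 = icosahedron).
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0),
                           subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_env <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_env[[key]]
      if (!is.null(id)) return(id)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_env[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; d <- f[k, 3]
      ab <- midpoint(a, b); bd <- midpoint(b, d); da <- midpoint(d, a)
      newf[4 * k - 3, ] <- c(a, ab, da)
      newf[4 * k - 2, ] <- c(b, bd, ab)
      newf[4 * k - 1, ] <- c(d, da, bd)
      newf[4 * k, ] <- c(ab, bd, da)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- sweep(v * radius, 2, center, "+")
  triangle_mesh(v, f)
}
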