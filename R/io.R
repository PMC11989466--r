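#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL and ASCII PLY.  Duplicate vertices are
#' merged on read (STL stores each triangle independently), coordinates are
#' preserved to better than 1e-6 mm, and watertightness is validated with a
#' reject-by-default policy: an open or inconsistently oriented surface
#' raises an error rather than being repaired silently.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @param validate reject non-watertight meshes (default `TRUE`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, validate = TRUE) {
  if (!file.exists(path))
    stop_glenovol("io", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  tri <- switch(ext,
                stl = read_stl_tris(path),
                ply = return(read_ply(path, validate = validate)),
                stop_glenovol("io", sprintf(
                  "unknown mesh extension '.%s' (expected .stl or .ply)",
                  ext)))
  mesh_from_triangle_soup(tri, validate = validate)
}

# n x 9 triangle soup (three vertices per row) -> deduplicated mesh.
mesh_from_triangle_soup <- function(tri, validate = TRUE) {
  if (nrow(tri) == 0L)
    stop_glenovol("corrupt_file", "mesh file contains no triangles")
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "/")
  uid <- match(key, key)
  keep <- !duplicated(uid)
  verts <- pts[keep, , drop = FALSE]
  remap <- match(uid, uid[keep])
  n <- nrow(tri)
  faces <- cbind(remap[seq_len(n)], remap[n + seq_len(n)],
                 remap[2 * n + seq_len(n)])
  triangle_mesh(verts, faces, validate = validate)
}

read_stl_tris <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80)
    stop_glenovol("corrupt_file", sprintf("truncated STL file: %s", path))
  size <- file.size(path)
  nfaces <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- length(nfaces) == 1 && !is.na(nfaces) &&
    size == 84 + 50 * as.numeric(nfaces)
  if (is_binary) {
    tri <- matrix(0, nrow = nfaces, ncol = 9)
    for (i in seq_len(nfaces)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      if (length(rec) < 12)
        stop_glenovol("corrupt_file",
                      sprintf("truncated STL record in %s", path))
      tri[i, ] <- rec[4:12]
      readBin(con, "raw", 2)
    }
    return(tri)
  }
  # ASCII: "solid" header with "vertex x y z" records.
  txt <- tryCatch(readLines(path, warn = FALSE),
                  error = function(e) stop_glenovol(
                    "corrupt_file", sprintf("unreadable STL file: %s", path)))
  if (!length(txt) || !grepl("^\\s*solid", txt[1]))
    stop_glenovol("corrupt_file",
                  sprintf("not a valid STL file (neither binary nor ASCII): %s",
                          path))
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) %% 3 != 0 || length(vlines) == 0)
    stop_glenovol("corrupt_file",
                  sprintf("ASCII STL vertex count not a multiple of 3: %s",
                          path))
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(nums))
    stop_glenovol("corrupt_file",
                  sprintf("malformed vertex line in ASCII STL: %s", path))
  matrix(t(nums), ncol = 9, byrow = TRUE)
}

read_ply <- function(path, validate = TRUE) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || txt[1] != "ply")
    stop_glenovol("corrupt_file", sprintf("not a PLY file: %s", path))
  endh <- match("end_header", txt)
  if (is.na(endh))
    stop_glenovol("corrupt_file", sprintf("PLY header not terminated: %s",
                                          path))
  header <- txt[seq_len(endh)]
  if (!any(grepl("^format ascii", header)))
    stop_glenovol("io", sprintf("only ASCII PLY is supported: %s", path))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    stop_glenovol("corrupt_file", sprintf("PLY missing element counts: %s",
                                          path))
  body <- txt[-seq_len(endh)]
  if (length(body) < nv + nf)
    stop_glenovol("corrupt_file", sprintf("truncated PLY body: %s", path))
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                    function(x) as.integer(x[1:4]), integer(4)))
  if (anyNA(verts) || anyNA(faces) || any(faces[, 1] != 3L))
    stop_glenovol("corrupt_file",
                  sprintf("malformed PLY body (triangles only): %s", path))
  triangle_mesh(verts, faces[, 2:4, drop = FALSE] + 1L, validate = validate)
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format chosen by extension.
#' @param binary write binary STL (ignored for PLY; default `FALSE`).
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "stl") {
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(c(0, 0, 0, t(v[f[i, ], ])), con, size = 4,
                 endian = "little")
        writeBin(raw(2), con)
      }
    } else {
      lines <- c("solid glenovol")
      for (i in seq_len(nrow(f))) {
        tri <- v[f[i, ], , drop = FALSE]
        lines <- c(lines, " facet normal 0 0 0", "  outer loop",
                   sprintf("   vertex %.9g %.9g %.9g",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "  endloop", " endfacet")
      }
      writeLines(c(lines, "endsolid glenovol"), path)
    }
  } else if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    writeLines(c(header,
                 sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L,
                         f[, 3] - 1L)),
               path)
  } else {
    stop_glenovol("io", sprintf("unknown mesh extension '.%s'", ext))
  }
  invisible(path)
}

#' Read annotated glenoid landmarks
#'
#' JSON schema: `entry` (3-vector, baseplate stud-hole center), `face_points`
#' (>= 3 points on the reamed glenoid face), `superior_hint` (3-vector),
#' `side` (`"right"` or `"left"`).
#'
#' @param path JSON file.
#' @return validated landmark list.
#' @export
read_landmarks <- function(path) {
  lm <- tryCatch(jsonlite::fromJSON(path),
                 error = function(e) stop_glenovol(
                   "corrupt_file", sprintf("unreadable landmarks JSON: %s",
                                           path)))
  for (field in c("entry", "face_points", "superior_hint", "side"))
    if (is.null(lm[[field]]))
      stop_glenovol("schema", sprintf("landmarks missing field '%s'", field))
  lm$entry <- as.numeric(lm$entry)
  lm$superior_hint <- as.numeric(lm$superior_hint)
  lm$face_points <- as.matrix(lm$face_points)
  if (length(lm$entry) != 3L || length(lm$superior_hint) != 3L)
    stop_glenovol("schema", "entry and superior_hint must be 3-vectors")
  if (ncol(lm$face_points) != 3L || nrow(lm$face_points) < 3L)
    stop_glenovol("schema", "face_points must be at least 3 x 3")
  if (!lm$side %in% c("right", "left"))
    stop_glenovol("schema", "side must be 'right' or 'left'")
  lm[c("entry", "face_points", "superior_hint", "side")]
}

#' Write glenoid landmarks to JSON
#' @param landmarks list as returned by [read_landmarks()].
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(entry = landmarks$entry,
                            face_points = landmarks$face_points,
                            superior_hint = landmarks$superior_hint,
                            side = landmarks$side),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Build a glenoid frame from a mesh and its landmarks
#'
#' Fits the baseplate plane to the annotated face points (normal oriented
#' away from the bone's vertex centroid) and assembles the frame.
#'
#' @param mesh the scapula [triangle_mesh()].
#' @param landmarks landmark list (see [read_landmarks()]).
#' @return a [glenoid_frame()].
#' @export
frame_from_landmarks <- function(mesh, landmarks) {
  pl <- fit_plane(landmarks$face_points,
                  ref_point = colMeans(mesh$vertices))
  build_frame(pl, landmarks$entry, landmarks$superior_hint,
              side = landmarks$side)
}
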