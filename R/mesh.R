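#' @useDynLib kneedrill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate sd pf pchisq pt uniroot rnorm runif qnorm
#' @importFrom utils write.csv read.csv
NULL

#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` is the geometric substrate for every query in the
#' package: a triangle soup in millimetres with shared vertices, optionally
#' carrying a region label per face (e.g. `"plateau"`,
#' `"lateral_condyle_medial_wall"`).
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one triangle per row as 1-based vertex
#'   indices.
#' @param face_labels optional character vector, one region tag per face.
#' @param validate if `TRUE` (default), check the watertightness and
#'   orientation invariants after a duplicate-vertex merge; a mesh that
#'   fails validation is rejected with an error naming the number of open
#'   (non-manifold) edges.
#'
#' @details Validation requires every undirected edge to be shared by
#'   exactly two faces and every directed edge to occur once (consistent
#'   orientation). Orientation is canonicalized so the signed volume is
#'   positive, i.e. face normals point outward.
#'
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `face_labels`.
#' @export
surface_mesh <- function(vertices, faces, face_labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
  if (nrow(faces) < 4L) stop("a closed mesh needs at least 4 faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) stop("face index out of range")
  if (!is.null(face_labels) && length(face_labels) != nrow(faces))
    stop("face_labels must have one entry per face")
  m <- structure(list(vertices = vertices, faces = faces,
                      face_labels = face_labels),
                 class = "surface_mesh")
  if (validate) m <- validate_mesh(merge_duplicate_vertices(m))
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$face_labels))
    cat(sprintf(", labels: %s", paste(unique(x$face_labels), collapse = ", ")))
  cat("\n")
  bb <- mesh_bbox(x)
  cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return 2 x 3 matrix, rows = (min, max), columns = (x, y, z).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

# weld vertices closer than `tol` (repair pass for soup formats like STL)
merge_duplicate_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(remap[mesh$faces], ncol = 3L)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  mesh$vertices <- newv
  mesh$faces <- newf[keep, , drop = FALSE]
  if (!is.null(mesh$face_labels)) mesh$face_labels <- mesh$face_labels[keep]
  mesh
}

# directed/undirected edge audit; flips orientation if volume is negative
validate_mesh <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  und <- pmin(ea, eb) * (nv + 1) + pmax(ea, eb)
  cnt <- table(und)
  open_edges <- sum(cnt != 2L)
  if (open_edges > 0L)
    stop(sprintf("mesh is not watertight: %d open or non-manifold edges", open_edges))
  dir_key <- ea * (nv + 1) + eb
  if (anyDuplicated(dir_key))
    stop("mesh orientation is inconsistent: repeated directed edges")
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }
  mesh
}

#' Signed enclosed volume of a mesh
#'
#' Positive for consistently outward-oriented watertight meshes
#' (divergence-theorem sum of signed tetrahedron volumes).
#'
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# per-face unit outward normals and centroids
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

#' Extract an isosurface mesh from an implicit function
#'
#' Samples `f` on a regular grid and extracts the zero level set
#' (negative = interior) by marching tetrahedra, welding shared vertices so
#' the result is watertight whenever the interior stays strictly inside
#' `bounds`.
#'
#' @param f vectorized implicit function taking an n x 3 matrix of points
#'   and returning n signed values (negative inside).
#' @param bounds 2 x 3 matrix of (min, max) per axis, mm.
#' @param pitch grid spacing, mm.
#' @param face_label optional single label applied to all faces.
#' @return a validated `surface_mesh`.
#' @export
mesh_from_implicit <- function(f, bounds, pitch = 1, face_label = NULL) {
  xs <- seq(bounds[1, 1], bounds[2, 1], by = pitch)
  ys <- seq(bounds[1, 2], bounds[2, 2], by = pitch)
  zs <- seq(bounds[1, 3], bounds[2, 3], by = pitch)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  vals <- f(g)
  # grid-coincident zeros (lattice-aligned features) count as outside, far
  # enough from zero that crossing vertices stay off the grid nodes
  vals[abs(vals) < 1e-6] <- 1e-6
  res <- marching_tetrahedra_cpp(vals, xs, ys, zs)
  if (nrow(res$faces) < 4L)
    stop("implicit surface produced no triangles inside the bounds")
  labels <- if (is.null(face_label)) NULL else rep(face_label, nrow(res$faces))
  surface_mesh(res$vertices, res$faces, face_labels = labels)
}

# ---------------------------------------------------------------------------
# STL / PLY readers and writers
# ---------------------------------------------------------------------------

#' Read a triangle mesh from STL (ASCII or binary) or PLY (ASCII)
#'
#' The mesh is repaired on load (duplicate vertices merged at 1e-6 mm) and
#' validated; loading fails if the result is still not watertight.
#'
#' @param path file path; format chosen by extension (`.stl`, `.ply`).
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") read_stl(path) else if (ext == "ply") read_ply(path)
  else stop("unsupported mesh format: ", ext)
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output path; `.stl` (binary by default) or `.ply` (ASCII).
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path)
  } else if (ext == "ply") {
    write_ply_ascii(mesh, path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  fsize <- file.info(path)$size
  close(con)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 84L)
  rec <- readBin(con, "raw", n = 50L * ntri)
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(seq_len(48L), ntri)
  vals <- readBin(rec[idx], "numeric", n = 12L * ntri, size = 4L, endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)  # normal xyz + 3 vertices
  verts <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  tri <- cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(tri[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid kneedrill", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("  outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid kneedrill", con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(frows, function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangular PLY faces are supported")
    x[2:4] + 1L
  }))
  surface_mesh(verts, faces)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}
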