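#' Construct a ray
#'
#' @param origin numeric length-3 point (mm).
#' @param direction numeric length-3 vector; normalized to unit length
#'   (zero-length directions are rejected).
#' @return an object of class `ray` with `origin` and `direction`.
#' @export
ray <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop("ray direction must be non-zero")
  structure(list(origin = origin, direction = direction / n), class = "ray")
}

#' Construct an orthonormal right-handed frame
#'
#' @param origin length-3 point.
#' @param u,v,w orthonormal axes with `u x v = w`. If `w` is omitted it is
#'   computed as `u x v`.
#' @return object of class `frame3`.
#' @export
frame3 <- function(origin, u, v, w = NULL) {
  u <- as.numeric(u); v <- as.numeric(v)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  if (is.null(w)) w <- cross3(u, v)
  w <- as.numeric(w) / sqrt(sum(as.numeric(w)^2))
  if (abs(sum(u * v)) > 1e-9 || abs(sum(u * w)) > 1e-9 || abs(sum(v * w)) > 1e-9)
    stop("frame axes are not orthonormal")
  if (max(abs(cross3(u, v) - w)) > 1e-9) stop("frame is not right-handed (u x v != w)")
  structure(list(origin = as.numeric(origin), u = u, v = v, w = w), class = "frame3")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Cast a ray against a watertight mesh
#'
#' Returns every surface crossing along the ray, sorted by distance, each
#' classified as entering or exiting bone from the sign of the direction
#' against the outward face normal. A ray starting inside the mesh reports
#' an exiting crossing first.
#'
#' @param mesh a `surface_mesh` (watertight; enforced at construction).
#' @param r a `ray`.
#' @return data.frame with columns `t` (mm, >= 0), `kind`
#'   (`"entering"`/`"exiting"`) and `face` (1-based face index), zero rows
#'   if the ray misses.
#' @export
cast_ray <- function(mesh, r) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(r, "ray"))
  res <- raycast_cpp(mesh$vertices, mesh$faces, r$origin, r$direction, 0)
  ord <- order(res$t)
  out <- data.frame(t = res$t[ord],
                    kind = ifelse(res$entering[ord] == 1L, "entering", "exiting"),
                    face = res$face[ord])
  # a ray grazing a shared vertex or edge reports one crossing per incident
  # face: collapse same-kind crossings at numerically equal t
  if (nrow(out) > 1L) {
    dup <- c(FALSE, abs(diff(out$t)) < 1e-9 &
               out$kind[-1] == out$kind[-nrow(out)])
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Test whether points lie strictly inside a watertight mesh
#'
#' Parity of crossings of an upward ray, with a uniform-grid acceleration
#' structure over the faces. Points within ~1e-6 mm of the surface may be
#' classified either way; containment at that scale is not meaningful on a
#' faceted surface.
#'
#' @param mesh a `surface_mesh`.
#' @param points length-3 point or n x 3 matrix.
#' @return logical vector, one value per point.
#' @export
contains_point <- function(mesh, points) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  storage.mode(points) <- "double"
  contains_batch_cpp(mesh$vertices, mesh$faces, points)
}

#' Rotate points rigidly about an arbitrary axis
#'
#' Rodrigues' rotation of a point set about the axis through `axis_point`
#' with unit direction `axis_dir`, by `angle_deg` degrees (right-hand rule).
#'
#' @param points length-3 point or n x 3 matrix.
#' @param axis_point length-3 point on the axis.
#' @param axis_dir length-3 direction (must be non-zero; normalized).
#' @param angle_deg rotation angle, degrees.
#' @return rotated points, same shape as input.
#' @export
rotate_about_axis <- function(points, axis_point, axis_dir, angle_deg) {
  vec_in <- is.null(dim(points))
  if (vec_in) points <- matrix(as.numeric(points), ncol = 3L)
  k <- as.numeric(axis_dir)
  nk <- sqrt(sum(k^2))
  if (!is.finite(nk) || nk < 1e-12) stop("axis direction must be non-zero")
  k <- k / nk
  th <- angle_deg * pi / 180
  p <- sweep(points, 2, as.numeric(axis_point))
  # k x p (right-hand rule)
  cx <- k[2] * p[, 3] - k[3] * p[, 2]
  cy <- k[3] * p[, 1] - k[1] * p[, 3]
  cz <- k[1] * p[, 2] - k[2] * p[, 1]
  kdp <- p[, 1] * k[1] + p[, 2] * k[2] + p[, 3] * k[3]
  out <- p * cos(th) +
    cbind(cx, cy, cz) * sin(th) +
    outer(kdp, k) * (1 - cos(th))
  out <- sweep(out, 2, as.numeric(axis_point), "+")
  dimnames(out) <- NULL
  if (vec_in) as.numeric(out) else out
}

#' Project points into the (u, v) plane of a frame
#'
#' @param points length-3 point or n x 3 matrix.
#' @param frame a `frame3`; the w-component is discarded.
#' @return n x 2 matrix of (u, v) coordinates.
#' @export
project_to_plane <- function(points, frame) {
  stopifnot(inherits(frame, "frame3"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  p <- sweep(points, 2, frame$origin)
  cbind(u = p %*% frame$u, v = p %*% frame$v)
}

# lift 2D frame coordinates back to 3D points on the frame plane
lift_from_plane <- function(uv, frame) {
  if (is.null(dim(uv))) uv <- matrix(as.numeric(uv), ncol = 2L)
  sweep(outer(uv[, 1], frame$u) + outer(uv[, 2], frame$v), 2, frame$origin, "+")
}

# distance from each point to the segment [a, b]
point_segment_distance <- function(points, a, b) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  ab <- as.numeric(b) - as.numeric(a)
  len2 <- sum(ab^2)
  ap <- sweep(points, 2, as.numeric(a))
  tt <- pmin(1, pmax(0, (ap %*% ab) / len2))
  dd <- ap - outer(as.numeric(tt), ab)
  sqrt(rowSums(dd^2))
}

#' Distance from points to a mesh surface
#'
#' Exact minimum point-to-triangle distance over all faces.
#'
#' @param mesh a `surface_mesh`.
#' @param points length-3 point or n x 3 matrix.
#' @return numeric vector of distances (mm).
#' @export
point_mesh_distance <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L)
  storage.mode(points) <- "double"
  point_mesh_dist_cpp(mesh$vertices, mesh$faces, points)
}
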