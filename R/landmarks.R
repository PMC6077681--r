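#' Detect the epicondyles and transepicondylar axis
#'
#' In the canonical right-knee frame the epicondyles are the extreme
#' surface points along -X (medial) and +X (lateral) within the distal
#' condylar half of the femur (below the mid-height of its bounding box).
#' The transepicondylar axis (TEA) passes through their midpoint with
#' direction medial -> lateral.
#'
#' @param femur a `surface_mesh` in the canonical frame.
#' @return list with `medial_epicondyle`, `lateral_epicondyle` (3D points)
#'   and `tea` (a [ray()]).
#' @export
epicondylar_axis <- function(femur) {
  v <- femur$vertices
  zmid <- mean(range(v[, 3]))
  distal <- v[v[, 3] < zmid, , drop = FALSE]
  if (nrow(distal) < 3L) stop("no distal condylar half found below mid-bounding-box")
  med <- distal[which.min(distal[, 1]), ]
  lat <- distal[which.max(distal[, 1]), ]
  sep <- lat[1] - med[1]
  if (sep < 1e-6) stop("degenerate femur: epicondylar extremes are ambiguous")
  dir <- lat - med
  list(medial_epicondyle = med, lateral_epicondyle = lat,
       tea = ray((med + lat) / 2, dir))
}

# true-lateral projection frame: view along the TEA so the condyles
# superimpose; u = anterior (+Y), v = proximal (+Z), w = TEA direction
lateral_frame <- function(tea) {
  w <- tea$direction
  up <- c(0, 0, 1)
  u <- cross3(up, w)          # ~ +Y when w ~ +X
  u <- u / sqrt(sum(u^2))
  v <- cross3(w, u)
  frame3(tea$origin, u, v, w)
}

#' Trace the intercondylar notch roof and its Blumensaat-line proxy
#'
#' Casts distal-to-proximal rays along the intercondylar corridor (the ML
#' midline between the condyles) and records the height at which each ray
#' first enters bone: that polyline is the notch roof. Its most anterior
#' point is the notch apex (the grid reference used in place of the
#' Blumensaat line) and its least-squares direction in the true-lateral
#' projection, oriented posterior -> anterior, is the Blumensaat-proxy
#' direction.
#'
#' @param femur a `surface_mesh` in the canonical frame.
#' @param tea the transepicondylar axis [ray()].
#' @param n_samples number of AP sampling stations.
#' @return list with `notch_apex` (3D point), `blumensaat_dir_2d` (unit 2D
#'   vector in the lateral frame), `roof_2d` (matrix of traced roof points)
#'   and `frame` (the lateral [frame3()]).
#' @export
notch_reference_line <- function(femur, tea, n_samples = 60L) {
  fr <- lateral_frame(tea)
  bb <- mesh_bbox(femur)
  x_mid <- tea$origin[1]
  x_off <- (bb[2, 1] - bb[1, 1]) / 4  # condylar stations either side
  ys <- seq(bb[1, 2], bb[2, 2], length.out = n_samples)
  z0 <- bb[1, 3] - 5
  first_entry <- function(x, y) {
    cr <- cast_ray(femur, ray(c(x, y, z0), c(0, 0, 1)))
    z <- z0 + cr$t[cr$kind == "entering"][1]
    if (length(z) == 0L) NA_real_ else z
  }
  roof <- matrix(NA_real_, 0, 3)
  for (y in ys) {
    z_mid <- first_entry(x_mid, y)
    if (is.na(z_mid)) next
    # a notch station is one where the corridor ray enters bone strictly
    # above the condylar surfaces either side of it
    z_side <- suppressWarnings(
      min(first_entry(x_mid - x_off, y), first_entry(x_mid + x_off, y),
          na.rm = TRUE))
    if (!is.finite(z_side) || z_mid < z_side + 2) next
    roof <- rbind(roof, c(x_mid, y, z_mid))
  }
  if (nrow(roof) < 5L) stop("no intercondylar notch detected")
  roof2d <- project_to_plane(roof, fr)
  apex_i <- which.max(roof2d[, 1])  # most anterior (u = anterior)
  fit <- stats::lm.fit(cbind(1, roof2d[, 1]), roof2d[, 2])
  d <- unname(c(1, fit$coefficients[2]))
  d <- d / sqrt(sum(d^2))           # oriented posterior -> anterior (+u)
  list(notch_apex = roof[apex_i, ], blumensaat_dir_2d = d,
       roof_2d = roof2d, frame = fr)
}

# faces forming the medial wall of the lateral condyle: labelled when
# labels exist, otherwise medially-facing faces (normal x < -cos 60) in the
# lateral half of the distal femur
medial_wall_faces <- function(femur, tea) {
  if (!is.null(femur$face_labels) &&
      any(femur$face_labels == "lateral_condyle_medial_wall")) {
    return(which(femur$face_labels == "lateral_condyle_medial_wall"))
  }
  nrm <- face_normals(femur)
  cen <- face_centroids(femur)
  zmid <- mean(range(femur$vertices[, 3]))
  which(nrm[, 1] < -0.5 & cen[, 1] > tea$origin[1] & cen[, 3] < zmid)
}

#' Build the quadrant grid on the lateral condyle's medial wall
#'
#' The quadrant (Bernard) grid lives in the true-lateral projection: its
#' first axis runs along the Blumensaat-line proxy (posterior -> anterior)
#' across the full projected silhouette of the medial-wall region of the
#' lateral condyle, and its second axis runs perpendicular, from the proxy
#' line toward the distal articular margin.
#'
#' @param femur a `surface_mesh`.
#' @param tea the transepicondylar axis.
#' @param notch result of [notch_reference_line()] (computed if `NULL`).
#' @return object of class `quadrant_grid` with the 2D origin, axes
#'   `e_along`/`e_perp`, extents (mm) and the lateral frame.
#' @export
quadrant_grid <- function(femur, tea, notch = NULL) {
  if (is.null(notch)) notch <- notch_reference_line(femur, tea)
  fr <- notch$frame
  e1 <- notch$blumensaat_dir_2d
  e2 <- c(e1[2], -e1[1])  # perpendicular; orient toward distal (-v)
  if (e2[2] > 0) e2 <- -e2
  wall <- medial_wall_faces(femur, tea)
  if (length(wall) == 0L) stop("no medial wall of the lateral condyle found")
  vidx <- unique(as.vector(femur$faces[wall, ]))
  sil <- project_to_plane(femur$vertices[vidx, , drop = FALSE], fr)
  s1 <- sil %*% e1
  s2 <- sil %*% e2
  c_roof <- mean(notch$roof_2d %*% e2)  # proxy-line station along e_perp
  origin2d <- min(s1) * e1 + c_roof * e2  # posterior border at the proxy line
  structure(list(origin2d = origin2d, e_along = e1, e_perp = e2,
                 extent_along = max(s1) - min(s1),
                 extent_perp = max(s2) - c_roof,
                 frame = fr),
            class = "quadrant_grid")
}

#' 2D position of a fractional grid coordinate
#'
#' Fractions 0 and 1 map exactly to the grid borders: `frac_along` is
#' measured from the posterior border along the Blumensaat proxy,
#' `frac_perp` from the proxy line toward distal.
#'
#' @param grid a [quadrant_grid()].
#' @param frac_along,frac_perp fractional coordinates.
#' @return length-2 numeric, (u, v) in the grid's lateral frame.
#' @export
grid_point2d <- function(grid, frac_along, frac_perp) {
  as.numeric(grid$origin2d +
    frac_along * grid$extent_along * grid$e_along +
    frac_perp * grid$extent_perp * grid$e_perp)
}

#' Femoral ACL footprint center by the quadrant method
#'
#' Places the footprint at the published single-bundle quadrant coordinates
#' (28.4% along the Blumensaat proxy from the posterior border, 35.7%
#' perpendicular to it from the proxy line) and lifts the 2D grid point
#' onto the medial wall of the lateral condyle by a ray cast along the TEA
#' from the intercondylar corridor.
#'
#' @param femur a `surface_mesh`.
#' @param grid a [quadrant_grid()].
#' @param frac_along fraction along the proxy line from the posterior
#'   border (default 0.284).
#' @param frac_perp fraction perpendicular to the proxy line, toward
#'   distal (default 0.357).
#' @return 3D point on the femoral surface.
#' @export
femoral_footprint_center <- function(femur, grid,
                                     frac_along = 0.284, frac_perp = 0.357) {
  uv <- grid_point2d(grid, frac_along, frac_perp)
  origin3d <- lift_from_plane(uv, grid$frame)[1, ]
  cr <- cast_ray(femur, ray(origin3d, grid$frame$w))
  ent <- cr[cr$kind == "entering", , drop = FALSE]
  if (nrow(ent) == 0L)
    stop(sprintf("footprint lift ray missed the condylar wall at 2D (%.2f, %.2f)",
                 uv[1], uv[2]))
  origin3d + ent$t[1] * grid$frame$w
}

#' Fit the tibial plateau frame
#'
#' Least-squares plane through the labelled plateau region (fallback: faces
#' with near-vertical normals in the top 15 mm of the tibia). Axes: `u` =
#' medial->lateral, `v` = posterior->anterior, `w` = plateau normal
#' (proximal).
#'
#' @param tibia a `surface_mesh`.
#' @return a [frame3()] with extra element `plateau_vidx` (indices of
#'   plateau vertices) attached as an attribute.
#' @export
plateau_frame <- function(tibia) {
  if (!is.null(tibia$face_labels) && any(tibia$face_labels == "plateau")) {
    fidx <- which(tibia$face_labels == "plateau")
  } else {
    nrm <- face_normals(tibia)
    cen <- face_centroids(tibia)
    ztop <- max(tibia$vertices[, 3])
    fidx <- which(nrm[, 3] > 0.7 & cen[, 3] > ztop - 15)
    if (length(fidx) == 0L) stop("no plateau region found")
  }
  vidx <- unique(as.vector(tibia$faces[fidx, ]))
  pts <- tibia$vertices[vidx, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  w <- sv$v[, 3]
  if (w[3] < 0) w <- -w            # proximal
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * w) * w
  u <- u / sqrt(sum(u^2))          # ML, lateral positive
  v <- cross3(w, u)                # anterior
  fr <- frame3(ctr, u, v, w)
  attr(fr, "plateau_vidx") <- vidx
  fr
}

#' Tibial ACL footprint center
#'
#' On the true proximal-to-distal view of the plateau, the footprint sits
#' at the published fractions of the plateau outline's bounding box (35.7%
#' of the AP depth from the anterior border, 51.5% of the ML width from the
#' medial border) and is lifted onto the plateau surface by a
#' proximal -> distal ray.
#'
#' @param tibia a `surface_mesh`.
#' @param pframe the plateau [frame3()] from [plateau_frame()].
#' @param frac_ap fraction of AP depth from the anterior border (default
#'   0.357).
#' @param frac_ml fraction of ML width from the medial border (default
#'   0.515).
#' @return 3D point on the plateau surface.
#' @export
tibial_footprint_center <- function(tibia, pframe,
                                    frac_ap = 0.357, frac_ml = 0.515) {
  vidx <- attr(pframe, "plateau_vidx")
  if (is.null(vidx)) vidx <- seq_len(nrow(tibia$vertices))
  uv <- project_to_plane(tibia$vertices[vidx, , drop = FALSE], pframe)
  u_med <- min(uv[, 1]); u_lat <- max(uv[, 1])   # +u = lateral
  v_post <- min(uv[, 2]); v_ant <- max(uv[, 2])  # +v = anterior
  u_pt <- u_med + frac_ml * (u_lat - u_med)
  v_pt <- v_ant - frac_ap * (v_ant - v_post)
  above <- lift_from_plane(c(u_pt, v_pt), pframe)[1, ] + 50 * pframe$w
  cr <- cast_ray(tibia, ray(above, -pframe$w))
  ent <- cr[cr$kind == "entering", , drop = FALSE]
  if (nrow(ent) == 0L) stop("tibial footprint lift ray missed the tibia")
  above - ent$t[1] * pframe$w
}

#' Compute the full landmark set of a knee model
#'
#' @param model a `knee_model` (canonical right-knee frame; use
#'   [canonical_knee()] first for left knees).
#' @param femoral_frac_along,femoral_frac_perp,tibial_frac_ap,tibial_frac_ml
#'   quadrant-method footprint fractions.
#' @return object of class `knee_landmarks`: epicondyles, `tea`,
#'   `notch_apex`, `blumensaat_dir_2d`, `grid`, `plateau_frame`,
#'   `femoral_fp`, `tibial_fp`.
#' @export
knee_landmarks <- function(model,
                           femoral_frac_along = 0.284,
                           femoral_frac_perp = 0.357,
                           tibial_frac_ap = 0.357,
                           tibial_frac_ml = 0.515) {
  epi <- epicondylar_axis(model$femur)
  notch <- notch_reference_line(model$femur, epi$tea)
  grid <- quadrant_grid(model$femur, epi$tea, notch)
  fp_f <- femoral_footprint_center(model$femur, grid,
                                   femoral_frac_along, femoral_frac_perp)
  pfr <- plateau_frame(model$tibia)
  fp_t <- tibial_footprint_center(model$tibia, pfr,
                                  tibial_frac_ap, tibial_frac_ml)
  structure(list(medial_epicondyle = epi$medial_epicondyle,
                 lateral_epicondyle = epi$lateral_epicondyle,
                 tea = epi$tea,
                 notch_apex = notch$notch_apex,
                 blumensaat_dir_2d = notch$blumensaat_dir_2d,
                 grid = grid, plateau_frame = pfr,
                 femoral_fp = fp_f, tibial_fp = fp_t),
            class = "knee_landmarks")
}
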