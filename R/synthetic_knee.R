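#' Parameters of the synthetic knee generator
#'
#' Defines the dimensions of a parametric distal femur + proximal tibia
#' pair in the canonical right-knee frame (+X lateral, +Y anterior,
#' +Z proximal, millimetres, full-extension pose). The only dimension with
#' a population reference is the transepicondylar distance (82.1 mm mean in
#' the cohort the simulation emulates); every other default is a plausible
#' fixed proportion of it and is documented as invented.
#'
#' @param transepicondylar_distance medial-to-lateral epicondyle distance
#'   (mm); must lie in \[60, 110\].
#' @param condyle_radius_med,condyle_radius_lat AP/SI semi-axes of the
#'   medial and lateral condylar ellipsoids (mm).
#' @param notch_width ML width of the intercondylar notch corridor (mm).
#' @param notch_height height of the notch roof above the most distal
#'   condylar surface (mm).
#' @param shaft_radius,shaft_length femoral shaft cylinder dimensions (mm).
#' @param plateau_ap_depth,plateau_ml_width,plateau_slab_thickness tibial
#'   plateau dimensions (mm).
#' @param voxel_pitch marching-tetrahedra grid spacing (mm).
#' @param side `"right"` or `"left"` (left output is the mirror image).
#' @return object of class `knee_params`.
#' @export
knee_params <- function(transepicondylar_distance = 82.1,
                        condyle_radius_med = 0.27 * transepicondylar_distance,
                        condyle_radius_lat = 0.27 * transepicondylar_distance,
                        notch_width = 0.22 * transepicondylar_distance,
                        notch_height = 0.30 * transepicondylar_distance,
                        shaft_radius = 0.17 * transepicondylar_distance,
                        shaft_length = 0.75 * transepicondylar_distance,
                        plateau_ap_depth = 0.62 * transepicondylar_distance,
                        plateau_ml_width = 0.95 * transepicondylar_distance,
                        plateau_slab_thickness = 12,
                        voxel_pitch = 1.0,
                        side = c("right", "left")) {
  side <- match.arg(side)
  p <- list(transepicondylar_distance = transepicondylar_distance,
            condyle_radius_med = condyle_radius_med,
            condyle_radius_lat = condyle_radius_lat,
            notch_width = notch_width, notch_height = notch_height,
            shaft_radius = shaft_radius, shaft_length = shaft_length,
            plateau_ap_depth = plateau_ap_depth,
            plateau_ml_width = plateau_ml_width,
            plateau_slab_thickness = plateau_slab_thickness,
            voxel_pitch = voxel_pitch, side = side)
  lens <- unlist(p[setdiff(names(p), c("side"))])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all knee_params lengths must be positive and finite")
  if (transepicondylar_distance < 60 || transepicondylar_distance > 110)
    stop("transepicondylar_distance outside the plausible [60, 110] mm range")
  structure(p, class = "knee_params")
}

# signed implicit fields (negative inside); approximate SDFs, exact zero set
sdf_ellipsoid <- function(p, center, semi) {
  q <- sweep(p, 2, center)
  (sqrt((q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 + (q[, 3] / semi[3])^2) - 1) *
    min(semi)
}

sdf_box <- function(p, center, half) {
  q <- abs(sweep(p, 2, center))
  pmax(q[, 1] - half[1], q[, 2] - half[2], q[, 3] - half[3])
}

sdf_zcyl <- function(p, center_xy, radius, zlo, zhi) {
  r <- sqrt((p[, 1] - center_xy[1])^2 + (p[, 2] - center_xy[2])^2)
  pmax(r - radius, zlo - p[, 3], p[, 3] - zhi)
}

# seeded smooth gaussian bumps: mild per-subject surface variation
bump_field <- function(p, centers, amps, width) {
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(centers))) {
    d2 <- (p[, 1] - centers[i, 1])^2 + (p[, 2] - centers[i, 2])^2 +
      (p[, 3] - centers[i, 3])^2
    out <- out - amps[i] * exp(-d2 / (2 * width^2))
  }
  out
}

# slope of the notch roof in the sagittal plane (Blumensaat-line proxy
# inclination: the roof descends anteriorly)
NOTCH_ROOF_SLOPE <- 0.35

femur_geometry <- function(params) {
  ted <- params$transepicondylar_distance
  nw <- params$notch_width
  a_ml <- (ted / 2 - nw / 2) / 2          # ML semi-axis of each condyle
  r_ref <- (params$condyle_radius_med + params$condyle_radius_lat) / 2
  list(
    a_ml = a_ml,
    cen_med = c(-(nw / 2 + a_ml), 0, 0),
    cen_lat = c(nw / 2 + a_ml, 0, 0),
    semi_med = c(a_ml, params$condyle_radius_med, params$condyle_radius_med),
    semi_lat = c(a_ml, params$condyle_radius_lat, params$condyle_radius_lat),
    z_roof = -r_ref + params$notch_height,  # roof height at y = 0
    meta_half = c(0.425 * ted, 0.8 * r_ref, NA),
    r_ref = r_ref
  )
}

femur_field <- function(params, bumps = NULL) {
  g <- femur_geometry(params)
  z_roof <- g$z_roof
  # the box bottom sits below the inclined roof plane everywhere so the
  # plane (the Blumensaat-line proxy) forms the whole notch roof
  z_lo <- z_roof - NOTCH_ROOF_SLOPE * g$meta_half[2] - 2
  meta_zc <- (z_lo + z_roof + 25) / 2
  meta_half <- c(g$meta_half[1], g$meta_half[2], (z_roof + 25 - z_lo) / 2)
  shaft_lo <- z_roof + 8
  shaft_hi <- z_roof + params$shaft_length
  function(p) {
    f_med <- sdf_ellipsoid(p, g$cen_med, g$semi_med)
    f_lat <- sdf_ellipsoid(p, g$cen_lat, g$semi_lat)
    f_meta <- pmax(sdf_box(p, c(0, 0, meta_zc), meta_half),
                   (z_roof - NOTCH_ROOF_SLOPE * p[, 2]) - p[, 3])
    f_shaft <- sdf_zcyl(p, c(0, 0), params$shaft_radius, shaft_lo, shaft_hi)
    f <- pmin(f_med, f_lat, f_meta, f_shaft)
    if (!is.null(bumps)) f <- f + bump_field(p, bumps$centers, bumps$amps, bumps$width)
    f
  }
}

tibia_field <- function(params) {
  g <- femur_geometry(params)
  z_top <- -max(params$condyle_radius_med, params$condyle_radius_lat) - 2
  hx <- params$plateau_ml_width / 2
  hy <- params$plateau_ap_depth / 2
  th <- params$plateau_slab_thickness
  shaft_r <- 0.16 * params$transepicondylar_distance
  shaft_lo <- z_top - 0.70 * params$transepicondylar_distance
  function(p) {
    # superelliptic slab: rounded-rectangle plateau outline
    rho <- ((abs(p[, 1]) / hx)^4 + (abs(p[, 2]) / hy)^4)^(1 / 4) - 1
    f_slab <- pmax(rho * min(hx, hy), p[, 3] - z_top, (z_top - th) - p[, 3])
    f_shaft <- sdf_zcyl(p, c(0, 0), shaft_r, shaft_lo, z_top - 6)
    pmin(f_slab, f_shaft)
  }
}

surface_with_retry <- function(field, bounds, pitch) {
  m <- tryCatch(mesh_from_implicit(field, bounds, pitch),
                error = function(e) e)
  if (inherits(m, "error")) {
    m <- tryCatch(mesh_from_implicit(field, bounds, pitch / 2),
                  error = function(e)
                    stop("surfacing failed even at halved pitch: ",
                         conditionMessage(e)))
  }
  m
}

label_femur_faces <- function(mesh, params) {
  g <- femur_geometry(mesh$params %||% params)
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  f_med <- sdf_ellipsoid(cen, g$cen_med, g$semi_med)
  f_lat <- sdf_ellipsoid(cen, g$cen_lat, g$semi_lat)
  z_roof <- g$z_roof
  z_lo <- z_roof - NOTCH_ROOF_SLOPE * g$meta_half[2] - 2
  meta_zc <- (z_lo + z_roof + 25) / 2
  f_meta <- pmax(sdf_box(cen, c(0, 0, meta_zc),
                         c(g$meta_half[1], g$meta_half[2], (z_roof + 25 - z_lo) / 2)),
                 (z_roof - NOTCH_ROOF_SLOPE * cen[, 2]) - cen[, 3])
  f_shaft <- sdf_zcyl(cen, c(0, 0), params$shaft_radius,
                      z_roof + 8, z_roof + params$shaft_length)
  dom <- max.col(-cbind(f_med, f_lat, f_meta, f_shaft))
  lab <- rep("external_cortex", nrow(cen))
  lab[dom == 1L] <- "medial_condyle_articular"
  # medial-facing wall of the lateral condyle (normal points toward -X)
  lab[dom == 2L & nrm[, 1] < -0.5] <- "lateral_condyle_medial_wall"
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mirror_mesh_x <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]  # restore outward orientation
  mesh
}

#' Generate one synthetic knee model
#'
#' Builds a watertight distal femur (two condylar ellipsoids, an
#' intercondylar notch with an inclined roof, a metaphyseal block and a
#' shaft) and a proximal tibia (plateau slab plus shaft) as implicit-surface
#' unions extracted by marching tetrahedra, with seeded smooth surface bumps
#' providing per-subject shape variation. Faces are labelled by their
#' dominant generating primitive (`medial_condyle_articular`,
#' `lateral_condyle_medial_wall`, `plateau`, `external_cortex`).
#'
#' @param params a [knee_params()] object.
#' @param seed integer seed for the surface-variation bumps; output is
#'   deterministic given `(params, seed)`.
#' @return object of class `knee_model` with elements `femur`, `tibia`,
#'   `side`, `params`, `seed`.
#' @export
generate_knee <- function(params = knee_params(), seed = 1L) {
  stopifnot(inherits(params, "knee_params"))
  g <- femur_geometry(params)
  bumps <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed %% .Machine$integer.max)
    k <- 8L
    # bump centers scattered over the two condyles
    which_c <- sample(c(1L, 2L), k, replace = TRUE)
    cen <- t(vapply(seq_len(k), function(i) {
      c0 <- if (which_c[i] == 1L) g$cen_med else g$cen_lat
      semi <- if (which_c[i] == 1L) g$semi_med else g$semi_lat
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      c0 + u * semi
    }, numeric(3)))
    list(centers = cen, amps = pmin(pmax(rnorm(k, 0, 0.5), -1.2), 1.2), width = 8)
  })

  pitch <- params$voxel_pitch
  ted <- params$transepicondylar_distance
  r_top <- g$z_roof + params$shaft_length
  m <- 3 * pitch
  fb <- rbind(c(-ted / 2 - m, -g$r_ref - 2 - m, -g$r_ref - 2 - m),
              c(ted / 2 + m, g$r_ref + 2 + m, r_top + m))
  femur <- surface_with_retry(femur_field(params, bumps), fb, pitch)
  femur$face_labels <- label_femur_faces(femur, params)

  z_top <- -max(params$condyle_radius_med, params$condyle_radius_lat) - 2
  tb <- rbind(c(-params$plateau_ml_width / 2 - m, -params$plateau_ap_depth / 2 - m,
                z_top - 0.70 * ted - m),
              c(params$plateau_ml_width / 2 + m, params$plateau_ap_depth / 2 + m,
                z_top + m))
  tibia <- surface_with_retry(tibia_field(params), tb, pitch)
  nrm <- face_normals(tibia)
  cen <- face_centroids(tibia)
  tlab <- rep("external_cortex", nrow(cen))
  tlab[nrm[, 3] > 0.8 & cen[, 3] > z_top - 1] <- "plateau"
  tibia$face_labels <- tlab

  if (params$side == "left") {
    femur <- mirror_mesh_x(femur)
    tibia <- mirror_mesh_x(tibia)
  }
  structure(list(femur = femur, tibia = tibia, side = params$side,
                 params = params, seed = seed),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("knee_model (%s side, TED %.1f mm, seed %d)\n", x$side,
              x$params$transepicondylar_distance, x$seed))
  cat("femur: "); print(x$femur)
  cat("tibia: "); print(x$tibia)
  invisible(x)
}

#' Mirror a left knee into the canonical right-knee frame
#'
#' All downstream analysis runs in the right-knee canonical frame
#' (+X lateral). Left knees are reflected across the sagittal plane and the
#' flag recorded on the returned model.
#'
#' @param model a `knee_model`.
#' @return the model, mirrored if `side == "left"`, with attribute
#'   `mirrored` set accordingly.
#' @export
canonical_knee <- function(model) {
  if (model$side == "left") {
    model$femur <- mirror_mesh_x(model$femur)
    model$tibia <- mirror_mesh_x(model$tibia)
    attr(model, "mirrored") <- TRUE
  } else {
    attr(model, "mirrored") <- FALSE
  }
  model
}

#' Sample a cohort of synthetic knees
#'
#' Draws per-subject parameters from a seeded population model: the
#' transepicondylar distance is normal with the cohort mean and SD
#' (82.1 +/- 5.7 mm by default) and every other length is its default
#' proportion of the drawn distance, jittered by an independent relative
#' SD to provide shape (not just scale) variation between subjects.
#'
#' @param n cohort size.
#' @param seed master seed; per-subject seeds are derived from it
#'   reproducibly.
#' @param population list with elements `ted_mean`, `ted_sd` and
#'   `shape_cv` (relative SD of the proportion jitter).
#' @param pitch surfacing pitch passed to each model (mm).
#' @return list of `knee_model` objects.
#' @export
sample_cohort <- function(n, seed = 42L,
                          population = list(ted_mean = 82.1, ted_sd = 5.7,
                                            shape_cv = 0.04),
                          pitch = 1.0) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sub_seeds <- sample.int(2^30, n)
  lapply(seq_len(n), function(i) {
    for (attempt in 1:100) {
      ted <- rnorm(1, population$ted_mean, population$ted_sd)
      jit <- function(x) x * exp(rnorm(1, 0, population$shape_cv))
      p <- tryCatch(
        knee_params(transepicondylar_distance = ted,
                    condyle_radius_med = jit(0.27 * ted),
                    condyle_radius_lat = jit(0.27 * ted),
                    notch_width = jit(0.22 * ted),
                    notch_height = jit(0.30 * ted),
                    shaft_radius = jit(0.17 * ted),
                    plateau_ap_depth = jit(0.62 * ted),
                    plateau_ml_width = jit(0.95 * ted),
                    voxel_pitch = pitch),
        error = function(e) NULL)
      if (!is.null(p)) return(generate_knee(p, seed = sub_seeds[i]))
    }
    stop("could not draw valid knee parameters in 100 attempts")
  })
}

#' Write a cohort to disk as STL pairs with JSON sidecars
#'
#' @param cohort list of `knee_model` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort)) {
    mod <- cohort[[i]]
    id <- sprintf("subject%03d", i)
    write_mesh(mod$femur, file.path(dir, paste0(id, "_femur.stl")))
    write_mesh(mod$tibia, file.path(dir, paste0(id, "_tibia.stl")))
    side_car <- list(
      side = mod$side, seed = mod$seed,
      params = unclass(mod$params),
      femur_labels = split(seq_len(nrow(mod$femur$faces)) - 1L, mod$femur$face_labels),
      tibia_labels = split(seq_len(nrow(mod$tibia$faces)) - 1L, mod$tibia$face_labels))
    jsonlite::write_json(side_car, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
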