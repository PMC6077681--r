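#' Far anteromedial portal line
#'
#' The virtual portal center is constrained to a line 10 mm above the
#' posed tibial plateau plane (along its normal), parallel to the plateau
#' ML axis, and a fixed AP offset anterior to the plateau's anterior-most
#' point. The line is parameterized by `s`, the signed ML position,
#' increasing medially: `P(s) = C - s * u`.
#'
#' @param posed a `posed_knee` from [flex_knee()].
#' @param anterior_offset_mm AP offset of the line anterior to the
#'   plateau's anterior-most point (default 15 mm).
#' @param height_mm height above the plateau plane (default 10 mm).
#' @return object of class `portal_line`: `C` (base point), `u`, `v`, `w`
#'   (posed plateau axes), `s_range` (ML bounding extent of the plateau,
#'   in `s` units) and `point(s)` evaluation via [portal_point()].
#' @export
portal_line <- function(posed, anterior_offset_mm = 15, height_mm = 10) {
  pf <- posed$plateau_frame_posed
  vidx <- attr(pf, "plateau_vidx")
  pv <- posed$tibia_posed$vertices[vidx, , drop = FALSE]
  rel <- sweep(pv, 2, pf$origin)
  v_ant <- max(rel %*% pf$v)
  u_rng <- range(rel %*% pf$u)
  C <- pf$origin + (v_ant + anterior_offset_mm) * pf$v + height_mm * pf$w
  structure(list(C = C, u = pf$u, v = pf$v, w = pf$w,
                 origin = pf$origin,
                 s_range = c(-u_rng[2], -u_rng[1]),  # s = -u coordinate
                 height_mm = height_mm),
            class = "portal_line")
}

#' Evaluate a portal line at parameter s
#'
#' @param line a [portal_line()].
#' @param s signed ML parameter (mm), increasing medially.
#' @return 3D point.
#' @export
portal_point <- function(line, s) {
  line$C - s * line$u
}

#' Transverse drill angle
#'
#' Angle in \[0, 90\] degrees between the drill direction (portal ->
#' femoral footprint) projected into the posed plateau plane and the
#' plateau AP axis: 0 means a purely sagittal drill, 90 a fully transverse
#' one. Only differences between angles matter downstream, so the AP-axis
#' datum is a convention.
#'
#' @param portal 3D portal point.
#' @param F femoral footprint center (3D).
#' @param pframe the posed plateau [frame3()].
#' @return angle in degrees.
#' @export
transverse_angle <- function(portal, F, pframe) {
  d <- as.numeric(F) - as.numeric(portal)
  du <- sum(d * pframe$u)
  dv <- sum(d * pframe$v)
  if (abs(du) < 1e-12 && abs(dv) < 1e-12)
    stop("drill direction is perpendicular to the plateau plane")
  atan2(abs(du), abs(dv)) * 180 / pi
}

# sample points of the medial condyle articular region (cylinder clearance
# is evaluated against these): face vertices + centroids of labelled faces
medial_condyle_samples <- function(femur) {
  if (is.null(femur$face_labels)) return(NULL)
  fidx <- which(femur$face_labels == "medial_condyle_articular")
  if (length(fidx) == 0L) return(NULL)
  vidx <- unique(as.vector(femur$faces[fidx, ]))
  rbind(femur$vertices[vidx, , drop = FALSE],
        face_centroids(femur)[fidx, , drop = FALSE])
}

# exit distance of the drill axis (origin F, direction d) through the femur:
# the LAST inside->outside crossing, so notch re-entries do not truncate
# the tunnel. Returns 0 if the axis never re-enters bone.
axis_exit_t <- function(femur, F, d) {
  cr <- cast_ray(femur, ray(F, d))
  ex <- cr$t[cr$kind == "exiting"]
  if (length(ex) == 0L) 0 else max(ex)
}

# clearance (mm) between the drill cylinder around segment P -> D and the
# medial condyle articular region; positive = no contact
drill_clearance <- function(samples, P, D, radius) {
  if (is.null(samples)) return(Inf)
  min(point_segment_distance(samples, P, D)) - radius
}

#' Clearance between a drill cylinder and the medial condyle
#'
#' Distance (mm) between the cylinder of the given diameter around the
#' portal -> footprint segment (extended to the tunnel exit) and the medial
#' femoral condyle's articular region; negative values mean contact.
#' `Inf` when the femur carries no medial-condyle label.
#'
#' @param posed a `posed_knee`.
#' @param F femoral footprint center.
#' @param portal a `portal_solution` or 3D portal point.
#' @param diameter_mm drill diameter (default 8).
#' @return clearance in mm.
#' @export
portal_clearance <- function(posed, F, portal, diameter_mm = 8) {
  P <- if (inherits(portal, "portal_solution")) portal$portal_point else as.numeric(portal)
  femur <- posed$base$femur
  d <- as.numeric(F) - P
  d <- d / sqrt(sum(d^2))
  D <- F + axis_exit_t(femur, F, d) * d
  drill_clearance(medial_condyle_samples(femur), P, D, diameter_mm / 2)
}

#' Find the maximum transverse drill angle (MTA)
#'
#' Searches the portal line for the most medial portal whose full drill
#' cylinder (radius = diameter/2 around the portal -> footprint segment,
#' extended to the tunnel exit) keeps non-negative clearance from the
#' medial femoral condyle's articular region. Feasibility is first sampled
#' across the bracket (and must be monotone: feasible laterally, infeasible
#' medially), then the boundary is bisected to 0.05 mm in `s`.
#'
#' @param posed a `posed_knee`.
#' @param F femoral footprint center.
#' @param diameter_mm drill diameter (default 8).
#' @param line a [portal_line()]; built with defaults when `NULL`.
#' @param bracket_pad extension of the search bracket beyond the plateau ML
#'   extent, mm (default 20).
#' @param n_scan number of pre-scan stations for the monotonicity check.
#' @param s_tol bisection tolerance on `s`, mm.
#' @return object of class `portal_solution`: `portal_point`, `s`,
#'   `transverse_angle_deg`, `offset_from_mta` (0), `clearance_mm`,
#'   `constraint_active`, `line`.
#' @export
find_mta <- function(posed, F, diameter_mm = 8, line = NULL,
                     bracket_pad = 20, n_scan = 24L, s_tol = 0.05) {
  if (is.null(line)) line <- portal_line(posed)
  femur <- posed$base$femur
  samples <- medial_condyle_samples(femur)
  radius <- diameter_mm / 2
  feas <- function(s) {
    P <- portal_point(line, s)
    d <- as.numeric(F) - P
    d <- d / sqrt(sum(d^2))
    D <- F + axis_exit_t(femur, F, d) * d
    drill_clearance(samples, P, D, radius)
  }
  # the far anteromedial portal is a medial portal: search only the branch
  # medial of the footprint's ML station (where the transverse angle is 0
  # and strictly increasing medially); portals lateral of the footprint
  # would aim the extended drill axis across the notch into the medial
  # condyle and are not surgically meaningful
  s_zero <- -sum((as.numeric(F) - line$C) * line$u)
  s_lo <- max(line$s_range[1] - bracket_pad, s_zero + 0.5)
  s_hi <- line$s_range[2] + bracket_pad  # medial end
  ss <- seq(s_lo, s_hi, length.out = n_scan)
  cl <- vapply(ss, feas, numeric(1))
  ok <- cl >= 0
  solution <- function(s, active) {
    P <- portal_point(line, s)
    structure(list(portal_point = P, s = s,
                   transverse_angle_deg = transverse_angle(P, F, posed$plateau_frame_posed),
                   offset_from_mta = 0,
                   clearance_mm = feas(s),
                   constraint_active = active, line = line),
              class = "portal_solution")
  }
  if (all(ok)) return(solution(s_hi, active = FALSE))
  if (!any(ok)) stop("drill corridor blocked: no feasible portal on the line")
  k <- which(!ok)[1]
  if (k == 1L || any(ok[k:length(ok)]))
    stop(sprintf(
      "feasibility is not monotone along the portal line (pattern: %s)",
      paste(ifelse(ok, "T", "F"), collapse = "")))
  a <- ss[k - 1L]; b <- ss[k]
  while (b - a > s_tol) {
    mid <- (a + b) / 2
    if (feas(mid) >= 0) a <- mid else b <- mid
  }
  solution(a, active = TRUE)
}

#' Portal at a prescribed transverse angle
#'
#' Moves the drill laterally from the MTA portal to the position whose
#' transverse angle equals `target_deg` (root-found to 0.01 degrees).
#'
#' @param posed a `posed_knee`.
#' @param F femoral footprint center.
#' @param target_deg target transverse angle; must not exceed the MTA.
#' @param mta the [find_mta()] solution (computed when `NULL`).
#' @param diameter_mm drill diameter (used only if `mta` is computed here).
#' @return a `portal_solution` with `offset_from_mta = target_deg - MTA`.
#' @export
portal_at_angle <- function(posed, F, target_deg, mta = NULL, diameter_mm = 8) {
  if (is.null(mta)) mta <- find_mta(posed, F, diameter_mm)
  line <- mta$line
  pframe <- posed$plateau_frame_posed
  if (target_deg > mta$transverse_angle_deg + 1e-9)
    stop("target angle exceeds the maximum transverse drill angle")
  ang <- function(s) transverse_angle(portal_point(line, s), F, pframe)
  # the angle is zero where the portal sits at the footprint's ML station
  # and increases strictly medially; root-find on that branch
  s_zero <- -sum((as.numeric(F) - line$C) * line$u)
  lo <- s_zero + 1e-6
  if (target_deg < ang(lo))
    stop("target angle unreachable on the portal line")
  r <- uniroot(function(s) ang(s) - target_deg, c(lo, mta$s),
               tol = 1e-7)
  s <- r$root
  if (abs(ang(s) - target_deg) > 0.01)
    stop("portal_at_angle did not converge to the target angle")
  P <- portal_point(line, s)
  structure(list(portal_point = P, s = s,
                 transverse_angle_deg = ang(s),
                 offset_from_mta = target_deg - mta$transverse_angle_deg,
                 clearance_mm = NA_real_,
                 constraint_active = FALSE, line = line),
            class = "portal_solution")
}

#' Drill the virtual femoral tunnel
#'
#' The tunnel axis starts at the femoral footprint center `F` and continues
#' into bone along the portal -> footprint direction. The exit point is the
#' last inside -> outside crossing of the axis with the femur (the external
#' cortex), the tunnel length the distance from `F` to it; a tunnel shorter
#' than 25 mm is flagged short, and the wall is classified for entrance or
#' mid-tunnel breakage.
#'
#' @param femur the femur `surface_mesh`.
#' @param F femoral footprint center (on the femoral surface).
#' @param portal a `portal_solution` or a plain 3D portal point.
#' @param diameter_mm drill diameter (default 8).
#' @param short_threshold_mm short-tunnel rule threshold (25 mm).
#' @param breakage_opts list of classifier settings passed to
#'   [classify_breakage()].
#' @return object of class `tunnel_result`: `axis` ([ray()] at `F`),
#'   `exit_point`, `length_mm`, `diameter_mm`, `breakage`, `short`.
#' @export
drill_tunnel <- function(femur, F, portal, diameter_mm = 8,
                         short_threshold_mm = 25, breakage_opts = list()) {
  P <- if (inherits(portal, "portal_solution")) portal$portal_point else as.numeric(portal)
  if (point_mesh_distance(femur, F) > 1.0)
    stop("footprint center is not on the femoral surface")
  d <- as.numeric(F) - P
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("portal and footprint coincide")
  d <- d / nd
  t_exit <- axis_exit_t(femur, F, d)
  exit_point <- F + t_exit * d
  res <- structure(list(axis = ray(F, d), exit_point = exit_point,
                        length_mm = t_exit, diameter_mm = diameter_mm,
                        breakage = NA_character_,
                        short = t_exit < short_threshold_mm),
                   class = "tunnel_result")
  res$breakage <- do.call(classify_breakage,
                          c(list(tunnel = res, femur = femur), breakage_opts))
  res
}

#' Classify femoral tunnel wall breakage
#'
#' Walks `n_theta` wall generator lines of the drill cylinder
#' (`W(t) = F + t * axis + r * n_theta`) through the proximal
#' `min(length, 25)` mm of the tunnel at `t_step` resolution and tests each
#' sample for containment in bone. Entrance breakage: some generator has no
#' in-bone sample within the first `a_cap` mm (the oblique-aperture
#' allowance). Otherwise mid-tunnel breakage: some generator leaves bone
#' between its first in-bone station (+`margin`) and the 25-mm cap
#' (-`margin`). Otherwise the wall is intact. The two classes are mutually
#' exclusive by definition.
#'
#' @param tunnel a `tunnel_result`.
#' @param femur the femur `surface_mesh`.
#' @param n_theta number of wall generators (default 72).
#' @param t_step axial sampling step, mm (default 0.25).
#' @param a_cap aperture allowance, mm (default 8).
#' @param margin end margin around the first-entry/cap stations, mm.
#' @param cap_mm breakage assessment depth cap, mm (default 25).
#' @return `"none"`, `"entrance"` or `"mid_tunnel"`.
#' @export
classify_breakage <- function(tunnel, femur, n_theta = 72L, t_step = 0.25,
                              a_cap = 8, margin = 0.5, cap_mm = 25) {
  F <- tunnel$axis$origin
  d <- tunnel$axis$direction
  r <- tunnel$diameter_mm / 2
  tcap <- min(tunnel$length_mm, cap_mm)
  ts <- seq(0, max(tcap, 0), by = t_step)
  # orthonormal basis perpendicular to the axis
  aux <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- cross3(d, aux); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- cross3(d, n1)
  th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  offs <- outer(cos(th), n1) + outer(sin(th), n2)  # n_theta x 3
  nt <- length(ts)
  pts <- matrix(0, n_theta * nt, 3)
  for (k in 1:3)
    pts[, k] <- F[k] + rep(ts, each = n_theta) * d[k] + r * rep(offs[, k], nt)
  inside <- matrix(contains_point(femur, pts), nrow = n_theta)  # theta x t
  early <- ts <= a_cap
  no_entry <- !apply(inside[, early, drop = FALSE], 1, any)
  if (any(no_entry)) return("entrance")
  a_idx <- apply(inside, 1, function(x) which(x)[1])
  breach <- vapply(seq_len(n_theta), function(i) {
    lo <- ts[a_idx[i]] + margin
    window <- ts > lo & ts < tcap - margin
    any(!inside[i, window])
  }, logical(1))
  if (any(breach)) "mid_tunnel" else "none"
}
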