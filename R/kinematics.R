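#' Pose a knee at a given flexion angle
#'
#' Pure hinge model: the tibia (mesh, plateau frame and tibial footprint)
#' rotates rigidly about the fixed transepicondylar axis while the femur --
#' and therefore the femoral footprint and any drilled tunnel -- stays
#' fixed in the world frame. The rotation sign is chosen so that positive
#' flexion carries the tibial shaft posteriorly. Roll-back and screw-home
#' motion are deliberately not modelled.
#'
#' @param model a `knee_model` in the full-extension pose.
#' @param landmarks a [knee_landmarks()] object for `model`.
#' @param flexion_deg flexion angle in degrees, within \[0, 160\].
#' @return object of class `posed_knee`: `base`, `landmarks`,
#'   `flexion_deg`, `tibia_posed`, `plateau_frame_posed`, `tibial_fp_posed`.
#' @export
flex_knee <- function(model, landmarks, flexion_deg) {
  if (!is.finite(flexion_deg) || flexion_deg < 0 || flexion_deg > 160)
    stop("flexion_deg must lie in [0, 160]")
  tea <- landmarks$tea
  # sign convention: the distal end of the tibial shaft must move toward -Y
  shaft_tip <- model$tibia$vertices[which.min(model$tibia$vertices[, 3]), ]
  probe <- rotate_about_axis(shaft_tip, tea$origin, tea$direction, 10)
  sgn <- if (probe[2] < shaft_tip[2]) 1 else -1
  ang <- sgn * flexion_deg
  rot <- function(p) rotate_about_axis(p, tea$origin, tea$direction, ang)

  tib <- model$tibia
  tib$vertices <- rot(tib$vertices)
  pf <- landmarks$plateau_frame
  vidx <- attr(pf, "plateau_vidx")
  pf_posed <- frame3(rot(pf$origin),
                     rot(pf$origin + pf$u) - rot(pf$origin),
                     rot(pf$origin + pf$v) - rot(pf$origin))
  attr(pf_posed, "plateau_vidx") <- vidx
  structure(list(base = model, landmarks = landmarks,
                 flexion_deg = flexion_deg,
                 tibia_posed = tib,
                 plateau_frame_posed = pf_posed,
                 tibial_fp_posed = rot(landmarks$tibial_fp),
                 .rot_angle = ang),
            class = "posed_knee")
}
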