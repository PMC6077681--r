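#' Graft bending angle at the femoral tunnel aperture
#'
#' With the knee in full extension, the intra-articular graft runs from the
#' tibial footprint center `A` to the femoral footprint center `B`; the
#' tunnel runs from `B` to its external-cortex exit `D`. The bending angle
#' is measured at `B` between the continuation of the graft line beyond `B`
#' (the A -> B direction) and the tunnel direction B -> D: 0 degrees means
#' the tunnel prolongs the graft line (no bend), larger values a sharper
#' bend.
#'
#' @param A tibial footprint center (3D, extension pose).
#' @param B femoral footprint center (3D).
#' @param D tunnel exit point (3D).
#' @return angle in degrees, in \[0, 180\].
#' @export
graft_bending_angle <- function(A, B, D) {
  u <- as.numeric(B) - as.numeric(A)  # graft continuation direction at B
  v <- as.numeric(D) - as.numeric(B)  # tunnel direction
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("coincident points: bending angle undefined")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
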