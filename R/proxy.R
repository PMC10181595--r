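#' Frontal-plane proxy for compartmental knee contact forces
#'
#' A deliberately simple two-contact-point static balance in the frontal
#' plane, standing in for a full musculoskeletal contact-model simulation
#' so the pipeline has an end-to-end compartmental output: with
#' intercondylar distance `d`, the medial/lateral split satisfies
#' `medial - lateral = 2 |KAM| / d` (KAM in absolute Nm) and
#' `medial + lateral = axial force`.  When the implied minor-compartment
#' force is negative it is clamped to zero (condylar lift-off), the other
#' compartment carries the full axial force, and the sample is flagged.
#'
#' This proxy ignores muscle forces, ligaments and cartilage contact
#' mechanics; it is NOT a musculoskeletal contact-model computation, and
#' every file written from it is suffixed `_proxy`.
#'
#' @param moments A [knee_moments()] result (Nm/kg, 101-point).
#' @param axial_force Axial (compressive) knee force waveform in BW on the
#'   same percent grid; the vertical GRF is a common crude choice.
#' @param intercondylar_distance Distance between the medial and lateral
#'   contact points, m (default 0.045, a common adult literature value).
#' @return A `kcf_proxy` tibble: `percent`, `medial`, `lateral`, `total`
#'   (BW), `clamp_flag`.
#' @export
#' @examples
#' # axial 2000 N and KAM 40 Nm at d = 45 mm for an 80 kg subject:
#' # medial = 2000/2 + 40/0.045 = 1888.9 N
proxy_kcf <- function(moments, axial_force, intercondylar_distance = 0.045) {
  d <- intercondylar_distance
  if (d <= 0.02 || d >= 0.10) {
    abort("intercondylar_distance must lie in (0.02, 0.10) m")
  }
  stopifnot(length(axial_force) == nrow(moments))
  # KAM in Nm/kg; in BW units the lever term is |KAM| / (d * g)
  half_diff <- abs(moments$kam) / (d * GRAVITY)
  medial <- axial_force / 2 + half_diff
  lateral <- axial_force - medial
  clamp <- lateral < 0 | medial < 0
  lateral_c <- pmax(lateral, 0)
  medial_c <- pmax(medial, 0)
  medial_c[lateral < 0] <- axial_force[lateral < 0]
  lateral_c[medial < 0] <- axial_force[medial < 0]
  structure(
    tibble(
      percent = moments$percent,
      medial = medial_c, lateral = lateral_c,
      total = axial_force, clamp_flag = clamp
    ),
    intercondylar_distance = d,
    class = c("kcf_proxy", class(tibble()))
  )
}
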