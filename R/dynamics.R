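#' Construct a ground wrench (force + moment time series)
#'
#' @param data Tibble with force columns `fx`, `fy`, `fz` and moment
#'   columns `mx`, `my`, `mz`; any extra columns (e.g. `percent`, `time`)
#'   are carried through.
#' @param reference Point the moments are expressed about, lab-frame
#'   metres; the lab origin `c(0, 0, 0)` by default.
#' @param units List with `force` (`"BW"` or `"N"`) and `moment`
#'   (`"Nm_per_kg"` or `"Nm"`); the pairs must be consistent (both
#'   mass-normalized or both absolute).
#' @param side `"right"`, `"left"` or `"total"`.
#' @param body_mass Subject mass in kg, required to convert between unit
#'   systems.
#' @return A `ground_wrench` tibble.
#' @export
ground_wrench <- function(data, reference = c(0, 0, 0),
                          units = list(force = "BW", moment = "Nm_per_kg"),
                          side = "total", body_mass = NA_real_) {
  data <- as_tibble(data)
  need <- c("fx", "fy", "fz", "mx", "my", "mz")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("wrench data lacks columns: ", paste(missing, collapse = ", ")))
  }
  normalized <- units$force == "BW"
  if (normalized != (units$moment == "Nm_per_kg")) {
    abort("force and moment units must both be normalized or both absolute")
  }
  structure(data,
    reference = reference, units = units, side = side, body_mass = body_mass,
    class = c("ground_wrench", class(tibble()))
  )
}

# transport factor linking (p - p') x F to the moment columns' units
moment_transport_factor <- function(units) {
  if (units$force == "BW" && units$moment == "Nm_per_kg") GRAVITY else 1
}

#' Move a wrench's moment reference point
#'
#' Applies the wrench transport law `M' = M + (p - p') x F`, where `p` is
#' the current reference point and `p'` the new one.  Exact: transporting
#' back recovers the original moments to machine precision.
#'
#' @param wrench A [ground_wrench()].
#' @param to New reference point, lab-frame metres (length 3).
#' @return The wrench with updated moments and `reference` attribute.
#' @export
transport_wrench <- function(wrench, to) {
  stopifnot(inherits(wrench, "ground_wrench"), length(to) == 3)
  p <- attr(wrench, "reference")
  d <- p - to
  f <- as.matrix(wrench[, c("fx", "fy", "fz")])
  add <- moment_transport_factor(attr(wrench, "units")) * cross3(d, f)
  wrench$mx <- wrench$mx + add[, 1]
  wrench$my <- wrench$my + add[, 2]
  wrench$mz <- wrench$mz + add[, 3]
  attr(wrench, "reference") <- to
  wrench
}

# force (N) and moment (Nm) matrices regardless of stored units
wrench_si <- function(wrench) {
  u <- attr(wrench, "units")
  f <- as.matrix(wrench[, c("fx", "fy", "fz")])
  m <- as.matrix(wrench[, c("mx", "my", "mz")])
  if (u$force == "BW") {
    mass <- attr(wrench, "body_mass")
    if (!is.finite(mass)) abort("body_mass needed to convert BW to N")
    f <- f * mass * GRAVITY
    m <- m * mass
  }
  list(force = f, moment = m)
}

#' Whole-body external wrench from COM acceleration
#'
#' Newton's law for the whole body: the total ground reaction force is
#' `F = m (a_com - g)`, returned in body-weight units.  This is the
#' whole-body specialization of the generalized-force computation, useful
#' as an additional observed feature for the PPCA model.  Moments are set
#' to zero (whole-body angular dynamics are not modelled here).
#'
#' @param com_accel `n x 3` matrix (or tibble with columns
#'   `com_acc_x/y/z`) of COM acceleration in m/s^2.
#' @param subject A [scale_subject()] model.
#' @return A [ground_wrench()] (`side = "total"`, BW / Nm/kg) at the lab
#'   origin.
#' @export
#' @examples
#' subj <- scale_subject(80, 1.75)
#' whole_body_wrench(matrix(0, 3, 3), subj) # quiet standing: (0, 1, 0) BW
whole_body_wrench <- function(com_accel, subject) {
  if (is.data.frame(com_accel)) {
    com_accel <- as.matrix(com_accel[, c("com_acc_x", "com_acc_y", "com_acc_z")])
  }
  if (!all(is.finite(com_accel))) abort("COM accelerations must be finite")
  g <- matrix(gravity_vec(), nrow(com_accel), 3, byrow = TRUE)
  f_bw <- (com_accel - g) / GRAVITY # mass * (a - g) / (mass * g)
  ground_wrench(
    tibble(
      fx = f_bw[, 1], fy = f_bw[, 2], fz = f_bw[, 3],
      mx = 0, my = 0, mz = 0
    ),
    side = "total", body_mass = subject$mass
  )
}

# shank anatomical frame from knee and ankle positions (rows = samples)
shank_frame <- function(knee, ankle) {
  y <- knee - ankle
  y <- y / sqrt(rowSums(y^2))
  zlab <- matrix(c(0, 0, 1), nrow(knee), 3, byrow = TRUE)
  z <- zlab - y * rowSums(zlab * y)
  z <- z / sqrt(rowSums(z^2))
  x <- cross3(y, z)
  list(x = x, y = y, z = z)
}

#' External knee moments by bottom-up inverse dynamics
#'
#' Newton-Euler recursion over the two distal segments (foot, then shank)
#' of the stance leg: the ground reaction force applied at the centre of
#' pressure is propagated through the ankle to the knee, including segment
#' weight and inertial terms (linear accelerations of the segment COMs and
#' sagittal angular acceleration of the shank by finite differences; the
#' foot is treated as flat on the ground during stance).  The resulting
#' external moment -- the moment of all loads distal to the knee about the
#' knee joint centre -- is resolved in the shank anatomical frame (long
#' axis knee-to-ankle, medio-lateral axis from the lab Z direction) and
#' normalized by body mass.
#'
#' Sign conventions: knee flexion moment (KFM) positive for external
#' flexion, knee adduction moment (KAM) positive for external adduction
#' (side-aware), knee rotation moment (KRM) positive for external internal
#' rotation.
#'
#' @param cycle A [time_normalize()] cycle providing
#'   `knee_pos_{x,y,z}_<s>` and `ankle_pos_{x,y,z}_<s>` channels (m).
#' @param grf A [ground_wrench()] for the stance foot on the cycle's
#'   percent grid (only the force columns are used; the force is applied
#'   at the COP).
#' @param cop A `cop_trajectory` from [repair_cop()] / [cop_from_grfm()]
#'   (stance-percent grid), or a tibble with `stance_percent`, `x_ap`,
#'   `y_ml`.
#' @param subject A [scale_subject()] model (segment masses/inertias).
#' @param side Stance side, `"right"` or `"left"`.
#' @param include_segment_dynamics Include segment weight and inertial
#'   terms?  With `FALSE` the result is the quasi-static moment of the
#'   ground force alone (useful for checks; massless-segment limit).
#' @return A `knee_moments` tibble: `percent` (101 points), `kfm`, `kam`,
#'   `krm` in Nm/kg, zero outside stance.
#' @export
knee_moments <- function(cycle, grf, cop, subject, side = "right",
                         include_segment_dynamics = TRUE) {
  sfx <- substr(side, 1, 1)
  sf <- attr(cycle, "stance_fraction")
  dur <- attr(cycle, "cycle_duration")
  pct <- cycle$percent
  in_st <- pct <= 100 * sf + 1e-9
  idx <- which(in_st)
  h <- (pct[2] - pct[1]) / 100 * dur

  need <- paste0(rep(c("knee_pos_", "ankle_pos_"), each = 3),
                 c("x_", "y_", "z_"), sfx)
  miss <- setdiff(need, names(cycle))
  if (length(miss)) {
    abort(paste0("cycle lacks position channels: ", paste(miss, collapse = ", ")))
  }
  knee <- as.matrix(cycle[idx, paste0("knee_pos_", c("x", "y", "z"), "_", sfx)])
  ankle <- as.matrix(cycle[idx, paste0("ankle_pos_", c("x", "y", "z"), "_", sfx)])

  # ground force in N at the COP
  si <- wrench_si(grf)
  f_g <- si$force[idx, , drop = FALSE]

  sp <- pct[idx] / sf # stance percent of the stance samples
  ok <- is.finite(cop$x_ap) & is.finite(cop$y_ml)
  if (sum(ok) < 2 || min(cop$stance_percent[ok]) > min(sp) + 1e-9 ||
      max(cop$stance_percent[ok]) < max(sp) - 1e-9) {
    abort("COP absent during stance")
  }
  cop_x <- interp_channel(cop$stance_percent[ok], cop$x_ap[ok], sp)
  cop_z <- interp_channel(cop$stance_percent[ok], cop$y_ml[ok], sp)
  cp <- cbind(cop_x, 0, cop_z)

  m_ext <- knee_moment_recursive(knee, ankle, cp, f_g, subject, side, h,
                                 include_segment_dynamics)

  # resolve in the shank frame and apply side-aware sign conventions
  fr <- shank_frame(knee, ankle)
  m_x <- rowSums(m_ext * fr$x)
  m_y <- rowSums(m_ext * fr$y)
  m_z <- rowSums(m_ext * fr$z)
  sgn <- if (side == "right") 1 else -1
  kfm <- -m_z / subject$mass
  kam <- sgn * m_x / subject$mass
  krm <- -sgn * m_y / subject$mass

  out <- tibble(percent = pct, kfm = 0, kam = 0, krm = 0)
  out$kfm[idx] <- kfm
  out$kam[idx] <- kam
  out$krm[idx] <- krm
  structure(out,
    side = side, stance_fraction = sf,
    class = c("knee_moments", class(tibble()))
  )
}

# Newton-Euler recursion foot -> shank; returns the external knee moment
# (moment of ground + gravity + d'Alembert loads distal to the knee) in Nm
knee_moment_recursive <- function(knee, ankle, cop, f_g, subject, side, h,
                                  include_segment_dynamics) {
  n <- nrow(knee)
  g_mat <- matrix(gravity_vec(), n, 3, byrow = TRUE)

  if (include_segment_dynamics) {
    foot <- segment_params(subject, "foot", side)
    shank <- segment_params(subject, "shank", side)
    m_f <- foot$mass
    m_s <- shank$mass
    i_f <- m_f * (foot$gyration_fraction * foot$length)^2
    i_s <- m_s * (shank$gyration_fraction * shank$length)^2
    # foot COM: fixed offset from the ankle (flat-foot assumption)
    com_f <- ankle + matrix(c(0.25 * foot$length, -0.02, 0), n, 3, byrow = TRUE)
    com_s <- knee + shank$com_fraction * (ankle - knee)
    a_f <- apply(com_f, 2, fd_deriv2, h = h)
    a_s <- apply(com_s, 2, fd_deriv2, h = h)
    # sagittal shank angle from vertical; foot assumed flat (alpha = 0)
    v <- ankle - knee
    theta <- atan2(v[, 1], -v[, 2])
    alpha_s <- fd_deriv2(theta, h)
  } else {
    m_f <- m_s <- 0
    i_f <- i_s <- 0
    com_f <- ankle
    com_s <- knee
    a_f <- a_s <- matrix(0, n, 3)
    alpha_s <- numeric(n)
  }

  # foot: force and moment from the shank on the foot (about the ankle)
  f_af <- m_f * a_f - m_f * g_mat - f_g
  m_af <- -cross3(ankle - com_f, f_af) - cross3(cop - com_f, f_g)
  # (foot angular terms vanish under the flat-foot assumption)

  # shank: moment from the thigh on the shank (about the knee)
  f_ks <- m_s * a_s - m_s * g_mat + f_af
  m_ks <- cbind(0, 0, i_s * alpha_s) -
    cross3(knee - com_s, f_ks) - cross3(ankle - com_s, -f_af) + m_af

  -m_ks # external moment about the knee
}

#' @export
print.knee_moments <- function(x, ...) {
  st <- x$percent <= 100 * attr(x, "stance_fraction")
  cat(sprintf(
    "<knee_moments>  %s side; peak |KFM| %.3f, |KAM| %.3f, |KRM| %.3f Nm/kg\n",
    attr(x, "side"), max(abs(x$kfm[st])), max(abs(x$kam[st])),
    max(abs(x$krm[st]))
  ))
  invisible(x)
}
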