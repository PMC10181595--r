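#' Construct a gait trial
#'
#' A `gait_trial` bundles synchronized time series for one walking trial in
#' a single wide tibble: a mandatory `time` column (s, uniform step) plus
#' named channels.  Channel naming conventions used across the package:
#'
#' * joint angles (rad): `hip_flexion_r`, `knee_flexion_l`, ...
#' * joint centre positions (m): `knee_pos_x_r`, `ankle_pos_y_l`, ...
#' * per-foot ground reaction force (BW): `grf_x_r` ... `grf_z_l`
#' * per-foot ground reaction moment about the lab origin (Nm/kg):
#'   `grm_x_r` ... `grm_z_l`
#' * per-foot centre of pressure (m): `cop_x_r`, `cop_z_r`, ...
#' * whole-body COM acceleration (m/s^2): `com_acc_x` ... `com_acc_z`
#'
#' @param data Tibble with `time` plus channel columns.
#' @param events Tibble of gait events (`kind`, `side`, `time`), as
#'   produced by [detect_events()] or supplied externally.
#' @param mass Subject mass in kg; body weight is derived as `mass * 9.81`.
#' @param units Named list recording channel unit families; defaults to
#'   the package conventions above.
#' @param meta Optional list of free-form metadata (subject id, cycle
#'   index, generator truth, ...).
#' @param mask_forces Zero the ground reaction channels outside the event
#'   stance intervals before validating; useful when events come from
#'   threshold detection, which leaves sub-threshold force tails in swing.
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(data, events, mass,
                       units = list(force = "BW", moment = "Nm_per_kg",
                                    angle = "rad", position = "m"),
                       meta = list(), mask_forces = FALSE) {
  data <- as_tibble(data)
  if (!"time" %in% names(data)) abort("trial data must contain a 'time' column")
  events <- as_tibble(events)
  out <- structure(
    list(
      data = data, events = events, mass = mass,
      body_weight = mass * GRAVITY, units = units, meta = meta
    ),
    class = "gait_trial"
  )
  if (mask_forces) out <- zero_outside_stance(out)
  validate_gait_trial(out)
  out
}

#' Validate the gait-trial invariants
#'
#' Checks that time is strictly increasing with a uniform step, that
#' events alternate heel strike / toe off per side, and that ground
#' reaction channels are exactly zero outside stance.
#'
#' @param trial A `gait_trial`.
#' @param tol Numerical tolerance for the uniform-step check.
#' @return The trial, invisibly; errors describe the violated invariant.
#' @export
validate_gait_trial <- function(trial, tol = 1e-8) {
  stopifnot(inherits(trial, "gait_trial"))
  t <- trial$data$time
  dt <- diff(t)
  if (any(dt <= 0)) abort("trial time must be strictly increasing")
  if (diff(range(dt)) > tol * mean(dt) * 100) {
    abort("trial time must have a uniform sampling step")
  }
  for (side in c("right", "left")) {
    ev <- trial$events[trial$events$side == side, , drop = FALSE]
    if (nrow(ev) > 1) {
      ev <- ev[order(ev$time), ]
      if (any(ev$kind[-1] == ev$kind[-nrow(ev)])) {
        abort(paste0(side, "-side events must alternate heel_strike/toe_off"))
      }
    }
    sfx <- substr(side, 1, 1)
    cols <- grep(paste0("^gr[fm]_[xyz]_", sfx, "$"), names(trial$data),
                 value = TRUE)
    if (length(cols)) {
      swing <- !stance_mask(trial$events, side, t)
      vals <- as.matrix(trial$data[swing, cols])
      if (length(vals) && any(vals != 0)) {
        abort(paste0("ground reaction channels must be exactly zero outside ",
                     side, " stance"))
      }
    }
  }
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial>  %d samples @ %.0f Hz, %d channels, %d events, mass %.1f kg\n",
    nrow(x$data), 1 / mean(diff(x$data$time)), ncol(x$data) - 1,
    nrow(x$events), x$mass
  ))
  invisible(x)
}

#' @export
as_tibble.gait_trial <- function(x, ...) x$data

#' Time-normalize one gait cycle to the 101-point convention
#'
#' Resamples every channel of the trial onto 101 equally spaced points
#' spanning one gait cycle (two consecutive ipsilateral heel strikes), the
#' standard convention for gait-waveform analysis, and records the stance
#' fraction from the intervening toe off.
#'
#' @param trial A [gait_trial()].
#' @param hs_start,hs_end Times (s) of two consecutive heel strikes of
#'   `side`; defaults to the first such pair in the event table.
#' @param side Which foot defines the cycle.
#' @param n_points Number of points in the normalized cycle (101 by
#'   convention: 0, 1, ..., 100 percent).
#' @param method Interpolation used for resampling: piecewise `"linear"`
#'   (default) or natural `"cubic"` splines.
#' @return A `normalized_cycle`: a tibble with `percent` plus all resampled
#'   channels, carrying `stance_fraction`, `cycle_duration` (s), `side` and
#'   the subject `mass` as attributes.
#' @export
time_normalize <- function(trial, hs_start = NULL, hs_end = NULL,
                           side = "right", n_points = 101L,
                           method = c("linear", "cubic")) {
  method <- match.arg(method)
  stopifnot(inherits(trial, "gait_trial"))
  ev <- trial$events[trial$events$side == side, , drop = FALSE]
  ev <- ev[order(ev$time), ]
  if (is.null(hs_start) || is.null(hs_end)) {
    hs <- ev$time[ev$kind == "heel_strike"]
    if (length(hs) < 2) abort("need two ipsilateral heel strikes to define a cycle")
    hs_start <- hs_start %||% hs[1]
    hs_end <- hs_end %||% hs[min(which(hs > hs_start))]
  }
  t <- trial$data$time
  eps <- 1e-9 * max(1, diff(range(t)))
  if (hs_start < min(t) - eps || hs_end > max(t) + eps || hs_end <= hs_start) {
    abort("cycle bounds must lie inside the trial time range")
  }
  if (sum(t >= hs_start & t <= hs_end) < 2) {
    abort("cycle must contain at least 2 samples")
  }
  to <- ev$time[ev$kind == "toe_off" & ev$time > hs_start + eps &
                  ev$time < hs_end - eps]
  if (length(to) == 0) abort("no toe_off event inside the cycle")
  stance_fraction <- (to[1] - hs_start) / (hs_end - hs_start)

  tout <- seq(hs_start, hs_end, length.out = n_points)
  channels <- setdiff(names(trial$data), "time")
  res <- purrr::map(trial$data[channels], function(y) {
    interp_channel(t, y, tout, method = method)
  })
  out <- tibble(percent = seq(0, 100, length.out = n_points), !!!res)
  new_normalized_cycle(out,
    stance_fraction = stance_fraction,
    cycle_duration = hs_end - hs_start,
    side = side, mass = trial$mass
  )
}

new_normalized_cycle <- function(data, stance_fraction, cycle_duration,
                                 side, mass) {
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    abort("stance_fraction must lie in (0, 1)")
  }
  structure(
    data,
    stance_fraction = stance_fraction,
    cycle_duration = cycle_duration,
    side = side,
    mass = mass,
    class = c("normalized_cycle", class(tibble()))
  )
}

#' Stance fraction of a normalized cycle
#' @param cycle A `normalized_cycle`.
#' @return Scalar in (0, 1): fraction of the gait cycle spent in stance.
#' @export
stance_fraction <- function(cycle) attr(cycle, "stance_fraction")

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf(
    "<normalized_cycle>  %s side, %d points, stance %.1f%%, duration %.3f s\n",
    attr(x, "side"), nrow(x), 100 * attr(x, "stance_fraction"),
    attr(x, "cycle_duration")
  ))
  NextMethod()
}
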