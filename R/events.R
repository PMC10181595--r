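#' Detect gait events from a vertical ground reaction force channel
#'
#' Heel strikes are upward crossings of `threshold` and toe offs are
#' downward crossings; crossing times are located by linear interpolation
#' between the bracketing samples, so events need not coincide with the
#' sampling grid.
#'
#' @param vertical_grf Vertical GRF waveform in N (one foot).
#' @param time Sample times in s, uniformly spaced and strictly increasing.
#' @param threshold Force threshold in N (> 0); 20 N is the usual
#'   force-plate convention.
#' @param side Which foot the channel belongs to (`"right"` or `"left"`).
#' @return A tibble of events with columns `kind`
#'   (`"heel_strike"`/`"toe_off"`), `side` and `time` (s), ordered in time.
#' @export
#' @examples
#' t <- seq(0, 1.5, by = 0.001)
#' f <- ifelse(t >= 0.5 & t <= 1.1, 800 * sin(pi * (t - 0.5) / 0.6), 0)
#' detect_events(f, t, threshold = 20)
detect_events <- function(vertical_grf, time, threshold = 20,
                          side = "right") {
  stopifnot(length(vertical_grf) == length(time), length(time) >= 2)
  if (threshold <= 0) abort("threshold must be > 0")
  dt <- diff(time)
  if (any(dt <= 0)) abort("time must be strictly increasing")
  above <- vertical_grf >= threshold
  if (!any(above)) abort("no stance detected: signal never crosses threshold")
  if (all(above)) abort("no swing detected: signal always above threshold")

  f <- vertical_grf - threshold
  idx <- which(diff(above) != 0)
  events <- purrr::map(idx, function(i) {
    # linear interpolation of the crossing time in [time[i], time[i+1]]
    tc <- time[i] + (0 - f[i]) / (f[i + 1] - f[i]) * (time[i + 1] - time[i])
    kind <- if (!above[i]) "heel_strike" else "toe_off"
    tibble(kind = kind, side = side, time = tc)
  })
  arrange(bind_rows(events), .data$time)
}

#' Zero force and moment channels outside detected stance intervals
#'
#' Enforces the trial invariant that ground reaction channels are exactly
#' zero during swing.  Stance intervals are taken from the trial's event
#' table (heel strike to the following toe off, per side).
#'
#' @param trial A [gait_trial()] object.
#' @return The trial with per-side `grf_*`/`grm_*` channels zeroed outside
#'   stance.
#' @export
zero_outside_stance <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  dat <- trial$data
  for (side in c("right", "left")) {
    sfx <- substr(side, 1, 1)
    cols <- grep(paste0("^gr[fm]_[xyz]_", sfx, "$"), names(dat), value = TRUE)
    if (length(cols) == 0) next
    in_stance <- stance_mask(trial$events, side, dat$time)
    dat[!in_stance, cols] <- 0
  }
  trial$data <- dat
  trial
}

# logical mask: is each time inside a stance interval for the given side?
stance_mask <- function(events, side, time) {
  ev <- events[events$side == side, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  mask <- rep(FALSE, length(time))
  if (nrow(ev) == 0) return(mask)
  # if the trial starts mid-stance the first event is a toe off
  if (ev$kind[1] == "toe_off") {
    mask <- mask | (time <= ev$time[1])
  }
  hs <- which(ev$kind == "heel_strike")
  for (i in hs) {
    to_after <- ev$time[ev$kind == "toe_off" & ev$time > ev$time[i]]
    end <- if (length(to_after)) min(to_after) else max(time)
    mask <- mask | (time >= ev$time[i] & time <= end)
  }
  mask
}
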