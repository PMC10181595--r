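#' Configuration for the synthetic treadmill-gait generator
#'
#' The generator emulates a knee-osteoarthritis treadmill cohort walking at
#' self-selected speed: per-subject anthropometrics and speed are drawn
#' from truncated normal distributions, each cycle's waveforms are built
#' from smooth deterministic templates (double-hump vertical GRF,
#' braking/propulsion anterior-posterior force, Fourier-type joint-angle
#' curves) perturbed by a shared low-rank latent term, a per-subject
#' random template offset, and white measurement noise.  Because the same
#' latent coefficients drive the kinematic and the ground-reaction blocks,
#' the generated data satisfy the structural assumption under which
#' conditional PPCA prediction of GRFM from kinematics is consistent.
#'
#' Cohort defaults (mass 80.5 +/- 15.3 kg, height 1.65 +/- 0.12 m, speed
#' 0.75 +/- 0.23 m/s, 18 subjects) mirror a typical knee-OA treadmill
#' training cohort.  Variability magnitudes (`latent_sd`,
#' `subject_offset_sd`, noise levels) are package choices documented in
#' the methods vignette, not measured quantities.
#'
#' @param n_subjects Number of subjects.
#' @param cycles_per_subject Gait cycles generated per subject.
#' @param mass_mean,mass_sd Body mass distribution (kg).
#' @param height_mean,height_sd Height distribution (m).
#' @param speed_mean,speed_sd Walking speed distribution (m/s).
#' @param latent_rank Number of shared latent inter-cycle variability
#'   modes (per-cycle coefficients, shared kinematics/GRFM).
#' @param latent_sd Per-mode latent standard deviations; default a
#'   geometrically tapering sequence `0.06 * 0.75^(k-1)` (BW-scale on the
#'   vertical force channel).
#' @param subject_offset_rank Number of fixed smooth modes spanned by the
#'   per-subject template offsets (coefficients constant within subject,
#'   shared between kinematic and GRFM channels).
#' @param subject_offset_sd Total standard deviation of the per-subject
#'   vertical-GRF offset across all offset modes (BW).
#' @param noise_sd_grf White noise SD on force channels (BW), tapered to
#'   zero at stance edges.
#' @param noise_sd_kin White noise SD on joint-angle channels (rad).
#' @param stance_fraction Fraction of the gait cycle spent in stance.
#' @param fs Sampling frequency (Hz).
#' @param seed Integer master seed; every draw is a deterministic function
#'   of `(seed, subject index, cycle index)`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 18L,
                             cycles_per_subject = 100L,
                             mass_mean = 80.5, mass_sd = 15.3,
                             height_mean = 1.65, height_sd = 0.12,
                             speed_mean = 0.75, speed_sd = 0.23,
                             latent_rank = 5L,
                             latent_sd = 0.06 * 0.75^(seq_len(latent_rank) - 1),
                             subject_offset_rank = 12L,
                             subject_offset_sd = 0.035,
                             noise_sd_grf = 0.02,
                             noise_sd_kin = 0.01,
                             stance_fraction = 0.6,
                             fs = 100,
                             seed = 1L) {
  stopifnot(
    n_subjects >= 1, cycles_per_subject >= 1, latent_rank >= 1,
    length(latent_sd) == latent_rank,
    all(c(mass_sd, height_sd, speed_sd, latent_sd,
          subject_offset_sd, noise_sd_grf, noise_sd_kin) >= 0),
    stance_fraction > 0, stance_fraction < 1
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      cycles_per_subject = as.integer(cycles_per_subject),
      mass_mean = mass_mean, mass_sd = mass_sd,
      height_mean = height_mean, height_sd = height_sd,
      speed_mean = speed_mean, speed_sd = speed_sd,
      latent_rank = as.integer(latent_rank), latent_sd = latent_sd,
      subject_offset_rank = as.integer(subject_offset_rank),
      subject_offset_sd = subject_offset_sd,
      noise_sd_grf = noise_sd_grf, noise_sd_kin = noise_sd_kin,
      stance_fraction = stance_fraction, fs = fs,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- abs(x - mean) > 3 * sd
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, mean - 3 * sd), mean + 3 * sd)
}

#' Generate one synthetic subject
#'
#' Draws anthropometrics (truncated at +/- 3 SD), walking speed, and the
#' per-subject template-offset coefficients, then scales a Winter-table
#' subject model.  Deterministic given `(config$seed, index)`.
#'
#' @param config A [generator_config()].
#' @param index Subject index, `1..n_subjects`.
#' @return A [scale_subject()] model with a `gait` attribute holding
#'   `speed` (m/s), `offsets` (offset-mode coefficients) and `index`.
#' @export
generate_subject <- function(config, index) {
  stopifnot(inherits(config, "generator_config"))
  if (index < 1 || index > config$n_subjects) {
    abort("subject index out of range for this config")
  }
  with_seed(derive_seed(config$seed, index, 0), {
    mass <- rnorm_trunc3(1, config$mass_mean, config$mass_sd)
    height <- rnorm_trunc3(1, config$height_mean, config$height_sd)
    speed <- max(0.2, rnorm_trunc3(1, config$speed_mean, config$speed_sd))
    offsets <- rnorm(config$subject_offset_rank)
    subj <- scale_subject(mass, height,
      subject_id = sprintf("S%02d", index)
    )
    attr(subj, "gait") <- list(speed = speed, offsets = offsets, index = index)
    subj
  })
}

gauss_bump <- function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2))

# stance-edge taper: zero at u = 0 and u = 1, smooth inside
stance_window <- function(u) sin(pi * pmin(pmax(u, 0), 1))^0.25

# unwindowed double-hump vertical GRF shape on stance phase u in [0, 1];
# shallow humps, as in slow self-selected-speed pathological gait
vgrf_shape <- function(u) {
  1.05 * gauss_bump(u, 0.25, 0.15) +
    1.02 * gauss_bump(u, 0.75, 0.15) +
    0.70 * gauss_bump(u, 0.50, 0.20)
}

#' Synthetic centre-of-pressure path on the stance phase
#'
#' The COP progresses smoothly from the calcaneus origin towards the toes
#' (a cubic smoothstep of length 0.185 m along the anterior axis) with a
#' small medio-lateral excursion.  Used by the generator to build ground
#' reaction moments, and by validation code as the ground truth that the
#' zero-moment-point inversion must recover.
#'
#' @param u Stance phase in `[0, 1]` (0 = heel strike, 1 = toe off).
#' @param calcaneus_origin Ground-plane `(x, z)` position of the calcaneus
#'   (m): anterior and lateral coordinates.
#' @param side `"right"` or `"left"` (flips the medio-lateral excursion).
#' @return A matrix with columns `x` (anterior) and `z` (lateral), metres.
#' @export
synthetic_cop_path <- function(u, calcaneus_origin = c(-0.08, 0.10),
                               side = "right") {
  u <- pmin(pmax(u, 0), 1)
  s3 <- u^2 * (3 - 2 * u)
  sgn <- if (side == "right") 1 else -1
  cbind(
    x = calcaneus_origin[1] + 0.185 * s3,
    z = calcaneus_origin[2] + sgn * 0.015 * sin(pi * u)
  )
}

# fixed lateral foot placement (ground-plane x, z) per side
calcaneus_origin_side <- function(side) {
  if (side == "right") c(-0.08, 0.10) else c(-0.08, -0.10)
}

# joint-angle templates (radians) on cycle phase x in [0, 1]
angle_templates <- function(x) {
  list(
    hip_flexion = 0.09 + 0.26 * cos(2 * pi * x) + 0.05 * sin(2 * pi * x),
    knee_flexion = 0.08 + 0.15 * gauss_bump(x, 0.15, 0.08) +
      1.00 * gauss_bump(x, 0.72, 0.10),
    ankle_flexion = -0.08 * gauss_bump(x, 0.05, 0.04) +
      0.15 * gauss_bump(x, 0.45, 0.12) -
      0.35 * gauss_bump(x, 0.63, 0.05)
  )
}

# per-channel latent gains: how strongly latent mode k moves each channel
KIN_GAINS <- c(hip_flexion = 0.50, knee_flexion = 0.80, ankle_flexion = 0.35)
GRF_GAINS <- c(v = 1.00, ap = 0.25, ml = 0.10)
# total per-subject kinematic offset SD (rad) at the default vertical-GRF
# offset SD; scaled proportionally with config$subject_offset_sd
KIN_OFFSET_SCALE <- 0.030
KIN_OFFSET_REF <- 0.035

# latent mode shapes on the stance phase for force channels
force_latent_mode <- function(u, k) sin(k * pi * u)
# subject-offset mode shapes on the stance phase
force_offset_mode <- function(u, j) sin(j * pi * u / 2 + 0.7 * j)

# kinematic mode shapes on the cycle phase, distinct per channel
kin_latent_mode <- function(x, k, chan_idx) {
  sin(2 * pi * k * x + 0.35 * chan_idx + 0.20 * k)
}
kin_offset_mode <- function(x, j, chan_idx) {
  sin(2 * pi * (0.5 + 0.5 * j) * x + 0.55 * chan_idx + 0.31 * j)
}

# project a windowed mode to zero cycle-mean by removing a multiple of the
# windowed template (keeps the span and the zero-outside-stance support)
project_zero_mean <- function(mode_full, template_full) {
  mt <- mean(template_full)
  if (abs(mt) < 1e-12) return(mode_full)
  mode_full - (mean(mode_full) / mt) * template_full
}

#' Generate one synthetic gait cycle
#'
#' Builds a single-cycle [gait_trial()] for one subject: per-foot ground
#' reaction forces (BW) and moments about the lab origin (Nm/kg), joint
#' angles (rad), planar joint-centre positions (m), whole-body COM
#' acceleration consistent with the total force, and heel-strike/toe-off
#' events.  Forces are exactly zero outside stance and the whole-cycle
#' mean of the summed vertical GRF is exactly 1 BW.  Ground reaction
#' moments are computed from the generated forces and the
#' [synthetic_cop_path()], so the zero-moment-point inversion is exact on
#' this data by construction.  Deterministic given
#' `(config$seed, subject, cycle_index)`.
#'
#' @param subject A [generate_subject()] model.
#' @param config The [generator_config()] used for the subject.
#' @param cycle_index Cycle number within the subject.
#' @return A [gait_trial()] covering exactly one gait cycle
#'   (right heel strike to right heel strike).
#' @export
generate_cycle <- function(subject, config, cycle_index = 1L) {
  stopifnot(inherits(subject, "subject_model"),
            inherits(config, "generator_config"))
  gait <- attr(subject, "gait")
  if (is.null(gait)) abort("subject lacks generator gait attributes")
  s <- config$stance_fraction
  speed <- gait$speed
  height <- subject$height

  # stride time from a height-proportional stride length
  nt <- max(30L, as.integer(round(0.64 * height / speed * config$fs)) + 1L)
  time <- (seq_len(nt) - 1) / config$fs
  t_cycle <- time[nt]
  x <- time / t_cycle # cycle phase of the right leg

  with_seed(derive_seed(config$seed, gait$index, cycle_index), {
    z <- rnorm(config$latent_rank, 0, config$latent_sd)
    draws <- list(
      noise_f = lapply(1:6, function(i) rnorm(nt)),
      noise_k = lapply(1:6, function(i) rnorm(nt))
    )
    build_cycle_deterministic(subject, config, z, draws, time, x, s, speed)
  })
}

# deterministic assembly given all random draws
build_cycle_deterministic <- function(subject, config, z, draws, time, x, s,
                                      speed) {
  nt <- length(time)
  t_cycle <- time[nt]
  gait <- attr(subject, "gait")
  c_off <- gait$offsets
  J <- config$subject_offset_rank
  off_gain <- if (J > 0) config$subject_offset_sd / sqrt(J) * 0.95^(seq_len(J) - 1) else numeric(0)

  phases <- list(right = x, left = (x + 0.5) %% 1)
  # stance membership from the same time expressions used for the event
  # table, so the zero-outside-stance invariant holds bit-exactly
  stance_of <- function(side) {
    if (side == "right") {
      in_st <- time <= s * t_cycle
      u <- time / (s * t_cycle)
    } else if (s > 0.5) {
      in_st <- time <= (s - 0.5) * t_cycle | time >= 0.5 * t_cycle
      dt <- ifelse(time >= 0.5 * t_cycle, time - 0.5 * t_cycle,
                   time + 0.5 * t_cycle)
      u <- dt / (s * t_cycle)
    } else {
      in_st <- time >= 0.5 * t_cycle & time <= (0.5 + s) * t_cycle
      u <- (time - 0.5 * t_cycle) / (s * t_cycle)
    }
    list(in_st = in_st, u = ifelse(in_st, pmin(pmax(u, 0), 1), NA_real_))
  }
  forces <- list()
  moments <- list()
  for (side in names(phases)) {
    st <- stance_of(side)
    in_st <- st$in_st
    u <- st$u
    w <- ifelse(in_st, stance_window(u), 0)
    w[is.na(w)] <- 0

    tpl_v <- ifelse(in_st, w * vgrf_shape(u), 0)
    # latent + subject-offset vertical modes, projected to zero cycle-mean
    mode_v <- function(fun, idx, gain) {
      m <- ifelse(in_st, w * fun(u, idx), 0)
      gain * project_zero_mean(m, tpl_v)
    }
    fv <- tpl_v
    for (k in seq_len(config$latent_rank)) {
      fv <- fv + z[k] * mode_v(force_latent_mode, k, GRF_GAINS[["v"]])
    }
    for (j in seq_len(J)) {
      fv <- fv + c_off[j] * off_gain[j] *
        project_zero_mean(ifelse(in_st, w * force_offset_mode(u, j), 0), tpl_v)
    }

    fap <- ifelse(in_st, -0.13 * speed * sin(2 * pi * u) * w, 0)
    for (k in seq_len(config$latent_rank)) {
      fap <- fap + z[k] * GRF_GAINS[["ap"]] *
        ifelse(in_st, w * force_latent_mode(u, k + 1), 0)
    }
    # the stance foot pushes the body toward the contralateral side
    sgn <- if (side == "right") -1 else 1
    fml <- ifelse(in_st, sgn * 0.04 * sin(pi * u) * w, 0)
    for (k in seq_len(config$latent_rank)) {
      fml <- fml + z[k] * GRF_GAINS[["ml"]] *
        ifelse(in_st, w * sin((k + 0.5) * pi * u), 0)
    }

    # measurement noise, tapered so stance edges stay exactly zero
    ni <- if (side == "right") 1:3 else 4:6
    fv <- fv + config$noise_sd_grf * w * draws$noise_f[[ni[1]]]
    fap <- fap + 0.5 * config$noise_sd_grf * w * draws$noise_f[[ni[2]]]
    fml <- fml + 0.3 * config$noise_sd_grf * w * draws$noise_f[[ni[3]]]

    forces[[side]] <- cbind(x = fap, y = fv, z = fml)
    moments[[side]] <- list(u = u, in_st = in_st)
  }

  # normalize so the whole-cycle mean of summed vertical GRF is exactly 1 BW
  m_tot <- mean(forces$right[, "y"] + forces$left[, "y"])
  for (side in names(forces)) forces[[side]] <- forces[[side]] / m_tot

  # ground reaction moments (Nm/kg) about the lab origin from the COP path
  for (side in names(forces)) {
    u <- moments[[side]]$u
    in_st <- moments[[side]]$in_st
    cop <- synthetic_cop_path(ifelse(in_st, u, 0),
                              calcaneus_origin_side(side), side)
    r <- cbind(cop[, "x"], 0, cop[, "z"])
    mm <- GRAVITY * cross3(r, forces[[side]])
    mm[!in_st, ] <- 0
    moments[[side]] <- mm
  }

  # joint angles: template + shared latent + subject offset + noise
  ang <- list()
  chans <- names(KIN_GAINS)
  for (side in names(phases)) {
    ph <- phases[[side]]
    tmpl <- angle_templates(ph)
    for (ci in seq_along(chans)) {
      a <- tmpl[[chans[ci]]]
      for (k in seq_len(config$latent_rank)) {
        a <- a + z[k] * KIN_GAINS[[ci]] * kin_latent_mode(ph, k, ci)
      }
      kin_off <- KIN_OFFSET_SCALE * config$subject_offset_sd / KIN_OFFSET_REF
      for (j in seq_len(J)) {
        a <- a + c_off[j] * (kin_off / max(1, sqrt(J))) *
          kin_offset_mode(ph, j, ci)
      }
      ni <- ci + if (side == "right") 0 else 3
      a <- a + config$noise_sd_kin * draws$noise_k[[ni]]
      ang[[paste0(chans[ci], "_", substr(side, 1, 1))]] <- a
    }
  }

  # planar joint-centre positions from the sagittal chain
  pos <- list()
  l_thigh <- 0.245 * subject$height
  l_shank <- 0.246 * subject$height
  hip_y <- 0.530 * subject$height
  for (side in names(phases)) {
    sfx <- substr(side, 1, 1)
    th <- ang[[paste0("hip_flexion_", sfx)]]
    kn <- ang[[paste0("knee_flexion_", sfx)]]
    # knee centre sits slightly lateral of the foot line, giving the
    # medially-placed COP lever that drives the adduction moment
    z_knee <- if (side == "right") 0.12 else -0.12
    z_lat <- if (side == "right") 0.10 else -0.10
    knee_x <- l_thigh * sin(th)
    knee_y <- hip_y - l_thigh * cos(th)
    shank_angle <- th - kn
    ankle_x <- knee_x + l_shank * sin(shank_angle)
    ankle_y <- knee_y - l_shank * cos(shank_angle)
    pos[[paste0("knee_pos_x_", sfx)]] <- knee_x
    pos[[paste0("knee_pos_y_", sfx)]] <- knee_y
    pos[[paste0("knee_pos_z_", sfx)]] <- rep(z_knee, nt)
    pos[[paste0("ankle_pos_x_", sfx)]] <- ankle_x
    pos[[paste0("ankle_pos_y_", sfx)]] <- ankle_y
    pos[[paste0("ankle_pos_z_", sfx)]] <- rep(z_lat, nt)
  }

  # COM acceleration consistent with the summed ground reaction force
  f_tot <- forces$right + forces$left
  com_acc <- GRAVITY * f_tot + matrix(gravity_vec(), nt, 3, byrow = TRUE)

  dat <- tibble(
    time = time,
    !!!ang, !!!pos,
    grf_x_r = forces$right[, "x"], grf_y_r = forces$right[, "y"],
    grf_z_r = forces$right[, "z"],
    grf_x_l = forces$left[, "x"], grf_y_l = forces$left[, "y"],
    grf_z_l = forces$left[, "z"],
    grm_x_r = moments$right[, 1], grm_y_r = moments$right[, 2],
    grm_z_r = moments$right[, 3],
    grm_x_l = moments$left[, 1], grm_y_l = moments$left[, 2],
    grm_z_l = moments$left[, 3],
    com_acc_x = com_acc[, 1], com_acc_y = com_acc[, 2],
    com_acc_z = com_acc[, 3]
  )
  left_ev <- if (s > 0.5) {
    # left foot is mid-stance at both cycle ends
    tibble(kind = c("toe_off", "heel_strike"), side = "left",
           time = c((s - 0.5) * t_cycle, 0.5 * t_cycle))
  } else {
    tibble(kind = c("heel_strike", "toe_off"), side = "left",
           time = c(0.5 * t_cycle, (0.5 + s) * t_cycle))
  }
  events <- arrange(
    bind_rows(
      tibble(kind = c("heel_strike", "toe_off", "heel_strike"),
             side = "right", time = c(0, s * t_cycle, t_cycle)),
      left_ev
    ),
    .data$time
  )
  gait_trial(
    dat, events, subject$mass,
    meta = list(
      subject_id = subject$subject_id,
      speed = speed,
      stance_fraction = s,
      calcaneus = list(right = calcaneus_origin_side("right"),
                       left = calcaneus_origin_side("left")),
      latent = z
    )
  )
}

#' Generate a full synthetic dataset
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per gait cycle: `subject_id`, `cycle`,
#'   and list-columns `subject` (the shared [generate_subject()] model)
#'   and `trial` (the [generate_cycle()] result).  Bit-reproducible from
#'   `config$seed`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, cycles_per_subject = 3)
#' generate_dataset(cfg)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rows <- purrr::map(seq_len(config$n_subjects), function(i) {
    subj <- generate_subject(config, i)
    tibble(
      subject_id = subj$subject_id,
      cycle = seq_len(config$cycles_per_subject),
      subject = list(subj),
      trial = purrr::map(seq_len(config$cycles_per_subject), function(k) {
        generate_cycle(subj, config, k)
      })
    )
  })
  bind_rows(rows)
}

#' Time-normalize every cycle of a generated (or loaded) dataset
#'
#' @param dataset A tibble as returned by [generate_dataset()] (columns
#'   `subject_id`, `cycle`, `trial`).
#' @param side Which leg's heel strikes define the cycles.
#' @return The dataset with the `trial` column replaced by a
#'   `normalized` list-column of [time_normalize()] results.
#' @export
normalize_dataset <- function(dataset, side = "right") {
  dataset$normalized <- purrr::map(dataset$trial, time_normalize, side = side)
  dataset$trial <- NULL
  dataset
}
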