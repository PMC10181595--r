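test_that("whole-body wrench reproduces the textbook cases", {
  subj <- scale_subject(80, 1.70)
  # quiet standing
  w <- whole_body_wrench(matrix(0, 5, 3), subj)
  expect_equal(unique(w$fx), 0)
  expect_equal(unique(w$fy), 1) # exactly 1 BW = 784.8 N for 80 kg
  # free fall
  acc <- matrix(c(0, -9.81, 0), 4, 3, byrow = TRUE)
  wf <- whole_body_wrench(acc, subj)
  expect_equal(max(abs(as.matrix(wf[, c("fx", "fy", "fz")]))), 0)
  # upward 1 m/s^2: F_y = 80 * 10.81 N
  acc2 <- matrix(c(0, 1, 0), 1, 3, byrow = TRUE)
  w2 <- whole_body_wrench(acc2, subj)
  expect_equal(w2$fy * subj$body_weight, 80 * 10.81, tolerance = 1e-12)
  expect_error(whole_body_wrench(matrix(c(NA, 0, 0), 1), subj), "finite")
})

test_that("wrench transport round-trips to machine precision", {
  set.seed(6)
  dat <- tibble::tibble(
    fx = rnorm(20), fy = 700 + rnorm(20), fz = rnorm(20),
    mx = rnorm(20), my = rnorm(20), mz = rnorm(20)
  )
  for (units in list(list(force = "N", moment = "Nm"),
                     list(force = "BW", moment = "Nm_per_kg"))) {
    w <- ground_wrench(dat, units = units, body_mass = 75)
    p <- c(0.31, 0, -0.42)
    back <- transport_wrench(transport_wrench(w, p), c(0, 0, 0))
    expect_equal(back$mx, dat$mx, tolerance = 1e-12)
    expect_equal(back$my, dat$my, tolerance = 1e-12)
    expect_equal(back$mz, dat$mz, tolerance = 1e-12)
  }
})

# a static cycle: constant joint-centre positions, constant vertical force
static_cycle <- function(knee = c(0, 0.45, 0.1), ankle = c(0, 0.07, 0.1)) {
  n <- 101
  fake_cycle(tibble::tibble(
    percent = seq(0, 100, length.out = n),
    knee_pos_x_r = knee[1], knee_pos_y_r = knee[2], knee_pos_z_r = knee[3],
    ankle_pos_x_r = ankle[1], ankle_pos_y_r = ankle[2],
    ankle_pos_z_r = ankle[3]
  ))
}

static_wrench <- function(fy = 700, n = 101, mass = 80) {
  ground_wrench(
    tibble::tibble(fx = 0, fy = fy, fz = 0, mx = 0, my = 0, mz = 0)[rep(1, n), ],
    units = list(force = "N", moment = "Nm"), side = "right",
    body_mass = mass
  )
}

static_cop <- function(x, z) {
  tibble::tibble(stance_percent = c(0, 100), x_ap = x, y_ml = z)
}

test_that("quasi-static lever arm gives the textbook sagittal moment", {
  subj <- scale_subject(80, 1.75)
  cyc <- static_cycle(knee = c(0, 0.45, 0.1))
  km <- knee_moments(cyc, static_wrench(700), static_cop(0.05, 0.1), subj,
                     include_segment_dynamics = FALSE)
  st <- cyc$percent <= 60
  # 700 N acting 0.05 m anterior: |sagittal moment| = 35 Nm
  expect_equal(abs(km$kfm[st][2]) * subj$mass, 35, tolerance = 1e-10)
  # anterior offset is an external extension moment under our convention
  expect_lt(km$kfm[st][2], 0)
  expect_true(all(km$kfm[!st] == 0))
})

test_that("a force line through the knee centre gives zero moments", {
  subj <- scale_subject(80, 1.75)
  cyc <- static_cycle(knee = c(0.02, 0.45, 0.1))
  km <- knee_moments(cyc, static_wrench(650), static_cop(0.02, 0.1), subj,
                     include_segment_dynamics = FALSE)
  expect_lt(max(abs(km$kfm)), 1e-12)
  expect_lt(max(abs(km$kam)), 1e-12)
  expect_lt(max(abs(km$krm)), 1e-12)
})

test_that("vertical force medial to the knee loads adduction on both sides", {
  subj <- scale_subject(80, 1.75)
  for (side in c("right", "left")) {
    sgn <- if (side == "right") 1 else -1
    z_knee <- sgn * 0.1
    cyc0 <- static_cycle(knee = c(0, 0.45, z_knee),
                         ankle = c(0, 0.07, z_knee))
    names(cyc0) <- sub("_r$", paste0("_", substr(side, 1, 1)), names(cyc0))
    cyc <- fake_cycle(cyc0)
    # COP 3 cm medial of the knee
    km <- knee_moments(cyc, static_wrench(700),
                       static_cop(0, z_knee - sgn * 0.03), subj, side = side,
                       include_segment_dynamics = FALSE)
    expect_gt(km$kam[2], 0)
  }
})

test_that("massless-segment moments are linear in the ground force", {
  subj <- scale_subject(70, 1.68)
  cyc <- static_cycle()
  k1 <- knee_moments(cyc, static_wrench(400), static_cop(0.07, 0.08), subj,
                     include_segment_dynamics = FALSE)
  k2 <- knee_moments(cyc, static_wrench(800), static_cop(0.07, 0.08), subj,
                     include_segment_dynamics = FALSE)
  expect_equal(k2$kfm, 2 * k1$kfm, tolerance = 1e-12)
  expect_equal(k2$kam, 2 * k1$kam, tolerance = 1e-12)
})

test_that("the recursive Newton-Euler path matches direct summation", {
  cfg <- quiet_config(latent_sd = 0.04 * 0.75^(0:4))
  subj <- generate_subject(cfg, 1)
  tr <- generate_cycle(subj, cfg, 1)
  cyc <- time_normalize(tr)
  sf <- attr(cyc, "stance_fraction")
  idx <- which(cyc$percent <= 100 * sf + 1e-9)
  wrench <- ground_wrench(
    tibble::tibble(
      fx = cyc$grf_x_r, fy = cyc$grf_y_r, fz = cyc$grf_z_r,
      mx = cyc$grm_x_r, my = cyc$grm_y_r, mz = cyc$grm_z_r
    ),
    side = "right", body_mass = subj$mass
  )
  # exact COP from the generator construction
  u <- cyc$percent[idx] / (100 * sf)
  path <- synthetic_cop_path(u, gaitwrench:::calcaneus_origin_side("right"),
                             "right")
  cop <- tibble::tibble(stance_percent = 100 * u, x_ap = path[, "x"],
                        y_ml = path[, "z"])
  km <- knee_moments(cyc, wrench, cop, subj, side = "right")

  # independent path: direct d'Alembert summation about the knee
  knee <- as.matrix(cyc[idx, c("knee_pos_x_r", "knee_pos_y_r", "knee_pos_z_r")])
  ankle <- as.matrix(cyc[idx, c("ankle_pos_x_r", "ankle_pos_y_r",
                                "ankle_pos_z_r")])
  f_g <- as.matrix(cyc[idx, c("grf_x_r", "grf_y_r", "grf_z_r")]) *
    subj$mass * 9.81
  h <- attr(cyc, "cycle_duration") / 100
  m_oracle <- direct_knee_moment(knee, ankle, cbind(path[, "x"], 0,
                                                    path[, "z"]),
                                 f_g, subj, "right", h)
  # resolve the oracle in the same shank frame / sign convention
  fr <- gaitwrench:::shank_frame(knee, ankle)
  kfm_o <- -rowSums(m_oracle * fr$z) / subj$mass
  kam_o <- rowSums(m_oracle * fr$x) / subj$mass
  krm_o <- -rowSums(m_oracle * fr$y) / subj$mass
  expect_lt(max(abs(km$kfm[idx] - kfm_o)) * subj$mass, 1e-8)
  expect_lt(max(abs(km$kam[idx] - kam_o)) * subj$mass, 1e-8)
  expect_lt(max(abs(km$krm[idx] - krm_o)) * subj$mass, 1e-8)
  # sanity: knee-OA gait shows a clear stance adduction moment
  expect_gt(max(km$kam), 0.1)
})

test_that("missing COP during stance is an error", {
  subj <- scale_subject(80, 1.75)
  cyc <- static_cycle()
  cop_na <- tibble::tibble(stance_percent = c(0, 100),
                           x_ap = c(NA_real_, NA_real_),
                           y_ml = c(0.1, 0.1))
  expect_error(
    knee_moments(cyc, static_wrench(700), cop_na, subj,
                 include_segment_dynamics = FALSE),
    "COP absent"
  )
})
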