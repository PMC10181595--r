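test_that("generation is deterministic in (seed, subject, cycle)", {
  cfg <- generator_config(n_subjects = 2, cycles_per_subject = 2, seed = 42)
  s1 <- generate_subject(cfg, 1)
  s1b <- generate_subject(cfg, 1)
  expect_identical(s1$mass, s1b$mass)
  expect_identical(attr(s1, "gait")$offsets, attr(s1b, "gait")$offsets)
  s2 <- generate_subject(cfg, 2)
  expect_false(s1$mass == s2$mass)

  c1 <- generate_cycle(s1, cfg, 1)
  c1b <- generate_cycle(s1, cfg, 1)
  expect_identical(c1$data, c1b$data)
  c2 <- generate_cycle(s1, cfg, 2)
  expect_false(identical(c1$data$grf_y_r, c2$data$grf_y_r))

  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trial[[3]]$data, d2$trial[[3]]$data)
})

test_that("cohort draws respect the truncated-normal bounds", {
  cfg <- generator_config(seed = 5)
  for (i in seq_len(cfg$n_subjects)) {
    s <- generate_subject(cfg, i)
    expect_lte(abs(s$mass - 80.5), 3 * 15.3)
    expect_lte(abs(s$height - 1.65), 3 * 0.12)
  }
})

test_that("whole-cycle mean of the summed vertical GRF is exactly 1 BW", {
  cfg <- generator_config(n_subjects = 3, cycles_per_subject = 2, seed = 9)
  ds <- generate_dataset(cfg)
  for (tr in ds$trial) {
    expect_equal(mean(tr$data$grf_y_r + tr$data$grf_y_l), 1,
                 tolerance = 1e-9)
  }
})

test_that("per-foot forces vanish exactly beyond the stance window", {
  cfg <- generator_config(n_subjects = 1, cycles_per_subject = 1,
                          stance_fraction = 0.6, seed = 3)
  tr <- generate_cycle(generate_subject(cfg, 1), cfg, 1)
  tt <- tr$data$time
  t_cyc <- max(tt)
  swing <- tt > 0.6 * t_cyc
  expect_true(all(tr$data$grf_y_r[swing] == 0))
  expect_true(all(tr$data$grf_x_r[swing] == 0))
  expect_true(all(tr$data$grm_z_r[swing] == 0))
  expect_silent(validate_gait_trial(tr))
})

test_that("with all variability off the cycle is the deterministic template", {
  cfg <- quiet_config()
  s1 <- generate_subject(cfg, 1)
  s2 <- generate_subject(cfg, 2)
  c11 <- generate_cycle(s1, cfg, 1)
  c12 <- generate_cycle(s1, cfg, 2)
  c21 <- generate_cycle(s2, cfg, 1)
  expect_identical(c11$data, c12$data)
  expect_identical(c11$data, c21$data)
  expect_gt(max(c11$data$grf_y_r), 1.0) # double-hump peaks above body weight
})

test_that("noise-free GRFM waveforms have numerical rank = latent rank", {
  cfg <- generator_config(
    n_subjects = 4, cycles_per_subject = 10,
    mass_sd = 0, height_sd = 0, speed_sd = 0,
    subject_offset_sd = 0, noise_sd_grf = 0, noise_sd_kin = 0,
    latent_rank = 5, seed = 21
  )
  nd <- normalize_dataset(generate_dataset(cfg))
  grfm_cols <- c("grf_x_r", "grf_y_r", "grf_z_r",
                 "grm_x_r", "grm_y_r", "grm_z_r")
  X <- t(vapply(nd$normalized, function(cy) {
    unlist(lapply(grfm_cols, function(ch) cy[[ch]]))
  }, numeric(606)))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  rank <- sum(sv > sv[1] * 1e-8)
  expect_equal(rank, 5)
})

test_that("stacked kinematics+GRFM rank is bounded by latent + offset modes", {
  cfg <- generator_config(
    n_subjects = 6, cycles_per_subject = 6,
    mass_sd = 0, height_sd = 0, speed_sd = 0,
    subject_offset_rank = 3, subject_offset_sd = 0.03,
    noise_sd_grf = 0, noise_sd_kin = 0,
    latent_rank = 4, seed = 22
  )
  nd <- normalize_dataset(generate_dataset(cfg))
  cols <- c("hip_flexion_r", "knee_flexion_r", "ankle_flexion_r",
            "hip_flexion_l", "knee_flexion_l", "ankle_flexion_l",
            "grf_x_r", "grf_y_r", "grf_z_r",
            "grm_x_r", "grm_y_r", "grm_z_r")
  X <- t(vapply(nd$normalized, function(cy) {
    unlist(lapply(cols, function(ch) cy[[ch]]))
  }, numeric(101 * length(cols))))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  rank <- sum(sv > sv[1] * 1e-8)
  expect_lte(rank, 4 + 3)
})

test_that("the implied COP stays inside the foot-sized footprint", {
  u <- seq(0, 1, by = 0.01)
  for (side in c("right", "left")) {
    calc <- gaitwrench:::calcaneus_origin_side(side)
    cop <- synthetic_cop_path(u, calc, side)
    expect_true(all(abs(cop[, "x"] - calc[1]) <= 0.30))
    expect_true(all(abs(cop[, "z"] - calc[2]) <= 0.15))
  }
})

test_that("COM acceleration is consistent with the summed ground force", {
  cfg <- quiet_config()
  s <- generate_subject(cfg, 1)
  tr <- generate_cycle(s, cfg, 1)
  w <- whole_body_wrench(tr$data, s)
  expect_equal(w$fx, tr$data$grf_x_r + tr$data$grf_x_l, tolerance = 1e-12)
  expect_equal(w$fy, tr$data$grf_y_r + tr$data$grf_y_l, tolerance = 1e-12)
  expect_equal(w$fz, tr$data$grf_z_r + tr$data$grf_z_l, tolerance = 1e-12)
})

test_that("dataset size follows the configuration", {
  cfg <- generator_config(n_subjects = 3, cycles_per_subject = 4, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds), 12)
  expect_equal(length(unique(ds$subject_id)), 3)
})
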