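test_that("agreement reproduces hand-computed RMSE and R-squared", {
  a <- c(1, 2, 3, 4)
  ag <- agreement(a, a)
  expect_equal(ag$rmse, 0)
  expect_equal(ag$r2, 1)
  shift <- agreement(a, a + 0.1)
  expect_equal(shift$rmse, 0.1, tolerance = 1e-12)
  hand <- agreement(a, c(1, 2, 3, 5))
  expect_equal(hand$rmse, 0.5)
  expect_equal(hand$r2, 1 - 1 / 5) # SS_res = 1, SS_tot = 5
  flat <- agreement(rep(2, 4), c(1, 2, 3, 4))
  expect_true(is.na(flat$r2))
  expect_false(flat$r2_defined)
})

test_that("rmse satisfies the triangle inequality", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(50)
    b <- rnorm(50)
    c <- rnorm(50)
    expect_lte(agreement(a, c)$rmse,
               agreement(a, b)$rmse + agreement(b, c)$rmse + 1e-12)
  }
})

test_that("peaks are found in the stance halves with local-max preference", {
  n <- 101
  pct <- seq(0, 100, length.out = n)
  sf <- 0.6
  u <- ifelse(pct <= 60, pct / 60, NA)
  w <- ifelse(is.na(u), 0,
              1.10 * exp(-(u - 0.25)^2 / (2 * 0.07^2)) +
                1.05 * exp(-(u - 0.75)^2 / (2 * 0.07^2)))
  ft <- extract_features(w, sf, 1.2)
  expect_equal(ft$peak1, 1.10, tolerance = 1e-3)
  expect_equal(ft$peak2, 1.05, tolerance = 1e-3)
  expect_equal(ft$peak1_pct, 25, tolerance = 2)
  expect_equal(ft$peak2_pct, 75, tolerance = 2)
  expect_false(ft$fallback_flag)
})

test_that("monotone waveforms fall back to window maxima and are flagged", {
  pct <- seq(0, 100, length.out = 101)
  ramp <- pct / 100
  ft <- extract_features(ramp, 0.6, 1)
  # fallback: value at 50% of stance (30% of cycle) and at stance end
  expect_equal(ft$peak1, 0.30, tolerance = 1e-9)
  expect_equal(ft$peak2, 0.60, tolerance = 1e-9)
  expect_true(ft$fallback_flag)
})

test_that("the half-sine stance impulse approaches the analytic 2T/pi", {
  dur <- 1.0
  sf <- 0.6 # stance lasts 0.6 s
  n <- 5001
  pct <- seq(0, 100, length.out = n)
  w <- ifelse(pct <= 60, sin(pi * pct / 60), 0)
  ft <- extract_features(w, sf, dur)
  expect_equal(ft$impulse, 2 * 0.6 / pi, tolerance = 1e-6)
  # impulse is linear in the waveform
  ft2 <- extract_features(2.5 * w, sf, dur)
  expect_equal(ft2$impulse, 2.5 * ft$impulse, tolerance = 1e-12)
  # and proportional to stance duration for a fixed shape
  ft3 <- extract_features(w, sf, 2 * dur)
  expect_equal(ft3$impulse, 2 * ft$impulse, tolerance = 1e-12)
})

test_that("exact Wilcoxon matches the worked enumeration cases", {
  # differences 1, -2, 3, 4: W+ = 8, three of 16 assignments reach it
  r <- wilcoxon_signed_rank(c(2, 1, 6, 8), c(1, 3, 3, 4))
  expect_equal(r$statistic, 8)
  expect_equal(r$p, 0.375, tolerance = 1e-12)
  # a single informative pair can never reach significance
  r1 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 5))
  expect_equal(r1$n, 1)
  expect_equal(r1$p, 1.0)
  # six concordant pairs: one-tail 1/64
  r6 <- wilcoxon_signed_rank(2:7, 1:6)
  expect_equal(r6$p, 0.03125, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate")
})

test_that("exact p equals literal sign enumeration for n <= 10", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n), sample(c(0, 1), 1)) # rounding induces ties
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(got$p, enumerate_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("the exact path agrees with stats::wilcox.test when ties are absent", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    d <- x - y
    if (anyDuplicated(abs(d)) || any(d == 0)) next
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the large-sample approximation stays close to the exact p", {
  set.seed(3)
  d <- rnorm(24) + 0.4
  exact <- wilcoxon_signed_rank(d, rep(0, 24), exact_limit = 25)
  approx <- wilcoxon_signed_rank(d, rep(0, 24), exact_limit = 10)
  expect_equal(approx$method, "normal_approx")
  expect_lt(abs(exact$p - approx$p), 0.01)
})

test_that("BH control matches the brute-force step-up", {
  out <- bh_fdr(c(0.01, 0.02, 0.04, 0.50), 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(0.5, 6))$reject, rep(FALSE, 6))
  expect_true(bh_fdr(0.001)$reject)
  expect_equal(nrow(bh_fdr(numeric())), 0)

  set.seed(29)
  for (i in 1:100) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- bh_fdr(p, 0.05)
    expect_equal(got$reject, stepup_bh_reject(p, 0.05))
    # BH rejections contain the Bonferroni ones and never exceed q
    expect_true(all(got$reject[p <= 0.05 / m]))
    expect_true(all(p[got$reject] <= 0.05))
  }
})

test_that("workflow comparison flags a shifted feature and only that one", {
  set.seed(55)
  ref <- tibble::tibble(
    cycle_id = rep(1:16, 2),
    component = rep(c("medial", "lateral"), each = 16),
    peak1 = rnorm(32, 2.5, 0.3),
    peak2 = rnorm(32, 2.2, 0.3),
    impulse = rnorm(32, 1.1, 0.2)
  )
  est <- ref
  est$impulse[est$component == "medial"] <-
    est$impulse[est$component == "medial"] + 0.3
  cmp <- compare_workflows(ref, est)
  expect_equal(nrow(cmp), 2 * 3)
  hit <- cmp[cmp$component == "medial" & cmp$feature == "impulse", ]
  expect_equal(hit$mad, 0.3, tolerance = 1e-12)
  # constant positive shift: the exact minimum two-sided p at n = 16
  expect_equal(hit$p, 2 / 2^16, tolerance = 1e-12)
  expect_true(hit$reject)
  expect_false(any(cmp$reject[!(cmp$component == "medial" &
                                  cmp$feature == "impulse")]))

  same <- compare_workflows(ref, ref)
  expect_true(all(same$mad == 0))
  expect_false(any(same$reject))
})

test_that("unpaired comparison inputs are rejected", {
  ref <- tibble::tibble(cycle_id = 1:3, component = "medial",
                        peak1 = 1:3, peak2 = 1:3, impulse = 1:3)
  est <- ref[1:2, ]
  expect_error(compare_workflows(ref, est), "paired")
})
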