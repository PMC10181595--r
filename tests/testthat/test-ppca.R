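# layout of six scalar channels, handy for small-model tests
scalar_layout <- function(n_obs = 3, n_tgt = 3) {
  feature_layout(
    observed = paste0("o", seq_len(n_obs)),
    target = paste0("t", seq_len(n_tgt)),
    n_points = 1L, stance_feature = FALSE
  )
}

# assemble a ppca_model by hand (unit scales)
manual_model <- function(mu, W, sigma2, layout) {
  scales <- rep(1, nrow(layout$blocks))
  names(scales) <- layout$blocks$channel
  structure(
    list(mu = mu, W = W, sigma2 = sigma2, q = ncol(W),
         eigenvalues = rep(NA_real_, length(mu)), n = NA, D = length(mu),
         scales = scales, layout = layout),
    class = "ppca_model"
  )
}

test_that("sigma2 is the mean of the discarded sample-covariance eigenvalues", {
  X <- data_with_exact_cov(diag(c(5, 3, 2, 1)), n = 40, seed = 2)
  m <- train_ppca(X, q = 2)
  expect_equal(m$sigma2, 1.5, tolerance = 1e-10)
  # independent oracle: direct eigendecomposition of stats::cov
  lam <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(m$sigma2, mean(lam[3:4]), tolerance = 1e-10)
})

test_that("the fitted subspace matches an independent eigendecomposition", {
  # well-separated spectra, so the top-q eigenspace is sharply defined
  specs <- list(c(9, 6, 4, 2.5, 1.5, 1), c(20, 10, 5, 2, 1, 0.5, 0.2, 0.1))
  for (i in seq_along(specs)) {
    X <- data_with_exact_cov(diag(specs[[i]]), n = 60, seed = 30 + i)
    q <- 3
    m <- train_ppca(X, q = q)
    e <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(m$eigenvalues[1:q], e$values[1:q], tolerance = 1e-10)
    # principal angles between the top-q eigenspace and span(W), via the
    # sine form (residual of projecting one basis onto the other), which
    # stays accurate for tiny angles
    qr_w <- qr.Q(qr(m$W))
    qr_u <- e$vectors[, 1:q, drop = FALSE]
    resid <- qr_u - qr_w %*% crossprod(qr_w, qr_u)
    angles <- asin(pmin(1, svd(resid)$d))
    expect_lt(max(angles), 1e-8)
    # the implied covariance reproduces the top-q spectrum
    C <- m$W %*% t(m$W) + diag(m$sigma2, ncol(X))
    expect_equal(eigen(C, symmetric = TRUE, only.values = TRUE)$values[1:q],
                 e$values[1:q], tolerance = 1e-8)
  }
})

test_that("noise-free low-rank data gives sigma2 = 0 and exact reconstruction", {
  set.seed(7)
  n <- 30
  q <- 3
  D <- 12
  Wt <- matrix(rnorm(D * q), D)
  Z <- matrix(rnorm(n * q), n)
  X <- Z %*% t(Wt) + matrix(rnorm(D), n, D, byrow = TRUE)
  m <- train_ppca(X, q = q)
  expect_lt(m$sigma2, 1e-10)
  # scores reconstruct the centered data exactly in the noiseless limit
  Xc <- sweep(X, 2, m$mu)
  Zhat <- Xc %*% m$W %*% solve(crossprod(m$W))
  expect_lt(max(abs(Zhat %*% t(m$W) - Xc)), 1e-8)
})

test_that("the Gram-matrix path (n < D) agrees with the direct path", {
  set.seed(12)
  X <- matrix(rnorm(20 * 50), 20, 50)
  m <- train_ppca(X, q = 4)
  lam <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(m$eigenvalues[1:4], lam[1:4], tolerance = 1e-8)
  # discarded mean over the min(n-1, D) - q nonzero eigenvalues
  expect_equal(m$sigma2, mean(lam[5:19]), tolerance = 1e-8)
  expect_error(train_ppca(X, q = 20), "q must satisfy")
})

test_that("conditioning at the observed mean returns the target mean", {
  lay <- scalar_layout()
  set.seed(4)
  W <- matrix(rnorm(18), 6, 3)
  mu <- rnorm(6)
  m <- manual_model(mu, W, 0.3, lay)
  pred <- ppca_conditional(m, mu[1:3])
  expect_equal(drop(pred$mean), mu[4:6], tolerance = 1e-12)
})

test_that("latent-space conditioning equals dense Gaussian conditioning", {
  set.seed(99)
  for (rep in 1:100) {
    D <- sample(4:12, 1)
    q <- sample(1:3, 1)
    n_obs <- sample(2:(D - 2), 1)
    lay <- scalar_layout(n_obs, D - n_obs)
    W <- matrix(rnorm(D * q), D)
    mu <- rnorm(D)
    s2 <- runif(1, 0.05, 1)
    x_obs <- rnorm(n_obs)
    m <- manual_model(mu, W, s2, lay)
    got <- drop(ppca_conditional(m, x_obs)$mean)
    want <- dense_conditional_mean(mu, W, s2, 1:n_obs, (n_obs + 1):D, x_obs)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("prediction is affine in the observed vector", {
  lay <- scalar_layout()
  set.seed(8)
  m <- manual_model(rnorm(6), matrix(rnorm(12), 6, 2), 0.2, lay)
  x1 <- rnorm(3)
  x2 <- rnorm(3)
  a <- 0.37
  p <- function(x) drop(ppca_conditional(m, x)$mean)
  lhs <- p(a * x1 + (1 - a) * x2)
  rhs <- a * p(x1) + (1 - a) * p(x2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("noiseless identifiable models recover the true target block", {
  set.seed(17)
  D <- 10
  q <- 3
  n_obs <- 6
  Wt <- matrix(rnorm(D * q), D)
  mu <- rnorm(D)
  n <- 80
  Z <- matrix(rnorm(n * q), n)
  X <- Z %*% t(Wt) + matrix(mu, n, D, byrow = TRUE)
  lay <- scalar_layout(n_obs, D - n_obs)
  m <- train_ppca(X, q = q)
  m$layout <- lay
  m$scales <- stats::setNames(rep(1, nrow(lay$blocks)), lay$blocks$channel)
  z_new <- rnorm(q)
  x_new <- drop(Wt %*% z_new) + mu
  pred <- drop(ppca_conditional(m, x_new[1:n_obs])$mean)
  expect_equal(pred, x_new[(n_obs + 1):D], tolerance = 1e-8)
})

test_that("held-in log-likelihood is non-decreasing in q on the ML path", {
  set.seed(23)
  X <- matrix(rnorm(200 * 8), 200, 8) %*% diag(c(4, 3, 2.2, 1.5, 1, 1, 1, 1))
  lls <- vapply(1:6, function(q) {
    m <- train_ppca(X, q = q)
    ppca_loglik(m, X)
  }, 0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("feature stacking has the documented shape and ordering", {
  cfg <- quiet_config()
  nd <- normalize_dataset(generate_dataset(cfg))
  lay <- feature_layout(
    observed = c("hip_flexion_r", "knee_flexion_r", "ankle_flexion_r"),
    target = paste0(c("grf_x_", "grf_y_", "grf_z_",
                      "grm_x_", "grm_y_", "grm_z_"), "r")
  )
  X <- build_features(nd$normalized[1:2], lay)
  expect_equal(dim(X), c(2L, 9L * 101L + 1L))
  # the stance feature sits in the final column
  sc <- attr(X, "scales")
  expect_equal(X[1, ncol(X)] * sc[["stance_fraction"]], 0.6)
  # permuting cycles permutes rows only
  X2 <- build_features(nd$normalized[2:1], lay, scales = attr(X, "scales"))
  expect_equal(X2[2, ], X[1, ], ignore_attr = TRUE)
  # a cycle lacking a target channel fails loudly
  crippled <- nd$normalized[[1]]
  crippled$grf_y_r <- NULL
  expect_error(build_features(list(crippled), lay), "grf_y_r")
})

test_that("infer_grfm masks predictions outside the stance window", {
  cfg <- quiet_config(n_subjects = 2, cycles_per_subject = 3)
  nd <- normalize_dataset(generate_dataset(cfg))
  lay <- default_layout()
  X <- build_features(nd$normalized, lay)
  m <- train_ppca(X, q = 2)
  pred <- infer_grfm(m, nd$normalized[[1]])
  swing <- pred$percent > 60
  expect_true(all(pred$grf_y_r[swing] == 0))
  expect_true(all(pred$grf_y_r.sd[swing] == 0))
  expect_true(all(pred$grf_y_r.sd >= 0))
  # noise-free identical cycles are reproduced to numerical precision
  expect_lt(max(abs(pred$grf_y_r - nd$normalized[[1]]$grf_y_r)), 1e-6)
})

test_that("model JSON serialization round-trips predictions", {
  cfg <- quiet_config(n_subjects = 2, cycles_per_subject = 3,
                      noise_sd_grf = 0.01, noise_sd_kin = 0.005,
                      latent_sd = rep(0.02, 5))
  nd <- normalize_dataset(generate_dataset(cfg))
  lay <- default_layout()
  m <- train_ppca(build_features(nd$normalized, lay), q = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_ppca_model(m, path)
  m2 <- read_ppca_model(path)
  p1 <- infer_grfm(m, nd$normalized[[1]])
  p2 <- infer_grfm(m2, nd$normalized[[1]])
  expect_equal(p1$grf_y_r, p2$grf_y_r, tolerance = 1e-12)
  expect_equal(m$sigma2, m2$sigma2, tolerance = 1e-12)
})
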