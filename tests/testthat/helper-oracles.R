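# Independent oracles used across the suite.  Each one deliberately takes
# a different computational path from the package implementation.

# --- Gaussian conditioning on the explicitly assembled D x D covariance ---
dense_conditional_mean <- function(mu, W, sigma2, obs_idx, tgt_idx, x_obs) {
  C <- W %*% t(W) + diag(sigma2, length(mu))
  mu_o <- mu[obs_idx]
  mu_t <- mu[tgt_idx]
  C_oo <- C[obs_idx, obs_idx, drop = FALSE]
  C_to <- C[tgt_idx, obs_idx, drop = FALSE]
  drop(mu_t + C_to %*% solve(C_oo, x_obs - mu_o))
}

# --- exact Wilcoxon two-sided p by literal enumeration of all 2^n signs ---
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  p_le <- mean(w_all <= w_obs + 1e-12)
  min(1, 2 * min(p_ge, p_le))
}

# --- Benjamini-Hochberg step-up by direct definition ---
stepup_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# --- direct-summation external knee moment (d'Alembert form) ---
# M_ext = (cop - knee) x F + sum_i (com_i - knee) x (m_i g)
#         - sum_i [ (com_i - knee) x (m_i a_i) + I_i alpha_i z ]
direct_knee_moment <- function(knee, ankle, cop, f_g, subject, side, h,
                               include_segment_dynamics = TRUE) {
  n <- nrow(knee)
  g_vec <- c(0, -9.81, 0)
  cross_rows <- function(a, b) {
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  }
  m_ext <- cross_rows(cop - knee, f_g)
  if (include_segment_dynamics) {
    seg <- function(name) {
      s <- subject$segments
      as.list(s[s$segment == name & s$side %in% c(side, "center"), ][1, ])
    }
    foot <- seg("foot")
    shank <- seg("shank")
    com_f <- ankle + matrix(c(0.25 * foot$length, -0.02, 0), n, 3, byrow = TRUE)
    com_s <- knee + shank$com_fraction * (ankle - knee)
    fd2 <- function(y) {
      d <- numeric(n)
      i <- 3:(n - 2)
      d[i] <- (-y[i - 2] + 16 * y[i - 1] - 30 * y[i] + 16 * y[i + 1] -
                 y[i + 2]) / (12 * h^2)
      d[1] <- (2 * y[1] - 5 * y[2] + 4 * y[3] - y[4]) / h^2
      d[2] <- (y[1] - 2 * y[2] + y[3]) / h^2
      d[n - 1] <- (y[n - 2] - 2 * y[n - 1] + y[n]) / h^2
      d[n] <- (2 * y[n] - 5 * y[n - 1] + 4 * y[n - 2] - y[n - 3]) / h^2
      d
    }
    a_f <- apply(com_f, 2, fd2)
    a_s <- apply(com_s, 2, fd2)
    v <- ankle - knee
    theta <- atan2(v[, 1], -v[, 2])
    alpha_s <- fd2(theta)
    i_s <- shank$mass * (shank$gyration_fraction * shank$length)^2
    for (sg in list(list(m = foot$mass, com = com_f, a = a_f,
                         ialpha = numeric(n)),
                    list(m = shank$mass, com = com_s, a = a_s,
                         ialpha = i_s * alpha_s))) {
      gm <- matrix(sg$m * g_vec, n, 3, byrow = TRUE)
      m_ext <- m_ext + cross_rows(sg$com - knee, gm) -
        cross_rows(sg$com - knee, sg$m * sg$a) -
        cbind(0, 0, sg$ialpha)
    }
  }
  m_ext
}

# --- shared fixture cache (generation is deterministic but not free) ---
.gw_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .gw_cache)) {
    assign(key, force(expr), envir = .gw_cache)
  }
  get(key, envir = .gw_cache)
}

# small noise-free config useful in several files (overridable defaults)
quiet_config <- function(...) {
  args <- list(
    n_subjects = 2, cycles_per_subject = 2,
    mass_sd = 0, height_sd = 0, speed_sd = 0,
    latent_sd = rep(0, 5), subject_offset_sd = 0,
    noise_sd_grf = 0, noise_sd_kin = 0, seed = 11
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# build a centered data matrix whose sample covariance is exactly `cov`
# (n must exceed ncol(cov))
data_with_exact_cov <- function(cov, n, seed = 1) {
  set.seed(seed)
  D <- ncol(cov)
  X <- matrix(rnorm(n * D), n, D)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (n - 1)
  # whiten, then colour with the target covariance
  es <- eigen(S, symmetric = TRUE)
  whiten <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  ec <- eigen(cov, symmetric = TRUE)
  colour <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0))) %*% t(ec$vectors)
  Xc %*% whiten %*% colour
}

# minimal normalized_cycle for unit tests that bypass time_normalize
fake_cycle <- function(data, stance_fraction = 0.6, cycle_duration = 1,
                       side = "right", mass = 80) {
  structure(
    tibble::as_tibble(data),
    stance_fraction = stance_fraction, cycle_duration = cycle_duration,
    side = side, mass = mass,
    class = c("normalized_cycle", class(tibble::tibble()))
  )
}
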