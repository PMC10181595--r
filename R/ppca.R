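#' Define the stacked feature layout for the PPCA model
#'
#' Each gait cycle is stacked into one feature vector: the named waveform
#' channels in order (101 values each by convention), followed by the
#' scalar stance-timing feature.  The observed block (available at
#' prediction time, e.g. joint angles) and the target block (to be
#' inferred, e.g. per-foot GRFM) must not overlap.
#'
#' @param observed Character vector of observed waveform channel names.
#' @param target Character vector of target waveform channel names.
#' @param n_points Samples per waveform channel (101 by convention).
#' @param stance_feature Append the cycle's stance fraction as a scalar
#'   observed feature (the stance-timing input that resolves double-support
#'   ambiguity)?
#' @return A `feature_layout`: list with a `blocks` tibble (`channel`,
#'   `role`, `start`, `end`), total dimension `D`, and `n_points`.
#' @export
#' @examples
#' feature_layout(c("hip_flexion_r", "knee_flexion_r"), c("grf_y_r"))
feature_layout <- function(observed, target, n_points = 101L,
                           stance_feature = TRUE) {
  if (length(intersect(observed, target))) {
    abort("observed and target blocks must not overlap")
  }
  chans <- c(observed, target)
  roles <- c(rep("observed", length(observed)), rep("target", length(target)))
  start <- (seq_along(chans) - 1L) * n_points + 1L
  blocks <- tibble(
    channel = chans, role = roles,
    start = start, end = start + n_points - 1L
  )
  if (stance_feature) {
    nxt <- max(blocks$end) + 1L
    blocks <- bind_rows(blocks, tibble(
      channel = "stance_fraction", role = "observed",
      start = nxt, end = nxt
    ))
  }
  structure(
    list(blocks = blocks, D = max(blocks$end), n_points = as.integer(n_points)),
    class = "feature_layout"
  )
}

#' Default layout: bilateral joint angles predicting right-foot GRFM
#'
#' @param side Foot whose GRFM is the target (`"r"` or `"l"`).
#' @param include_wrench Also observe the whole-body COM acceleration
#'   channels (the whole-body wrench information), when available.
#' @return A [feature_layout()].
#' @export
default_layout <- function(side = "r", include_wrench = FALSE) {
  ang <- c(t(outer(c("hip_flexion_", "knee_flexion_", "ankle_flexion_"),
                   c("r", "l"), paste0)))
  if (include_wrench) ang <- c(ang, "com_acc_x", "com_acc_y", "com_acc_z")
  feature_layout(
    observed = ang,
    target = paste0(c("grf_x_", "grf_y_", "grf_z_",
                      "grm_x_", "grm_y_", "grm_z_"), side)
  )
}

layout_indices <- function(layout, role) {
  b <- layout$blocks[layout$blocks$role == role, , drop = FALSE]
  unlist(purrr::map2(b$start, b$end, seq), use.names = FALSE)
}

#' Stack normalized cycles into a feature matrix
#'
#' Row i is the concatenation of cycle i's channels in layout order, each
#' channel divided by its training-set scale (pooled standard deviation),
#' with the stance fraction appended when the layout requests it.
#'
#' @param cycles List of [time_normalize()] results (or the `normalized`
#'   list-column of [normalize_dataset()]).
#' @param layout A [feature_layout()].
#' @param scales Named per-channel scales; `NULL` (training) computes them
#'   from `cycles` and attaches them to the result.
#' @return An `n x D` matrix with attributes `scales` and `layout`.
#' @export
build_features <- function(cycles, layout, scales = NULL) {
  stopifnot(inherits(layout, "feature_layout"))
  blocks <- layout$blocks
  n <- length(cycles)
  if (n == 0) abort("no cycles supplied")
  X <- matrix(NA_real_, n, layout$D)
  for (bi in seq_len(nrow(blocks))) {
    ch <- blocks$channel[bi]
    idx <- seq(blocks$start[bi], blocks$end[bi])
    if (ch == "stance_fraction") {
      X[, idx] <- vapply(cycles, function(cy) attr(cy, "stance_fraction"), 0)
    } else {
      for (i in seq_len(n)) {
        cy <- cycles[[i]]
        if (!ch %in% names(cy)) {
          abort(paste0("cycle ", i, " lacks channel '", ch, "'"))
        }
        v <- cy[[ch]]
        if (length(v) != layout$n_points) {
          abort(paste0("channel '", ch, "' is not ", layout$n_points,
                       "-point in cycle ", i))
        }
        X[i, idx] <- v
      }
    }
  }
  if (is.null(scales)) {
    scales <- vapply(seq_len(nrow(blocks)), function(bi) {
      idx <- seq(blocks$start[bi], blocks$end[bi])
      s <- stats::sd(as.vector(X[, idx]))
      if (!is.finite(s) || s < 1e-8) 1 else s
    }, 0)
    names(scales) <- blocks$channel
  }
  for (bi in seq_len(nrow(blocks))) {
    idx <- seq(blocks$start[bi], blocks$end[bi])
    X[, idx] <- X[, idx] / scales[[blocks$channel[bi]]]
  }
  attr(X, "scales") <- scales
  attr(X, "layout") <- layout
  X
}

#' Fit a probabilistic PCA model by maximum likelihood
#'
#' Closed-form ML fit of the isotropic latent linear Gaussian model
#' `x = W z + mu + eps`, `eps ~ N(0, sigma2 I)`: `mu` is the column mean,
#' the sample covariance is eigendecomposed (via the `n x n` Gram matrix
#' when `n <= D`), `sigma2` is the mean of the discarded portion of the
#' nonzero spectrum, and `W = U_q (Lambda_q - sigma2 I)^{1/2}`.
#'
#' @param X `n x D` feature matrix, typically from [build_features()]
#'   (its `scales`/`layout` attributes are stored in the model).
#' @param q Number of retained components; `NULL` keeps the smallest q
#'   whose cumulative explained variance reaches `ev_target`.
#' @param ev_target Cumulative explained-variance target for automatic q.
#' @return A `ppca_model`: `mu`, `W`, `sigma2`, `q`, the nonzero
#'   eigenvalue spectrum, the training log-likelihood, and the feature
#'   `layout`/`scales` when available.
#' @export
train_ppca <- function(X, q = NULL, ev_target = 0.95) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("feature matrix contains non-finite values")
  n <- nrow(X)
  D <- ncol(X)
  if (n < 2) abort("need at least 2 training rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  r_nom <- min(n - 1L, D)

  if (n - 1 >= D) {
    S <- crossprod(Xc) / (n - 1)
    e <- eigen(S, symmetric = TRUE)
    lambda <- pmax(e$values, 0)
    U <- e$vectors
  } else {
    K <- tcrossprod(Xc) / (n - 1)
    e <- eigen(K, symmetric = TRUE)
    lambda <- pmax(e$values[seq_len(r_nom)], 0)
    keep <- lambda > max(lambda[1], 1e-300) * 1e-14
    U <- matrix(0, D, r_nom)
    if (any(keep)) {
      sc <- sqrt(lambda[keep] * (n - 1))
      U[, keep] <- crossprod(Xc, e$vectors[, which(keep), drop = FALSE]) %*%
        diag(1 / sc, sum(keep))
    }
  }

  ev_frac <- cumsum(lambda[seq_len(r_nom)]) / sum(lambda[seq_len(r_nom)])
  if (is.null(q)) {
    q <- min(which(ev_frac >= ev_target))
    q <- max(1L, min(q, r_nom - 1L))
  }
  q <- as.integer(q)
  if (q < 1 || q >= min(n, D)) abort("q must satisfy 1 <= q < min(n, D)")

  sigma2 <- if (q < r_nom) mean(lambda[(q + 1):r_nom]) else 0
  W <- U[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(pmax(lambda[seq_len(q)] - sigma2, 0)), q)

  model <- structure(
    list(
      mu = mu, W = W, sigma2 = sigma2, q = q,
      eigenvalues = lambda[seq_len(r_nom)],
      n = n, D = D,
      scales = attr(X, "scales"),
      layout = attr(X, "layout")
    ),
    class = "ppca_model"
  )
  model$loglik <- ppca_train_loglik(model)
  model
}

# training log-likelihood from the fitted spectrum (NA when sigma2 = 0)
ppca_train_loglik <- function(model) {
  lam <- model$eigenvalues
  q <- model$q
  s2 <- model$sigma2
  D <- model$D
  n <- model$n
  if (s2 <= 0) return(NA_real_)
  logdetC <- sum(log(lam[seq_len(q)])) + (D - q) * log(s2)
  trCinvS <- q + sum(lam[-seq_len(q)]) / s2
  -n / 2 * (D * log(2 * pi) + logdetC + trCinvS)
}

#' Log-likelihood of a data matrix under a fitted PPCA model
#'
#' @param model A [train_ppca()] fit.
#' @param X Data matrix in the same (standardized) feature space.
#' @return The Gaussian log-likelihood; `-Inf`-avoiding `NA` if
#'   `sigma2 = 0`.
#' @export
ppca_loglik <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- model$D
  s2 <- model$sigma2
  if (s2 <= 0) return(NA_real_)
  W <- model$W
  q <- model$q
  Xc <- sweep(X, 2, model$mu)
  M <- crossprod(W) + diag(s2, q)
  logdetC <- (D - q) * log(s2) + determinant(M, logarithm = TRUE)$modulus
  trS <- sum(Xc^2) / n
  XW <- Xc %*% W
  trWSW <- sum(XW * t(solve(M, t(XW)))) / n
  trCinvS <- (trS - trWSW) / s2
  as.numeric(-n / 2 * (D * log(2 * pi) + logdetC + trCinvS))
}

# solve M z = b robustly, where M = W_o' W_o + sigma2 I (q x q)
solve_latent <- function(M, B) {
  sv <- svd(M)
  tol <- max(sv$d[1], 1e-300) * 1e-12
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], B) / sv$d[pos])
}

#' Conditional prediction of target features from observed features
#'
#' Gaussian conditioning under the fitted PPCA joint, computed through the
#' q-dimensional latent posterior (never forming the `D x D` covariance):
#' with `M = W_o' W_o + sigma2 I`, the conditional mean of the target
#' block is `mu_t + W_t M^{-1} W_o' (x_o - mu_o)`, identical to
#' `mu_t + C_to C_oo^{-1} (x_o - mu_o)` for the implied covariance
#' `C = W W' + sigma2 I`.  The conditional covariance diagonal is
#' `sigma2 (1 + diag(W_t M^{-1} W_t'))`.
#'
#' @param model A [train_ppca()] fit whose layout defines observed and
#'   target blocks.
#' @param observed Numeric vector over the observed block in natural
#'   (unstandardized) units, or a matrix with one row per case.
#' @return List with `mean` and `sd` matrices (cases x target features),
#'   de-standardized to natural units.
#' @export
ppca_conditional <- function(model, observed) {
  stopifnot(inherits(model, "ppca_model"))
  layout <- model$layout
  if (is.null(layout)) abort("model carries no feature layout")
  io <- layout_indices(layout, "observed")
  it <- layout_indices(layout, "target")
  obs <- if (is.matrix(observed)) observed else matrix(observed, nrow = 1)
  if (ncol(obs) != length(io)) {
    abort(sprintf("observed vector has length %d; layout expects %d",
                  ncol(obs), length(io)))
  }
  scales <- model$scales
  sc_vec <- feature_scale_vector(layout, scales)
  obs_std <- sweep(obs, 2, sc_vec[io], "/")

  W_o <- model$W[io, , drop = FALSE]
  W_t <- model$W[it, , drop = FALSE]
  M <- crossprod(W_o) + diag(model$sigma2, model$q)
  dX <- sweep(obs_std, 2, model$mu[io])
  Z <- t(solve_latent(M, crossprod(W_o, t(dX))))
  mean_std <- sweep(Z %*% t(W_t), 2, model$mu[it], "+")
  WtMinv <- t(solve_latent(M, t(W_t)))
  var_t <- model$sigma2 * (1 + rowSums(WtMinv * W_t))
  mean_nat <- sweep(mean_std, 2, sc_vec[it], "*")
  sd_nat <- matrix(sqrt(pmax(var_t, 0)), nrow(obs), length(it),
                   byrow = TRUE) *
    matrix(sc_vec[it], nrow(obs), length(it), byrow = TRUE)
  list(mean = mean_nat, sd = sd_nat)
}

# expand per-channel scales into a length-D vector (1s when scales absent)
feature_scale_vector <- function(layout, scales) {
  v <- rep(1, layout$D)
  if (is.null(scales)) return(v)
  b <- layout$blocks
  for (bi in seq_len(nrow(b))) {
    v[seq(b$start[bi], b$end[bi])] <- scales[[b$channel[bi]]]
  }
  v
}

#' Infer per-foot GRFM waveforms from a cycle's kinematics
#'
#' Extracts the observed feature block from a normalized cycle, performs
#' PPCA Gaussian conditioning, and returns the predicted GRFM waveforms
#' masked to the stance window (forces and moments are exactly zero beyond
#' `100 * stance_fraction` percent of the cycle), with per-sample
#' posterior standard deviations.
#'
#' @param model A [train_ppca()] fit with a waveform target layout.
#' @param cycle A [time_normalize()] result providing all observed
#'   channels, or a plain numeric vector over the observed block.
#' @param stance_fraction Stance fraction used for masking; defaults to
#'   the cycle's own (required when `cycle` is a bare vector).
#' @return A `grfm_prediction` tibble: `percent`, one column per target
#'   channel, and matching `.sd` columns; attributes `stance_fraction`.
#' @export
infer_grfm <- function(model, cycle, stance_fraction = NULL) {
  layout <- model$layout
  if (is.null(layout)) abort("model carries no feature layout (untrained?)")
  b <- layout$blocks[layout$blocks$role == "observed", , drop = FALSE]
  if (inherits(cycle, "normalized_cycle") || is.data.frame(cycle)) {
    sf <- stance_fraction %||% attr(cycle, "stance_fraction")
    obs <- unlist(purrr::map(b$channel, function(ch) {
      if (ch == "stance_fraction") return(sf)
      if (!ch %in% names(cycle)) abort(paste0("cycle lacks channel '", ch, "'"))
      cycle[[ch]]
    }), use.names = FALSE)
  } else {
    obs <- as.numeric(cycle)
    sf <- stance_fraction
    if (is.null(sf)) abort("stance_fraction is required with a bare vector")
  }
  cond <- ppca_conditional(model, obs)

  tb <- layout$blocks[layout$blocks$role == "target", , drop = FALSE]
  np <- layout$n_points
  pct <- percent_grid(np)
  mask <- pct <= 100 * sf + 1e-9
  out <- tibble(percent = pct)
  pos <- 0L
  for (bi in seq_len(nrow(tb))) {
    idx <- pos + seq_len(np)
    m <- cond$mean[1, idx]
    sdv <- cond$sd[1, idx]
    m[!mask] <- 0
    sdv[!mask] <- 0
    out[[tb$channel[bi]]] <- m
    out[[paste0(tb$channel[bi], ".sd")]] <- sdv
    pos <- pos + np
  }
  structure(out,
    stance_fraction = sf,
    class = c("grfm_prediction", class(tibble()))
  )
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf(
    "<ppca_model>  D = %d features, q = %d components, sigma2 = %.4g\n",
    x$D, x$q, x$sigma2
  ))
  cat(sprintf("  trained on n = %d cycles; top-q explained variance %.1f%%\n",
              x$n, 100 * sum(x$eigenvalues[seq_len(x$q)]) / sum(x$eigenvalues)))
  invisible(x)
}

#' Tidy the PPCA spectrum
#'
#' @param x A `ppca_model`.
#' @param ... Unused.
#' @return One row per nonzero eigenvalue: `component`, `eigenvalue`,
#'   `prop_variance`, `cum_variance`, `retained`.
#' @export
tidy.ppca_model <- function(x, ...) {
  lam <- x$eigenvalues
  tibble(
    component = seq_along(lam),
    eigenvalue = lam,
    prop_variance = lam / sum(lam),
    cum_variance = cumsum(lam) / sum(lam),
    retained = seq_along(lam) <= x$q
  )
}

#' One-row model summary
#'
#' @param x A `ppca_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `d`, `q`, `sigma2`, `ev_retained`, `loglik`.
#' @export
glance.ppca_model <- function(x, ...) {
  tibble(
    n = x$n, d = x$D, q = x$q, sigma2 = x$sigma2,
    ev_retained = sum(x$eigenvalues[seq_len(x$q)]) / sum(x$eigenvalues),
    loglik = x$loglik %||% NA_real_
  )
}
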