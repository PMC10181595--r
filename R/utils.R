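`%||%` <- function(x, y) if (is.null(x)) y else x

#' Linear interpolation of a channel onto new abscissae
#'
#' Thin wrapper around [stats::approx()] that errors outside the input
#' range instead of extrapolating silently.
#' @noRd
interp_channel <- function(x, y, xout, method = c("linear", "cubic")) {
  method <- match.arg(method)
  eps <- 1e-9 * max(1, diff(range(x)))
  if (min(xout) < min(x) - eps || max(xout) > max(x) + eps) {
    abort("interpolation target lies outside the sampled time range")
  }
  xout <- pmin(pmax(xout, min(x)), max(x))
  if (method == "linear") {
    stats::approx(x, y, xout = xout, ties = "ordered")$y
  } else {
    stats::spline(x, y, xout = xout, method = "natural")$y
  }
}

#' First derivative by 5-point central finite differences
#'
#' Interior points use the fourth-order central stencil; the two points at
#' each end fall back to second-order one-sided formulas.
#' @noRd
fd_deriv1 <- function(y, h) {
  n <- length(y)
  if (n < 5) {
    return(c(diff(y) / h, (y[n] - y[n - 1]) / h))
  }
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (y[i - 2] - 8 * y[i - 1] + 8 * y[i + 1] - y[i + 2]) / (12 * h)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
  d[2] <- (y[3] - y[1]) / (2 * h)
  d[n - 1] <- (y[n] - y[n - 2]) / (2 * h)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * h)
  d
}

#' Second derivative, 5-point central stencil with one-sided ends
#' @noRd
fd_deriv2 <- function(y, h) {
  n <- length(y)
  if (n < 5) {
    d1 <- fd_deriv1(y, h)
    return(fd_deriv1(d1, h))
  }
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (-y[i - 2] + 16 * y[i - 1] - 30 * y[i] + 16 * y[i + 1] - y[i + 2]) /
    (12 * h^2)
  d[1] <- (2 * y[1] - 5 * y[2] + 4 * y[3] - y[4]) / h^2
  d[2] <- (y[1] - 2 * y[2] + y[3]) / h^2
  d[n - 1] <- (y[n - 2] - 2 * y[n - 1] + y[n]) / h^2
  d[n] <- (2 * y[n] - 5 * y[n - 1] + 4 * y[n - 2] - y[n - 3]) / h^2
  d
}

# cross product for 3-vectors / row-wise for n x 3 matrices
cross3 <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 3, nrow = max(NROW(a), NROW(b)), byrow = !is.matrix(a))
    b <- matrix(b, ncol = 3, nrow = nrow(a), byrow = !is.matrix(b))
    cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1]
    )
  } else {
    c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
}

#' Deterministic 32-bit rolling hash of character input, for provenance stamps
#' @noRd
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# trapezoidal integral of y over x (uniform or not)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# derive a reproducible sub-seed (< 2^31) from a base seed and indices
derive_seed <- function(seed, ...) {
  parts <- c(seed %% 65011, vapply(list(...), function(k) k %% 9973, 0))
  s <- 104729
  for (p in parts) s <- (s * 31 + p * 2654435) %% 2147483647
  as.integer(s)
}

# percent grid shared by all 101-point gait-cycle waveforms
percent_grid <- function(n = 101L) seq(0, 100, length.out = n)
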