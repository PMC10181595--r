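#' Waveform agreement: RMSE and coefficient of determination
#'
#' `rmse = sqrt(mean((a - b)^2))` and `r2 = 1 - SS_res / SS_tot` with the
#' total sum of squares taken about the mean of `a`, the reference
#' (measured) waveform.  This is the coefficient of determination, not a
#' squared Pearson correlation, so it can be negative for poor estimates.
#'
#' @param a Reference waveform (numeric, length >= 2).
#' @param b Estimated waveform, same length.
#' @return One-row tibble: `rmse`, `r2`, `r2_defined`, `n`.  When the
#'   reference has zero variance, `r2` is `NA` and `r2_defined` is
#'   `FALSE`.
#' @export
#' @examples
#' agreement(c(1, 2, 3, 4), c(1, 2, 3, 5))
agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  rmse <- sqrt(mean(d^2))
  ss_tot <- sum((a - mean(a))^2)
  if (ss_tot < 1e-300) {
    return(tibble(rmse = rmse, r2 = NA_real_, r2_defined = FALSE,
                  n = length(a)))
  }
  tibble(
    rmse = rmse,
    r2 = 1 - sum(d^2) / ss_tot,
    r2_defined = TRUE,
    n = length(a)
  )
}

#' Extract discrete loading features from a gait waveform
#'
#' Computes the first and second peak and the stance impulse of a
#' cycle-normalized waveform.  The stance window is split at 50% of
#' stance: `peak1` is the highest local maximum in the first half,
#' `peak2` in the second half; when a half-window contains no interior
#' local maximum the window's global maximum is used and `fallback_flag`
#' is set.  The impulse is the trapezoidal time integral of the waveform
#' over stance (value x s); since the waveform is zero in swing for
#' ground-reaction channels, integrating over stance only is exact for
#' them and a stated choice for moments.
#'
#' @param waveform Numeric waveform sampled on an equally spaced grid over
#'   the full gait cycle (101 points by convention; any length works).
#' @param stance_fraction Fraction of the cycle in stance, in (0, 1).
#' @param cycle_duration Cycle duration in s.
#' @return One-row tibble: `peak1`, `peak1_pct` (stance %), `peak2`,
#'   `peak2_pct`, `impulse`, `fallback_flag`.
#' @export
extract_features <- function(waveform, stance_fraction, cycle_duration) {
  n <- length(waveform)
  stopifnot(n >= 3, stance_fraction > 0, stance_fraction < 1,
            cycle_duration > 0)
  pct <- seq(0, 100, length.out = n)
  t <- pct / 100 * cycle_duration
  in_st <- pct <= 100 * stance_fraction + 1e-9
  if (sum(in_st) < 2) abort("stance window contains fewer than 2 samples")
  stance_pct <- pct[in_st] / stance_fraction # 0..100 of stance

  pick_peak <- function(lo, hi) {
    w <- which(stance_pct >= lo & stance_pct <= hi)
    if (length(w) == 0) return(list(value = NA_real_, pct = NA_real_, fb = TRUE))
    y <- waveform[in_st][w]
    interior <- which(diff(sign(diff(y))) < 0) + 1L
    if (length(interior)) {
      i <- interior[which.max(y[interior])]
      list(value = y[i], pct = stance_pct[w][i], fb = FALSE)
    } else {
      i <- which.max(y)
      list(value = y[i], pct = stance_pct[w][i], fb = TRUE)
    }
  }
  p1 <- pick_peak(0, 50)
  p2 <- pick_peak(50, 100)

  # trapezoid over stance, with the end interpolated to the exact boundary
  ts <- t[in_st]
  ys <- waveform[in_st]
  t_end <- stance_fraction * cycle_duration
  imp <- trapz(ts, ys)
  last <- max(which(in_st))
  if (last < n && t_end > t[last] + 1e-12) {
    y_end <- ys[length(ys)] +
      (waveform[last + 1] - ys[length(ys)]) * (t_end - t[last]) /
        (t[last + 1] - t[last])
    imp <- imp + (t_end - t[last]) * (ys[length(ys)] + y_end) / 2
  }

  tibble(
    peak1 = p1$value, peak1_pct = p1$pct,
    peak2 = p2$value, peak2_pct = p2$pct,
    impulse = imp,
    fallback_flag = p1$fb || p2$fb
  )
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's convention) and tied absolute
#' differences receive mid-ranks.  For `n <= exact_limit` the two-sided p
#' value is computed from the exact null distribution of `W+` over all
#' `2^n` sign assignments (evaluated by dynamic programming over the
#' doubled rank sums, which is identical to full enumeration); larger
#' samples use the normal approximation with continuity and tie
#' corrections.  The two-sided p is twice the smaller tail probability,
#' capped at 1.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Largest post-drop n for which the exact distribution
#'   is used.
#' @return One-row tibble: `statistic` (W+), `n` (pairs after zero
#'   removal), `p`, `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 1, 6, 8), c(1, 3, 3, 4)) # differences 1,-2,3,4
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("degenerate paired sample: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])

  if (n <= exact_limit) {
    # exact null distribution of 2*W+ over all sign assignments
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- c(1, rep(0, total)) # counts[s + 1] = #assignments with 2W+ = s
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^n
    p_le <- sum(counts[1:(w2 + 1)]) / 2^n
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    cc <- 0.5 * sign(w - mu)
    z <- (w - mu - cc) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(statistic = w, n = n, p = p, method = method)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Computes BH-adjusted q values via [stats::p.adjust()] and flags
#' rejections at `q <= q_threshold` (the step-up procedure at FDR level
#' `q_threshold`).
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param q_threshold FDR level (default 0.05).
#' @return Tibble with `p`, `q`, `reject`; empty input gives an empty
#'   tibble.
#' @export
bh_fdr <- function(pvals, q_threshold = 0.05) {
  if (length(pvals) == 0) {
    return(tibble(p = numeric(), q = numeric(), reject = logical()))
  }
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p values must lie in [0, 1]")
  }
  q <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, q = q, reject = q <= q_threshold)
}

#' Compare per-cycle loading features between two workflows
#'
#' For each (component, feature) pair: the mean absolute difference (MAD)
#' between paired per-cycle values, their RMSE and coefficient of
#' determination, an exact Wilcoxon signed-rank test, and
#' Benjamini-Hochberg q values computed across every feature tested.
#'
#' @param ref_features,est_features Tibbles of per-cycle features from the
#'   reference and estimated workflow: columns `cycle_id`, `component`,
#'   plus one column per feature (any of `peak1`, `peak2`, `impulse`, or
#'   others).
#' @param features Feature columns to compare.
#' @param q_threshold FDR level for rejection flags.
#' @return A `workflow_comparison` tibble with one row per
#'   (component, feature): `mad`, `rmse`, `r2`, `statistic`, `p`, `q`,
#'   `reject`, `n`.
#' @export
compare_workflows <- function(ref_features, est_features,
                              features = c("peak1", "peak2", "impulse"),
                              q_threshold = 0.05) {
  req <- c("cycle_id", "component", features)
  for (nm in req) {
    if (!nm %in% names(ref_features) || !nm %in% names(est_features)) {
      abort(paste0("both feature tables need column '", nm, "'"))
    }
  }
  paired <- dplyr::inner_join(
    ref_features, est_features,
    by = c("cycle_id", "component"), suffix = c("_ref", "_est")
  )
  if (nrow(paired) != nrow(ref_features) || nrow(paired) != nrow(est_features)) {
    abort("inputs are not fully paired by (cycle_id, component)")
  }
  combos <- tidyr::expand_grid(
    component = unique(paired$component), feature = features
  )
  rows <- purrr::pmap(combos, function(component, feature) {
    sub <- paired[paired$component == component, ]
    a <- sub[[paste0(feature, "_ref")]]
    b <- sub[[paste0(feature, "_est")]]
    ag <- agreement(a, b)
    wt <- if (all(a == b)) {
      tibble(statistic = NA_real_, p = 1) # identical workflows: no evidence
    } else {
      wilcoxon_signed_rank(a, b)[, c("statistic", "p")]
    }
    tibble(
      component = component, feature = feature,
      mad = mean(abs(a - b)), rmse = ag$rmse, r2 = ag$r2,
      statistic = wt$statistic, p = wt$p, n = nrow(sub)
    )
  })
  out <- bind_rows(rows)
  fdr <- bh_fdr(out$p, q_threshold)
  out$q <- fdr$q
  out$reject <- fdr$reject
  class(out) <- c("workflow_comparison", class(out))
  out
}
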