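#' Centre of pressure from a ground wrench (zero-moment-point method)
#'
#' Solves `r x F = M` for the point `r` on the ground plane (vertical
#' coordinate 0) about which the horizontal ground reaction moment
#' vanishes.  With the lab convention X anterior, Y vertical, Z right and
#' the wrench expressed about a ground-plane reference point `p`:
#'
#' * `COP_x = p_x + M_z / F_y` (anterior-posterior)
#' * `COP_z = p_z - M_x / F_y` (medio-lateral)
#'
#' Worked sign example: `F = (0, 700, 0)` N with `M = (-35, 0, 70)` Nm
#' about the origin places the COP at `(x, z) = (0.10, 0.05)` m.  Samples
#' whose vertical force is below `fz_threshold` are returned undefined
#' (`NA` with `defined = FALSE`) rather than blowing up, since the ratio
#' diverges as the force vanishes near heel strike and toe off.
#'
#' @param wrench A [ground_wrench()] about a ground-plane reference point
#'   (`reference[2]` must be 0); any units (converted internally to SI).
#' @param fz_threshold Minimum vertical force in N for a defined sample.
#' @param stance_percent Optional stance-phase axis (0-100) for the
#'   samples; taken from a `percent` column via the wrench's
#'   `stance_fraction` attribute when absent, else `0..100` evenly.
#' @return A `cop_trajectory` tibble: `stance_percent`, `x_ap`, `y_ml`
#'   (m), `defined`, `source` (`"raw_zmp"`).
#' @export
cop_from_grfm <- function(wrench, fz_threshold = 20, stance_percent = NULL) {
  stopifnot(inherits(wrench, "ground_wrench"))
  p <- attr(wrench, "reference")
  if (abs(p[2]) > 1e-9) {
    abort("wrench must be expressed about a ground-plane point (reference y = 0)")
  }
  si <- wrench_si(wrench)
  fy <- si$force[, 2]
  ok <- fy >= fz_threshold
  if (!any(ok)) abort("no stance: all samples below the vertical force threshold")
  x <- unname(ifelse(ok, p[1] + si$moment[, 3] / fy, NA_real_))
  z <- unname(ifelse(ok, p[3] - si$moment[, 1] / fy, NA_real_))
  if (is.null(stance_percent)) {
    stance_percent <- seq(0, 100, length.out = nrow(wrench))
  }
  structure(
    tibble(
      stance_percent = stance_percent, x_ap = x, y_ml = z,
      defined = ok, source = "raw_zmp"
    ),
    class = c("cop_trajectory", class(tibble()))
  )
}

# degree-10 polynomial through both anchors: straight line between the
# anchors plus u(1-u) times a degree-8 Chebyshev expansion, fit by least
# squares on the supplied core samples
fit_anchored_poly <- function(u_core, y_core, y0, y1) {
  line <- function(u) y0 + (y1 - y0) * u
  basis <- function(u) {
    t1 <- 2 * u - 1
    out <- matrix(NA_real_, length(u), 9)
    tkm1 <- rep(1, length(u))
    tk <- t1
    out[, 1] <- tkm1
    out[, 2] <- tk
    for (k in 3:9) {
      tkp <- 2 * t1 * tk - tkm1
      out[, k] <- tkp
      tkm1 <- tk
      tk <- tkp
    }
    out * (u * (1 - u))
  }
  A <- basis(u_core)
  beta <- qr.coef(qr(A), y_core - line(u_core))
  beta[is.na(beta)] <- 0
  function(u) line(u) + drop(basis(u) %*% beta)
}

#' Repair a raw zero-moment-point COP trajectory near heel strike/toe off
#'
#' The ZMP ratio diverges where the vertical force vanishes, so the first
#' and last portions of stance (0-15% and 85-100%) are replaced by a
#' 10th-order polynomial anchored at the calcaneus origin: per coordinate,
#' a degree-10 polynomial constrained to pass exactly through the
#' calcaneus position at 0% and 100% stance is least-squares fitted to the
#' reliable 15-85% core samples, evaluated over the endpoint regions, and
#' linearly blended into the raw samples over 2%-wide windows inside the
#' fitted regions so the junctions are continuous.  The 15-85% core is
#' never modified.
#'
#' @param raw A `cop_trajectory` (or tibble with `stance_percent`, `x_ap`,
#'   `y_ml`, optional `defined`) covering at least the 15-85% stance core.
#' @param calcaneus_origin Ground-plane `(x, z)` anchor position in m
#'   (the musculoskeletal model's calcaneus origin), where the COP sits at
#'   heel strike.
#' @param toe_anchor Ground-plane `(x, z)` anchor at toe off.  The COP
#'   leaves the ground under the forefoot, so the default places this one
#'   nominal forward COP excursion (0.20 m, about 80% of an adult foot
#'   length) anterior to the calcaneus origin; pass
#'   `calcaneus_origin + c(0.8 * foot_length, 0)` for a subject-specific
#'   anchor.
#' @param core Percent range of stance treated as reliable raw ZMP output.
#' @return A `cop_trajectory` with `source` equal to `"raw_zmp"` on the
#'   core and `"polynomial_fitted"` on 0-15% and 85-100%; attribute
#'   `calcaneus_origin`.
#' @export
repair_cop <- function(raw, calcaneus_origin,
                       toe_anchor = calcaneus_origin + c(0.20, 0),
                       core = c(15, 85)) {
  sp <- raw$stance_percent
  defined <- if ("defined" %in% names(raw)) raw$defined else
    is.finite(raw$x_ap) & is.finite(raw$y_ml)
  in_core <- sp >= core[1] & sp <= core[2]
  core_ok <- in_core & defined
  if (sum(core_ok) < 12) {
    abort("underdetermined fit: fewer than 12 valid core COP samples")
  }
  if (any(in_core & !defined)) {
    abort("COP must be defined over the whole 15-85% stance core")
  }
  u <- sp / 100

  out <- tibble(
    stance_percent = sp,
    x_ap = raw$x_ap, y_ml = raw$y_ml,
    defined = TRUE,
    source = ifelse(in_core, "raw_zmp", "polynomial_fitted")
  )
  for (coord in c("x_ap", "y_ml")) {
    ci <- if (coord == "x_ap") 1 else 2
    fit <- fit_anchored_poly(u[core_ok], raw[[coord]][core_ok],
                             calcaneus_origin[ci], toe_anchor[ci])
    y <- out[[coord]]
    y[!in_core] <- fit(u[!in_core])
    # blend the fit into the raw junction values over 2% windows; rule = 2
    # tolerates a junction a hair outside the sampled core grid
    lo_val <- stats::approx(sp[core_ok], raw[[coord]][core_ok],
                            xout = core[1], rule = 2)$y
    hi_val <- stats::approx(sp[core_ok], raw[[coord]][core_ok],
                            xout = core[2], rule = 2)$y
    blo <- !in_core & sp >= core[1] - 2 & sp < core[1]
    w_lo <- (sp[blo] - (core[1] - 2)) / 2
    y[blo] <- y[blo] + w_lo * (lo_val - fit(core[1] / 100))
    bhi <- !in_core & sp > core[2] & sp <= core[2] + 2
    w_hi <- 1 - (sp[bhi] - core[2]) / 2
    y[bhi] <- y[bhi] + w_hi * (hi_val - fit(core[2] / 100))
    out[[coord]] <- y
  }
  dist <- sqrt((out$x_ap - calcaneus_origin[1])^2 +
                 (out$y_ml - calcaneus_origin[2])^2)
  if (any(dist > 0.40)) {
    warn("repaired COP leaves the 0.40 m footprint bound around the calcaneus")
  }
  structure(out,
    calcaneus_origin = calcaneus_origin,
    class = c("cop_trajectory", class(tibble()))
  )
}

#' @export
print.cop_trajectory <- function(x, ...) {
  nfit <- sum(x$source == "polynomial_fitted")
  cat(sprintf(
    "<cop_trajectory>  %d samples (%d polynomial-fitted), AP span %.3f m\n",
    nrow(x), nfit, diff(range(x$x_ap, na.rm = TRUE))
  ))
  invisible(x)
}
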