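#' Bundled anthropometric segment-parameter tables
#'
#' Returns the per-segment inertial fractions used by [scale_subject()].
#' The `"winter"` table holds the classical cadaver-based body segment
#' parameters (Winter, Biomechanics and Motor Control of Human Movement,
#' 4th ed.): segment mass as a fraction of body mass, segment length as a
#' fraction of standing height (Drillis-Contini proportions), centre of
#' mass location as a fraction of segment length from the proximal end,
#' and radius of gyration about the segment COM as a fraction of segment
#' length.  Bilateral segments appear once per side so the mass fractions
#' of the full set sum to 1.
#'
#' @param table_id Name of the table; currently only `"winter"`.
#' @return A tibble with columns `segment`, `side`, `mass_fraction`,
#'   `length_fraction`, `com_fraction`, `gyration_fraction`.
#' @export
#' @examples
#' anthropometric_table("winter")
anthropometric_table <- function(table_id = "winter") {
  if (!identical(table_id, "winter")) {
    abort(paste0("unknown anthropometric table: '", table_id, "'"))
  }
  uni <- tibble(
    segment = c("head_neck", "trunk"),
    side = "center",
    mass_fraction = c(0.081, 0.497),
    length_fraction = c(0.182, 0.288),
    com_fraction = c(0.500, 0.500),
    gyration_fraction = c(0.495, 0.503)
  )
  bi <- tibble(
    segment = c("upper_arm", "forearm", "hand", "thigh", "shank", "foot"),
    mass_fraction = c(0.028, 0.016, 0.006, 0.100, 0.0465, 0.0145),
    length_fraction = c(0.186, 0.146, 0.108, 0.245, 0.246, 0.152),
    com_fraction = c(0.436, 0.430, 0.506, 0.433, 0.433, 0.500),
    gyration_fraction = c(0.322, 0.303, 0.297, 0.323, 0.302, 0.475)
  )
  bind_rows(
    uni,
    mutate(bi, side = "right"),
    mutate(bi, side = "left")
  )
}

#' Scale a subject model from mass and height
#'
#' Produces subject-specific segment parameters by scaling a bundled
#' anthropometric table: segment mass = mass_fraction x body mass, segment
#' length = length_fraction x height.  This is the table-based counterpart
#' of marker-based musculoskeletal model scaling, intended for workflows
#' where no static calibration trial is available.
#'
#' @param mass Body mass in kg (> 0).
#' @param height Standing height in m (> 0).
#' @param table_id Anthropometric table name, see [anthropometric_table()].
#' @param subject_id Optional identifier carried through the workflow.
#' @return A `subject_model` object: a list with `subject_id`, `mass` (kg),
#'   `height` (m), `body_weight` (N) and `segments`, a tibble with one row
#'   per segment holding the scaled `mass` (kg) and `length` (m) alongside
#'   the source fractions.
#' @export
#' @examples
#' subj <- scale_subject(mass = 80, height = 1.80)
#' subj$segments[subj$segments$segment == "thigh", ]
scale_subject <- function(mass, height, table_id = "winter",
                          subject_id = "subject") {
  stopifnot(is.numeric(mass), is.numeric(height))
  if (mass <= 0) abort("mass must be > 0")
  if (height <= 0) abort("height must be > 0")
  tab <- anthropometric_table(table_id)
  segments <- mutate(
    tab,
    mass = .data$mass_fraction * !!mass,
    length = .data$length_fraction * !!height
  )
  out <- list(
    subject_id = subject_id,
    mass = mass,
    height = height,
    body_weight = mass * GRAVITY,
    table_id = table_id,
    segments = segments
  )
  class(out) <- "subject_model"
  validate_subject_model(out)
  out
}

validate_subject_model <- function(x) {
  stopifnot(inherits(x, "subject_model"))
  if (x$mass <= 0 || x$height <= 0) abort("subject mass and height must be > 0")
  s <- x$segments
  if (any(s$mass_fraction <= 0 | s$mass_fraction >= 1)) {
    abort("segment mass fractions must lie in (0, 1)")
  }
  if (abs(sum(s$mass_fraction) - 1) > 1e-6) {
    abort("full-body segment mass fractions must sum to 1")
  }
  if (any(s$com_fraction <= 0 | s$com_fraction >= 1) ||
      any(s$gyration_fraction <= 0 | s$gyration_fraction >= 1)) {
    abort("COM and gyration fractions must lie in (0, 1)")
  }
  invisible(x)
}

# convenience accessor: one segment's scaled parameters as a list
segment_params <- function(subject, segment, side = "right") {
  s <- subject$segments
  row <- s[s$segment == segment & s$side %in% c(side, "center"), ]
  if (nrow(row) == 0) abort(paste0("unknown segment: ", segment))
  as.list(row[1, ])
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "<subject_model '%s'>  mass %.1f kg, height %.2f m, body weight %.1f N\n",
    x$subject_id, x$mass, x$height, x$body_weight
  ))
  cat(sprintf("  %d segments from table '%s'\n", nrow(x$segments), x$table_id))
  invisible(x)
}
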