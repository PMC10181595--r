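#' Read an OpenSim storage (.sto) file
#'
#' Parses the OpenSim ASCII storage dialect: free-form `key=value` header
#' lines, a mandatory `endheader` marker, a tab-separated column-name row
#' whose first column is `time`, and numeric data rows.  `nRows` /
#' `nColumns` headers, when present, are validated against the body.
#'
#' @param path File path.
#' @return A tibble of the table; attributes `header` (named list of
#'   header fields) and `name` (first header line when it is not a
#'   key=value pair).
#' @export
read_sto <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) abort("malformed header: no 'endheader' line found")
  end <- end[1]
  header <- list()
  name <- NULL
  for (i in seq_len(end - 1)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      header[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else if (i == 1) {
      name <- ln
    } else {
      abort(sprintf("malformed header at line %d: '%s'", i, ln))
    }
  }
  cols <- strsplit(lines[end + 1], "\t", fixed = TRUE)[[1]]
  cols <- trimws(cols)
  cols <- cols[cols != ""]
  body <- lines[-seq_len(end + 1)]
  body <- body[trimws(body) != ""]
  vals <- purrr::map(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "[\t ]+")[[1]])
  })
  bad <- which(vapply(vals, length, 0L) != length(cols))
  if (length(bad)) {
    abort(sprintf("malformed data row at line %d: expected %d columns",
                  end + 1 + bad[1], length(cols)))
  }
  mat <- do.call(rbind, vals)
  if (!is.null(header$nRows) && as.integer(header$nRows) != nrow(mat)) {
    abort(sprintf("header nRows=%s does not match %d body rows",
                  header$nRows, nrow(mat)))
  }
  if (!is.null(header$nColumns) && as.integer(header$nColumns) != length(cols)) {
    abort(sprintf("header nColumns=%s does not match %d body columns",
                  header$nColumns, length(cols)))
  }
  out <- as_tibble(as.data.frame(mat))
  names(out) <- cols
  if (cols[1] == "time" && is.unsorted(out$time, strictly = FALSE)) {
    abort("time column must be non-decreasing")
  }
  attr(out, "header") <- header
  attr(out, "name") <- name
  out
}

#' Write an OpenSim storage (.sto) file
#'
#' @param data Data frame; first column should be `time`.
#' @param path Output path.
#' @param name Name line written at the top of the header.
#' @param header Named list of extra `key=value` header fields (e.g.
#'   provenance stamps).
#' @param digits Significant digits written (10 keeps round-trips well
#'   inside 1e-8).
#' @return `path`, invisibly.
#' @export
write_sto <- function(data, path, name = "gaitwrench", header = list(),
                      digits = 10) {
  data <- as.data.frame(data)
  base <- list(
    version = 1,
    nRows = nrow(data),
    nColumns = ncol(data),
    inDegrees = header$inDegrees %||% "no"
  )
  header$inDegrees <- NULL
  fields <- c(base, header)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(name, con)
  for (k in names(fields)) writeLines(paste0(k, "=", fields[[k]]), con)
  writeLines("endheader", con)
  writeLines(paste(names(data), collapse = "\t"), con)
  body <- apply(data, 1, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

# channels holding rotational coordinates, for MOT degree conversion
is_angle_channel <- function(nm) {
  grepl("flexion|adduction|rotation|angle|tilt|obliquity|list", nm)
}

#' Read an OpenSim motion (.mot) file
#'
#' Same dialect as [read_sto()]; when the header declares `inDegrees=yes`
#' the rotational coordinate columns (matched by name) are converted to
#' radians, the package's internal angle unit.
#'
#' @param path File path.
#' @param degrees_to_radians Convert angle columns when the file is in
#'   degrees?
#' @return A tibble (angles in radians unless conversion is disabled).
#' @export
read_mot <- function(path, degrees_to_radians = TRUE) {
  out <- read_sto(path)
  hdr <- attr(out, "header")
  if (degrees_to_radians && identical(tolower(hdr$inDegrees %||% "no"), "yes")) {
    for (nm in names(out)) {
      if (nm != "time" && is_angle_channel(nm)) {
        out[[nm]] <- out[[nm]] * pi / 180
      }
    }
    hdr$inDegrees <- "converted_to_radians"
    attr(out, "header") <- hdr
  }
  out
}

#' Write an OpenSim motion (.mot) file
#'
#' Angles are stored internally in radians; by OpenSim convention they are
#' written in degrees with `inDegrees=yes`.
#'
#' @param data Data frame with a `time` column; angle columns matched by
#'   name are converted.
#' @param path Output path.
#' @param in_degrees Write angle columns in degrees?
#' @param ... Passed to [write_sto()].
#' @return `path`, invisibly.
#' @export
write_mot <- function(data, path, in_degrees = TRUE, ...) {
  data <- as.data.frame(data)
  if (in_degrees) {
    for (nm in names(data)) {
      if (nm != "time" && is_angle_channel(nm)) {
        data[[nm]] <- data[[nm]] * 180 / pi
      }
    }
  }
  write_sto(data, path,
            header = list(inDegrees = if (in_degrees) "yes" else "no"), ...)
}

#' Read a marker-trajectory (.trc) file
#'
#' Minimal reader for the Vicon/OpenSim TRC dialect: two metadata rows
#' (`DataRate ...` keys and values), a marker-name row, an X/Y/Z subrow,
#' and numeric data.
#'
#' @param path File path.
#' @return A long tibble with `frame`, `time`, `marker`, `x`, `y`, `z`;
#'   attributes `units` and `data_rate`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) abort("truncated TRC file")
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  meta <- setNames(as.list(vals), keys)
  head_cols <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  markers <- head_cols[-(1:2)]
  markers <- markers[markers != ""]
  body <- lines[-(1:5)]
  body <- body[trimws(body) != ""]
  rows <- purrr::map(body, function(ln) {
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
  })
  n_expect <- 2 + 3 * length(markers)
  bad <- which(vapply(rows, length, 0L) < n_expect)
  if (length(bad)) {
    abort(sprintf("malformed TRC data row %d: expected %d fields",
                  bad[1], n_expect))
  }
  mat <- do.call(rbind, rows)
  long <- purrr::imap(markers, function(mk, i) {
    tibble(
      frame = as.integer(mat[, 1]), time = mat[, 2], marker = mk,
      x = mat[, 2 + 3 * (i - 1) + 1],
      y = mat[, 2 + 3 * (i - 1) + 2],
      z = mat[, 2 + 3 * (i - 1) + 3]
    )
  })
  out <- bind_rows(long)
  attr(out, "units") <- meta$Units %||% NA_character_
  attr(out, "data_rate") <- as.numeric(meta$DataRate %||% NA)
  out
}

#' Read a CSV gait trial with a YAML unit sidecar
#'
#' The CSV dialect is one header row of channel names with a mandatory
#' `time` column.  The sidecar (`<path>.yaml` by default) declares the
#' subject mass and the units of the stored channels
#' (`force: N|BW`, `moment: Nm|Nm_per_kg`, `angle: rad|deg`); raw-Newton
#' forces and Nm moments are converted to the internal BW / Nm-per-kg
#' units using the subject's body weight, degrees to radians.
#'
#' @param path CSV path.
#' @param sidecar YAML sidecar path.
#' @param events Optional event tibble; when `NULL`, events stored in the
#'   sidecar are used if present, otherwise they are threshold-detected
#'   from the vertical force channels (and the forces masked to the
#'   detected stance intervals).
#' @return A [gait_trial()].
#' @export
read_trial_csv <- function(path, sidecar = paste0(path, ".yaml"),
                           events = NULL) {
  dat <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!file.exists(sidecar)) abort(paste0("missing unit sidecar: ", sidecar))
  side <- yaml::read_yaml(sidecar)
  mass <- side$mass
  if (is.null(mass)) abort("sidecar must declare the subject mass (kg)")
  units <- side$units %||% list()
  bw <- mass * GRAVITY
  conv_force <- identical(units$force %||% "BW", "N")
  conv_moment <- identical(units$moment %||% "Nm_per_kg", "Nm")
  conv_angle <- identical(units$angle %||% "rad", "deg")
  for (nm in setdiff(names(dat), "time")) {
    if (conv_force && grepl("^grf_", nm)) dat[[nm]] <- dat[[nm]] / bw
    if (conv_moment && grepl("^grm_", nm)) dat[[nm]] <- dat[[nm]] / mass
    if (conv_angle && is_angle_channel(nm)) dat[[nm]] <- dat[[nm]] * pi / 180
  }
  if (is.null(events) && !is.null(side$events)) {
    events <- as_tibble(dplyr::bind_rows(lapply(side$events, as_tibble)))
  }
  detected <- is.null(events)
  if (detected) {
    events <- bind_rows(purrr::map(c("right", "left"), function(s) {
      ch <- paste0("grf_y_", substr(s, 1, 1))
      if (!ch %in% names(dat)) return(NULL)
      tryCatch(
        detect_events(dat[[ch]] * bw, dat$time, side = s),
        error = function(e) NULL
      )
    }))
  }
  # threshold-detected events leave sub-threshold force tails in swing
  gait_trial(dat, events, mass, meta = list(source = path),
             mask_forces = detected)
}

#' Write a gait trial to CSV (+ YAML sidecar in package units)
#'
#' @param trial A [gait_trial()].
#' @param path Output CSV path; sidecar written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial$data, path, row.names = FALSE)
  events <- lapply(seq_len(nrow(trial$events)), function(i) {
    list(kind = trial$events$kind[i], side = trial$events$side[i],
         time = trial$events$time[i])
  })
  yaml::write_yaml(
    list(mass = trial$mass, units = trial$units, events = events),
    paste0(path, ".yaml")
  )
  invisible(path)
}
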