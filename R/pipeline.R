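#' Configuration for the end-to-end estimation pipeline
#'
#' @param event_threshold Vertical-force threshold for event detection, N.
#' @param fz_threshold Vertical-force threshold below which the ZMP COP is
#'   undefined, N.
#' @param calcaneus_origin Ground-plane `(x, z)` calcaneus anchor for the
#'   COP repair, m.
#' @param side Stance side processed (`"right"` or `"left"`).
#' @param proxy_kcf Also run the frontal-plane contact-force proxy?
#' @param intercondylar_distance Condylar spacing for the proxy, m, in
#'   (0.02, 0.10).
#' @param output_dir Directory for `.sto` / CSV outputs; `NULL` skips
#'   writing.
#' @param verbose Log each stage?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(event_threshold = 20, fz_threshold = 20,
                            calcaneus_origin = calcaneus_origin_side("right"),
                            side = "right",
                            proxy_kcf = FALSE,
                            intercondylar_distance = 0.045,
                            output_dir = NULL, verbose = FALSE) {
  if (event_threshold <= 0 || fz_threshold <= 0) {
    abort("thresholds must be > 0")
  }
  if (intercondylar_distance <= 0.02 || intercondylar_distance >= 0.10) {
    abort("intercondylar_distance must lie in (0.02, 0.10) m")
  }
  structure(
    list(
      event_threshold = event_threshold, fz_threshold = fz_threshold,
      calcaneus_origin = calcaneus_origin, side = side,
      proxy_kcf = proxy_kcf,
      intercondylar_distance = intercondylar_distance,
      output_dir = output_dir, verbose = verbose
    ),
    class = "pipeline_config"
  )
}

pipe_log <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(paste0("[pipeline] ", fmt), ...))
}

# ground_wrench over the cycle grid from an inferred GRFM prediction
prediction_wrench <- function(pred, side, mass) {
  sfx <- substr(side, 1, 1)
  ground_wrench(
    tibble(
      percent = pred$percent,
      fx = pred[[paste0("grf_x_", sfx)]],
      fy = pred[[paste0("grf_y_", sfx)]],
      fz = pred[[paste0("grf_z_", sfx)]],
      mx = pred[[paste0("grm_x_", sfx)]],
      my = pred[[paste0("grm_y_", sfx)]],
      mz = pred[[paste0("grm_z_", sfx)]]
    ),
    side = side, body_mass = mass
  )
}

#' Run the full estimation pipeline on one kinematic trial
#'
#' For every complete gait cycle of the configured side (consecutive
#' ipsilateral heel strikes in the trial's event table):
#' time-normalization, PPCA inference of the per-foot GRFM from the
#' kinematic block, zero-moment-point COP with polynomial endpoint
#' repair, bottom-up external knee moments, and optionally the
#' frontal-plane contact-force proxy.  Deterministic given its inputs.
#' When measured GRFM channels are present in the trial, a per-cycle
#' agreement report (RMSE / R-squared per channel) is produced.
#'
#' @param trial A [gait_trial()] with kinematic channels and events.
#' @param model A trained [train_ppca()] model (or path to a
#'   [write_ppca_model()] JSON file).
#' @param subject The [scale_subject()] model for this trial's subject.
#' @param config A [pipeline_config()].
#' @return A `gw_pipeline` list: `cycles` (tibble with one row per cycle
#'   and list-columns `normalized`, `grfm`, `cop`, `knee_moments`,
#'   `kcf_proxy`), `report` (agreement vs measured GRFM, when available),
#'   and `files` (paths written, when `output_dir` is set).
#' @export
run_pipeline <- function(trial, model, subject, config = pipeline_config()) {
  stopifnot(inherits(trial, "gait_trial"), inherits(config, "pipeline_config"))
  if (is.character(model)) model <- read_ppca_model(model)
  if (is.null(model$layout)) abort("model/layout mismatch: model has no layout")
  if (is.null(trial$events) || nrow(trial$events) == 0) {
    abort("missing input: events (none supplied and none in the trial)")
  }
  side <- config$side
  ev <- trial$events[trial$events$side == side, ]
  hs <- sort(ev$time[ev$kind == "heel_strike"])
  if (length(hs) < 2) abort("no complete gait cycle in the trial events")

  obs_chan <- model$layout$blocks$channel[
    model$layout$blocks$role == "observed" &
      model$layout$blocks$channel != "stance_fraction"
  ]
  miss <- setdiff(obs_chan, names(trial$data))
  if (length(miss)) {
    abort(paste0("model/layout mismatch: trial lacks channels ",
                 paste(miss, collapse = ", ")))
  }

  sfx <- substr(side, 1, 1)
  rows <- purrr::map(seq_len(length(hs) - 1), function(i) {
    cyc <- time_normalize(trial, hs[i], hs[i + 1], side = side)
    pipe_log(config, "cycle %d: normalized (%d samples)", i, nrow(cyc))
    pred <- infer_grfm(model, cyc)
    wrench <- prediction_wrench(pred, side, trial$mass)
    sf <- attr(cyc, "stance_fraction")
    st <- wrench$percent <= 100 * sf + 1e-9
    raw <- cop_from_grfm(
      wrench[st, ],
      fz_threshold = config$fz_threshold,
      stance_percent = wrench$percent[st] / sf
    )
    foot_len <- 0.152 * subject$height
    cop <- repair_cop(
      raw, config$calcaneus_origin,
      toe_anchor = config$calcaneus_origin + c(0.8 * foot_len, 0)
    )
    km <- knee_moments(cyc, wrench, cop, subject, side = side)
    kcf <- if (isTRUE(config$proxy_kcf)) {
      proxy_kcf(km, pred[[paste0("grf_y_", sfx)]],
                config$intercondylar_distance)
    }
    pipe_log(config, "cycle %d: grfm + cop + knee moments done", i)
    tibble(
      cycle = i, hs_start = hs[i], hs_end = hs[i + 1],
      stance_fraction = sf,
      normalized = list(cyc), grfm = list(pred), cop = list(cop),
      knee_moments = list(km), kcf_proxy = list(kcf)
    )
  })
  cycles <- bind_rows(rows)

  report <- pipeline_report(cycles, side)
  files <- if (!is.null(config$output_dir)) {
    write_pipeline_outputs(cycles, report, trial, model, config)
  }
  structure(
    list(cycles = cycles, report = report, files = files,
         side = side, subject_id = subject$subject_id),
    class = "gw_pipeline"
  )
}

# agreement vs measured GRFM channels, when the trial carried them
pipeline_report <- function(cycles, side) {
  sfx <- substr(side, 1, 1)
  chans <- paste0(c("grf_x_", "grf_y_", "grf_z_",
                    "grm_x_", "grm_y_", "grm_z_"), sfx)
  rows <- purrr::map(seq_len(nrow(cycles)), function(i) {
    cyc <- cycles$normalized[[i]]
    pred <- cycles$grfm[[i]]
    have <- intersect(chans, names(cyc))
    if (length(have) == 0) return(NULL)
    bind_rows(purrr::map(have, function(ch) {
      ag <- agreement(cyc[[ch]], pred[[ch]])
      tibble(cycle = cycles$cycle[i], channel = ch,
             rmse = ag$rmse, r2 = ag$r2)
    }))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) NULL else out
}

write_pipeline_outputs <- function(cycles, report, trial, model, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(
    gaitwrench_version = as.character(utils::packageVersion("gaitwrench")),
    model_hash = content_hash(c(model$sigma2, model$q, model$mu[1:5])),
    config_hash = content_hash(unlist(config[c(
      "event_threshold", "fz_threshold", "side", "intercondylar_distance"
    )]))
  )
  sfx <- substr(config$side, 1, 1)
  files <- character()
  flat <- function(col, keep) {
    bind_rows(purrr::map(seq_len(nrow(cycles)), function(i) {
      d <- as_tibble(cycles[[col]][[i]])[, keep]
      d$time <- cycles$hs_start[i] +
        (cycles$hs_end[i] - cycles$hs_start[i]) * d[[1]] / 100
      d[, c("time", setdiff(keep, names(d)[1]))]
    }))
  }
  grfm_cols <- c("percent", paste0(c("grf_x_", "grf_y_", "grf_z_",
                                     "grm_x_", "grm_y_", "grm_z_"), sfx))
  p <- file.path(config$output_dir, "grfm.sto")
  write_sto(flat("grfm", grfm_cols), p, name = "estimated_grfm",
            header = stamp)
  files <- c(files, p)
  cop_all <- bind_rows(purrr::map(seq_len(nrow(cycles)), function(i) {
    d <- as_tibble(cycles$cop[[i]])
    d$time <- cycles$hs_start[i] + d$stance_percent / 100 *
      cycles$stance_fraction[i] *
      (cycles$hs_end[i] - cycles$hs_start[i])
    d[, c("time", "x_ap", "y_ml")]
  }))
  p <- file.path(config$output_dir, "cop.sto")
  write_sto(cop_all, p, name = "estimated_cop", header = stamp)
  files <- c(files, p)
  p <- file.path(config$output_dir, "knee_moments.sto")
  write_sto(flat("knee_moments", c("percent", "kfm", "kam", "krm")), p,
            name = "external_knee_moments", header = stamp)
  files <- c(files, p)
  if (isTRUE(config$proxy_kcf)) {
    p <- file.path(config$output_dir, "kcf_proxy.sto")
    write_sto(flat("kcf_proxy", c("percent", "medial", "lateral", "total")),
              p, name = "kcf_frontal_plane_proxy", header = stamp)
    files <- c(files, p)
  }
  if (!is.null(report)) {
    p <- file.path(config$output_dir, "report.csv")
    utils::write.csv(report, p, row.names = FALSE)
    files <- c(files, p)
  }
  files
}

#' @export
print.gw_pipeline <- function(x, ...) {
  cat(sprintf("<gw_pipeline>  %d cycles (%s side, subject %s)\n",
              nrow(x$cycles), x$side, x$subject_id))
  if (!is.null(x$report)) {
    cat("  agreement vs measured GRFM:\n")
    print(x$report %>% group_by(.data$channel) %>%
            summarise(rmse = mean(.data$rmse), r2 = mean(.data$r2),
                      .groups = "drop"))
  }
  invisible(x)
}
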