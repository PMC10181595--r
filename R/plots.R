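#' Plot a normalized gait cycle
#'
#' Facetted waveforms over the gait cycle, with the stance/swing boundary
#' marked.
#'
#' @param object A [time_normalize()] result.
#' @param channels Channels to show; defaults to all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_cycle <- function(object, channels = NULL, ...) {
  channels <- channels %||% setdiff(names(object), "percent")
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("percent", channels)],
    -"percent", names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$percent, .data$value)) +
    ggplot2::geom_vline(
      xintercept = 100 * attr(object, "stance_fraction"),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = NULL)
}

#' Plot inferred GRFM waveforms with posterior uncertainty bands
#'
#' @param object An [infer_grfm()] prediction.
#' @param level Width of the plotted band in posterior standard
#'   deviations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grfm_prediction <- function(object, level = 1.96, ...) {
  chans <- setdiff(names(object), c("percent", grep("\\.sd$", names(object),
                                                    value = TRUE)))
  long <- bind_rows(purrr::map(chans, function(ch) {
    tibble(
      percent = object$percent, channel = ch,
      value = object[[ch]],
      lo = object[[ch]] - level * object[[paste0(ch, ".sd")]],
      hi = object[[ch]] + level * object[[paste0(ch, ".sd")]]
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$percent, .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)", y = "BW / Nm/kg")
}

#' Plot a centre-of-pressure path
#'
#' Ground-plane COP path coloured by provenance (raw zero-moment-point
#' samples vs polynomial-fitted endpoint regions).
#'
#' @param object A `cop_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cop_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$x_ap, .data$y_ml, colour = .data$source)
  ) +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior-posterior (m)", y = "medio-lateral (m)",
                  colour = NULL)
  calc <- attr(object, "calcaneus_origin")
  if (!is.null(calc)) {
    p <- p + ggplot2::annotate("point", x = calc[1], y = calc[2],
                               shape = 4, size = 3)
  }
  p
}

#' Plot external knee moments over the gait cycle
#'
#' @param object A [knee_moments()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knee_moments <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"percent",
                              names_to = "moment", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$percent, .data$value,
                                     colour = .data$moment)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gait cycle (%)", y = "external moment (Nm/kg)",
                  colour = NULL)
}

#' Plot cross-validated GRFM error by channel and subject
#'
#' Pooled per-channel RMSE bars with per-subject means overlaid.
#'
#' @param object A [cv_grfm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gw_cv <- function(object, ...) {
  ggplot2::ggplot(object$pooled,
                  ggplot2::aes(.data$channel, .data$rmse_mean)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_point(
      data = object$per_subject,
      ggplot2::aes(.data$channel, .data$rmse_mean),
      position = ggplot2::position_jitter(width = 0.1, height = 0),
      alpha = 0.7
    ) +
    ggplot2::labs(x = NULL, y = "cross-validated RMSE (channel units)",
                  title = sprintf("%s cross-validation", object$scheme))
}
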