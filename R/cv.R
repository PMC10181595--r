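#' Cross-validated GRFM prediction error
#'
#' Trains the PPCA model on all cycles outside the held-out fold (feature
#' scales are recomputed from each training fold so nothing leaks from the
#' held-out data), predicts the held-out cycles' target block from their
#' observed block, and scores each predicted waveform against the truth
#' with [agreement()] (RMSE and R-squared, stance-masked like
#' [infer_grfm()]).
#'
#' Folds: `scheme = "subject"` is leave-one-subject-out (the paper-style
#' validation of generalization to unseen subjects); `scheme = "cycle"` is
#' leave-one-cycle-out, which keeps every subject represented in training
#' and therefore bounds the subject-generalization penalty from below.
#'
#' @param dataset Tibble with columns `subject_id`, `cycle` and a
#'   `normalized` list-column (see [normalize_dataset()]).
#' @param layout A [feature_layout()].
#' @param q Components to retain; `NULL` for automatic selection per fold.
#' @param scheme `"subject"` (LOSO) or `"cycle"` (LOCO).
#' @return A `gw_cv` object: `per_cycle` (one row per cycle x channel),
#'   `per_subject` and `pooled` summaries (mean/sd of per-cycle values,
#'   matching the usual per-cycle aggregation style of gait studies),
#'   plus the scheme and q used.
#' @export
cv_grfm <- function(dataset, layout, q = NULL,
                    scheme = c("subject", "cycle")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("subject_id", "cycle", "normalized") %in% names(dataset)))
  subj <- dataset$subject_id
  if (scheme == "subject" && length(unique(subj)) < 2) {
    abort("leave-one-subject-out needs at least 2 subjects")
  }
  counts <- table(subj)
  if (any(counts == 0)) abort("a subject with zero cycles was supplied")

  cycles <- dataset$normalized
  X_raw <- build_features(cycles, layout,
                          scales = unit_scales(layout))
  blocks <- layout$blocks
  tb <- blocks[blocks$role == "target", , drop = FALSE]
  np <- layout$n_points
  it <- layout_indices(layout, "target")
  io <- layout_indices(layout, "observed")
  sfs <- vapply(cycles, function(cy) attr(cy, "stance_fraction"), 0)

  fold_id <- if (scheme == "subject") match(subj, unique(subj)) else
    seq_len(nrow(dataset))
  res <- vector("list", max(fold_id))
  for (f in sort(unique(fold_id))) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    scales <- fold_scales(X_raw[train, , drop = FALSE], blocks)
    sc_vec <- feature_scale_vector(layout, scales)
    Xtr <- sweep(X_raw[train, , drop = FALSE], 2, sc_vec, "/")
    model <- train_ppca(Xtr, q = q)
    model$scales <- scales
    model$layout <- layout

    pred <- ppca_conditional(model, X_raw[test, io, drop = FALSE])$mean
    truth <- X_raw[test, it, drop = FALSE]
    res[[f]] <- score_fold(pred, truth, test, dataset, tb, np, sfs)
  }
  per_cycle <- bind_rows(res)

  per_subject <- per_cycle %>%
    group_by(.data$subject_id, .data$channel) %>%
    summarise(
      rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
      r2_mean = mean(.data$r2), r2_sd = stats::sd(.data$r2),
      n_cycles = dplyr::n(), .groups = "drop"
    )
  pooled <- per_cycle %>%
    group_by(.data$channel) %>%
    summarise(
      rmse_mean = mean(.data$rmse), rmse_sd = stats::sd(.data$rmse),
      r2_mean = mean(.data$r2), r2_sd = stats::sd(.data$r2),
      n_cycles = dplyr::n(), .groups = "drop"
    )
  structure(
    list(per_cycle = per_cycle, per_subject = per_subject, pooled = pooled,
         scheme = scheme, q = q, n_folds = length(unique(fold_id))),
    class = "gw_cv"
  )
}

unit_scales <- function(layout) {
  s <- rep(1, nrow(layout$blocks))
  names(s) <- layout$blocks$channel
  s
}

fold_scales <- function(X_train, blocks) {
  s <- vapply(seq_len(nrow(blocks)), function(bi) {
    v <- stats::sd(as.vector(X_train[, seq(blocks$start[bi], blocks$end[bi])]))
    if (!is.finite(v) || v < 1e-8) 1 else v
  }, 0)
  names(s) <- blocks$channel
  s
}

score_fold <- function(pred, truth, test, dataset, tb, np, sfs) {
  rows <- vector("list", length(test) * nrow(tb))
  k <- 0L
  pct <- percent_grid(np)
  for (i in seq_along(test)) {
    mask <- pct <= 100 * sfs[test[i]] + 1e-9
    for (bi in seq_len(nrow(tb))) {
      idx <- (bi - 1) * np + seq_len(np)
      p <- pred[i, idx]
      p[!mask] <- 0
      ag <- agreement(truth[i, idx], p)
      k <- k + 1L
      rows[[k]] <- tibble(
        subject_id = dataset$subject_id[test[i]],
        cycle = dataset$cycle[test[i]],
        channel = tb$channel[bi],
        rmse = ag$rmse, r2 = ag$r2
      )
    }
  }
  bind_rows(rows)
}

#' Leave-one-subject-out GRFM cross-validation
#' @inheritParams cv_grfm
#' @return See [cv_grfm()].
#' @export
loso_cv <- function(dataset, layout, q = NULL) {
  cv_grfm(dataset, layout, q = q, scheme = "subject")
}

#' Leave-one-cycle-out GRFM cross-validation
#' @inheritParams cv_grfm
#' @return See [cv_grfm()].
#' @export
loco_cv <- function(dataset, layout, q = NULL) {
  cv_grfm(dataset, layout, q = q, scheme = "cycle")
}

#' @export
print.gw_cv <- function(x, ...) {
  cat(sprintf("<gw_cv>  %s scheme, %d folds\n",
              if (x$scheme == "subject") "leave-one-subject-out"
              else "leave-one-cycle-out", x$n_folds))
  print(x$pooled)
  invisible(x)
}

#' Per-cycle (or aggregated) cross-validation scores
#'
#' @param x A [cv_grfm()] result.
#' @param level `"cycle"`, `"subject"` or `"pooled"`.
#' @param ... Unused.
#' @return The requested tibble of scores.
#' @export
tidy.gw_cv <- function(x, level = c("subject", "cycle", "pooled"), ...) {
  level <- match.arg(level)
  switch(level,
    cycle = x$per_cycle,
    subject = x$per_subject,
    pooled = x$pooled
  )
}

#' One-row cross-validation summary (vertical GRF channel)
#'
#' @param x A [cv_grfm()] result.
#' @param channel Channel summarised; defaults to the vertical force of
#'   the first target foot if present, else the first channel.
#' @param ... Unused.
#' @export
glance.gw_cv <- function(x, channel = NULL, ...) {
  pooled <- x$pooled
  channel <- channel %||% {
    v <- grep("^grf_y_", pooled$channel, value = TRUE)
    if (length(v)) v[1] else pooled$channel[1]
  }
  row <- pooled[pooled$channel == channel, ]
  tibble(
    scheme = x$scheme, n_folds = x$n_folds, channel = channel,
    rmse = row$rmse_mean, rmse_sd = row$rmse_sd,
    r2 = row$r2_mean, r2_sd = row$r2_sd
  )
}
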