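PPCA_MODEL_FORMAT <- 1L

#' Serialize a fitted PPCA model to JSON
#'
#' Writes a single-file JSON representation (format-versioned) holding the
#' mean vector, loading matrix, noise variance, eigenvalue spectrum,
#' per-channel scales and the feature layout, so a trained model can be
#' shipped and reloaded without the training data.
#'
#' @param model A [train_ppca()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppca_model <- function(model, path) {
  stopifnot(inherits(model, "ppca_model"))
  layout <- model$layout
  obj <- list(
    format_version = PPCA_MODEL_FORMAT,
    package_version = as.character(utils::packageVersion("gaitwrench")),
    mu = model$mu,
    W = lapply(seq_len(ncol(model$W)), function(j) model$W[, j]),
    sigma2 = model$sigma2,
    q = model$q,
    eigenvalues = model$eigenvalues,
    n = model$n, D = model$D,
    scales = as.list(model$scales),
    layout = if (!is.null(layout)) list(
      n_points = layout$n_points,
      blocks = lapply(seq_len(nrow(layout$blocks)), function(i) {
        as.list(layout$blocks[i, ])
      })
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a PPCA model written by [write_ppca_model()]
#'
#' @param path JSON path.
#' @return A `ppca_model`.
#' @export
read_ppca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version > PPCA_MODEL_FORMAT) {
    abort("unsupported PPCA model format version")
  }
  layout <- NULL
  if (!is.null(obj$layout)) {
    blocks <- as_tibble(obj$layout$blocks)
    layout <- structure(
      list(
        blocks = mutate(blocks,
                        start = as.integer(.data$start),
                        end = as.integer(.data$end)),
        D = max(blocks$end),
        n_points = as.integer(obj$layout$n_points)
      ),
      class = "feature_layout"
    )
  }
  W <- if (is.list(obj$W)) do.call(cbind, obj$W) else as.matrix(obj$W)
  # the JSON holds W column-wise; simplification may yield a q x D matrix
  if (nrow(W) == obj$q && ncol(W) == length(obj$mu) && obj$q != length(obj$mu)) {
    W <- t(W)
  }
  if (!all(dim(W) == c(length(obj$mu), obj$q))) {
    abort("corrupt model file: loading matrix has the wrong shape")
  }
  model <- structure(
    list(
      mu = as.numeric(obj$mu),
      W = matrix(as.numeric(W), ncol = obj$q),
      sigma2 = obj$sigma2,
      q = as.integer(obj$q),
      eigenvalues = as.numeric(obj$eigenvalues),
      n = obj$n, D = obj$D,
      scales = unlist(obj$scales),
      layout = layout
    ),
    class = "ppca_model"
  )
  model$loglik <- ppca_train_loglik(model)
  model
}
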