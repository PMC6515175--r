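# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn a model object into a tidy tibble
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return a tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return a one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn tidy per-epoch training history of a fitted model.
#' @export
tidy.gfm_fit <- function(x, ...) x$history

#' @describeIn glance final losses, train accuracy and parameter count.
#' @export
glance.gfm_fit <- function(x, ...) {
  h <- tail(x$history, 1L)
  tibble::tibble(
    epochs = x$config$epochs,
    nll = h$nll, ce = h$ce, total = h$total, train_acc = h$train_acc,
    n_classes = length(x$classes),
    n_parameters = length(params_to_vec(x$flow, x$clf))
  )
}

#' @describeIn tidy long-format cosine similarities between gesture centers.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    gesture_a = rep(as.integer(rownames(m)), times = ncol(m)),
    gesture_b = rep(as.integer(colnames(m)), each = nrow(m)),
    cosine = as.numeric(m)
  )
}

#' @describeIn tidy per-cell envelope strength of a latent sweep grid.
#' @export
tidy.sweep_grid <- function(x, ...) {
  tibble::tibble(row = x$row, col = x$col, v = x$v,
                 strength = vapply(x$window, envelope_strength, numeric(1)))
}

#' Plot training curves of a fitted model
#'
#' @param object a `gfm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gfm_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("nll", "ce", "train_acc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Joint flow + classifier training")
}

#' Plot a gesture-center correlation matrix
#'
#' @param object a `correlation_matrix`.
#' @param ... unused.
#' @return a ggplot heat map of pairwise cosines.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$gesture_b),
                                   y = factor(.data$gesture_a),
                                   fill = .data$cosine)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "gesture", y = "gesture", fill = "cosine",
                  title = "Gesture-center correlation matrix")
}

#' Plot the strength map of a latent sweep grid
#'
#' One tile per latent dimension (rows x columns of the retained latent),
#' colored by the generated envelope's strength.
#'
#' @param object a `sweep_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "latent column", y = "latent row", fill = "strength",
                  title = sprintf("Envelopes generated from one-hot latents (v = %g)",
                                  object$v[1L]))
}
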