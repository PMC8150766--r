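#' Tidy and glance methods for trained models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' model summary.
#'
#' @param x a `classical_branch`, `cnn_branch` or `fusion_model`.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.classical_branch <- function(x, ...) x$history

#' @rdname tidiers
#' @export
tidy.cnn_branch <- function(x, ...) x$history

#' @rdname tidiers
#' @export
tidy.fusion_model <- function(x, ...) x$history

model_glance <- function(x, branch) {
  tibble::tibble(branch = branch, epochs = nrow(x$history),
                 best_val_acc = x$val_acc,
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @rdname tidiers
#' @export
glance.classical_branch <- function(x, ...) model_glance(x, "classical")

#' @rdname tidiers
#' @export
glance.cnn_branch <- function(x, ...) model_glance(x, "cnn")

#' @rdname tidiers
#' @export
glance.fusion_model <- function(x, ...) model_glance(x, "fusion")

#' Plot a segment's trace
#'
#' @param object an `ieeg_segment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ieeg_segment <- function(object, ...) {
  df <- tibble::tibble(
    time = rep((seq_len(n_points(object)) - 1) / object$fs,
               times = nrow(object$samples)),
    channel = factor(rep(seq_len(nrow(object$samples)), each = n_points(object))),
    value = as.vector(t(object$samples)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("%s segment", object$label)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' @param history tibble from `tidy()` on a trained model.
#' @return A ggplot object with loss and validation-accuracy panels.
#' @export
plot_history <- function(history) {
  df <- tidyr::pivot_longer(history, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot attention weights over timesteps
#'
#' @param h_att matrix `N x T` of attention weights from
#'   [classical_predict()].
#' @return A ggplot boxplot of weight per timestep.
#' @export
plot_attention <- function(h_att) {
  df <- tibble::tibble(
    timestep = factor(rep(seq_len(ncol(h_att)) - 1, each = nrow(h_att))),
    weight = as.vector(h_att))
  ggplot2::ggplot(df, ggplot2::aes(.data$timestep, .data$weight)) +
    ggplot2::geom_boxplot() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "timestep", y = "attention weight")
}
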