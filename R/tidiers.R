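# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a training fit
#'
#' @param x An `rv_fit` from [train()].
#' @param ... Unused.
#' @return The per-epoch loss trace as a tibble (`epoch`, `loss`).
#' @method tidy rv_fit
#' @export
tidy.rv_fit <- function(x, ...) x$trace

#' @rdname tidy.rv_fit
#' @return For `glance()`: a one-row summary (objective, epochs, batch size,
#'   final/initial loss, parameter count, seed).
#' @method glance rv_fit
#' @export
glance.rv_fit <- function(x, ...) {
  tibble(objective = x$config$objective, epochs = x$config$epochs,
         batch_size = x$config$batch_size,
         initial_loss = x$trace$loss[1],
         final_loss = x$trace$loss[nrow(x$trace)],
         n_params = x$encoder$n_params, seed = x$seed)
}

#' Tidy an experiment
#'
#' @param x An `rv_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return Seed-level scores in long form.
#' @method tidy rv_experiment
#' @export
tidy.rv_experiment <- function(x, ...) {
  tidyr::pivot_longer(x$scores, c("color_score", "shape_score"),
                      names_to = "score", values_to = "value") |>
    mutate(score = sub("_score$", "", .data$score))
}

#' @rdname tidy.rv_experiment
#' @return For `glance()`: the canonical one-row-per-model summary table.
#' @method glance rv_experiment
#' @export
glance.rv_experiment <- function(x, ...) report(x)

#' Tidy an RDM into long pair form
#'
#' @param x An `rdm` matrix from [cosine_rdm()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, object labels (when attached) and
#'   `similarity`.
#' @method tidy rdm
#' @export
tidy.rdm <- function(x, ...) {
  n <- nrow(x)
  lab <- attr(x, "labels")
  out <- tibble(row = rep(seq_len(n), times = n),
                col = rep(seq_len(n), each = n),
                similarity = as.vector(unclass(x)[, , drop = TRUE]))
  if (!is.null(lab)) {
    out$row_object <- paste(lab$shape_id, lab$color_id, sep = "_")[out$row]
    out$col_object <- paste(lab$shape_id, lab$color_id, sep = "_")[out$col]
  }
  out
}

#' Heatmap of a representational similarity matrix
#'
#' @param object An `rdm` from [cosine_rdm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tidy.rdm(object)
  n <- nrow(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(n),
                             labels = unique(df$row_object) %||% seq_len(n)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = unique(df$col_object) %||% seq_len(n),
                                position = "top") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 0,
                                                       vjust = 0.5))
}

#' Colour/shape score bars for an experiment
#'
#' Mirrors the familiar two-bar summary: mean colour and shape score per
#' model phase with cell-wise standard errors.
#'
#' @param object An `rv_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rv_experiment
#' @export
autoplot.rv_experiment <- function(object, ...) {
  df <- tidy.rv_experiment(object) |>
    group_by(.data$phase, .data$score) |>
    summarise(mean = mean(.data$value),
              se = stats::sd(.data$value) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$mean,
                                   fill = .data$score)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = c(color = "#d95f02",
                                          shape = "#1b9e77")) +
    ggplot2::labs(x = NULL, y = "mean pairwise similarity", fill = NULL,
                  title = object$manifest$condition) +
    ggplot2::theme_minimal()
}

#' Scatter of 2-D stimulus projections
#'
#' @param projection Output of [project_2d()] carrying `shape_id` and
#'   `color_id` columns.
#' @return A ggplot: points coloured by colour label, shaped by shape label.
#' @export
plot_projection <- function(projection) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data$color_id,
                               shape = .data$shape_id)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}
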