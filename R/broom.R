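# Tidy accessors and plots for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a randomized-network model
#'
#' One row per (hidden node or direct link, class) pair of the solved
#' output-weight matrix, plus the SNN output bias as `term = "bias"`.
#'
#' @param x An `rnn_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `class`, `estimate`.
#' @export
tidy.rnn_model <- function(x, ...) {
  terms <- if (x$variant == "RVFL" && isTRUE(x$use_direct_links)) {
    c(paste0("input", seq_len(x$d)), paste0("hidden", seq_len(x$Z)))
  } else {
    paste0("hidden", seq_len(x$Z))
  }
  out <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(as.data.frame(x$P),
                            .name_repair = ~ x$class_names),
                  term = terms, .before = 1),
    -"term", names_to = "class", values_to = "estimate")
  if (!is.null(x$e)) {
    out <- dplyr::bind_rows(out, tibble(term = "bias",
                                        class = x$class_names,
                                        estimate = x$e))
  }
  out
}

#' @rdname tidy.rnn_model
#' @return `glance` gives a one-row summary: variant, dimensions, hidden
#'   nodes, classes, activation, and the training Frobenius residual.
#' @export
glance.rnn_model <- function(x, ...) {
  tibble(variant = x$variant, d = x$d, Z = x$Z, n_classes = x$n_classes,
         activation = x$activation, residual = x$residual, seed = x$seed)
}

#' Tidy / glance an ETRN ensemble
#'
#' @param x An `etrn_model`.
#' @param ... Unused.
#' @return `tidy`: the member `glance` rows stacked with a `member`
#'   column; `glance`: one row for the ensemble.
#' @export
tidy.etrn_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$elm), member = "elm", .before = 1),
    dplyr::mutate(glance(x$rvfl), member = "rvfl", .before = 1),
    dplyr::mutate(glance(x$snn), member = "snn", .before = 1))
}

#' @rdname tidy.etrn_model
#' @export
glance.etrn_model <- function(x, ...) {
  tibble(members = 3L, d = x$elm$d, Z = x$elm$Z,
         n_classes = x$n_classes,
         seeds = paste(x$seeds, collapse = ","))
}

#' Tidy a pipeline run
#'
#' @param x A `dlbcnet_run`.
#' @param ... Unused.
#' @return The per-class + macro metric tibble in long form
#'   (`class`, `metric`, `value`).
#' @export
tidy.dlbcnet_run <- function(x, ...) {
  tidyr::pivot_longer(x$report, -"class", names_to = "metric",
                      values_to = "value")
}

#' @rdname tidy.dlbcnet_run
#' @return `glance`: one row with the five macro averages and test size.
#' @export
glance.dlbcnet_run <- function(x, ...) {
  macro <- dplyr::filter(x$report, .data$class == "macro")
  dplyr::mutate(dplyr::select(macro, -"class"),
                n_test = nrow(x$features$test),
                mode = x$config$mode)
}

#' Plot per-class metrics of a run
#'
#' @param object A `dlbcnet_run`.
#' @param ... Unused.
#' @return A ggplot: metric value by class, faceted by metric.
#' @export
autoplot.dlbcnet_run <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot GAN training losses
#'
#' @param object A `gan_pair`.
#' @param ... Unused.
#' @return A ggplot of discriminator and generator loss per iteration.
#' @export
autoplot.gan_pair <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss_history, -"iteration",
                            names_to = "player", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                   color = .data$player)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param scores N x m score matrix (e.g. `predict(fit, x, type = "raw")`).
#' @param y_true Integer labels.
#' @param class_names Optional class names.
#' @return A ggplot of the per-class ROC curves with the chance diagonal.
#' @export
plot_roc <- function(scores, y_true, class_names = NULL) {
  pts <- roc_points_ovr(scores, y_true, class_names)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
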