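#' Tidy a fitted study into per-unit rows
#'
#' @param x a `causal_study`.
#' @param ... unused.
#' @return the per-test-unit predictions tibble.
#' @method tidy causal_study
#' @export
tidy.causal_study <- function(x, ...) x$predictions

#' One-row summary of a fitted study
#'
#' @param x a `causal_study`.
#' @param ... unused.
#' @return a one-row tibble combining the classification and (when ground
#'   truth is available) causal and interval metrics.
#' @method glance causal_study
#' @export
glance.causal_study <- function(x, ...) {
  out <- x$metrics$classification[, c("accuracy", "f1", "auc")]
  if (!is.null(x$metrics$causal)) {
    out <- dplyr::bind_cols(out, x$metrics$causal)
  }
  if (!is.null(x$metrics$interval)) {
    out <- dplyr::bind_cols(
      out, x$metrics$interval[, c("coverage", "calibration_error")])
  }
  dplyr::bind_cols(tibble::tibble(variant = x$config$variant,
                                  n_test = nrow(x$predictions)), out)
}

#' Tidy a DAG into an edge tibble
#'
#' @param x a `causal_dag`.
#' @param ... unused.
#' @return tibble with `from`, `to`, `weight`.
#' @method tidy causal_dag
#' @export
tidy.causal_dag <- function(x, ...) x$edges

#' Tidy an effect estimate into per-unit rows
#'
#' @param x an `effect_estimate`.
#' @param ... unused.
#' @return tibble with `pseudo_outcome` and `tau_smooth`.
#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::tibble(pseudo_outcome = x$pseudo, tau_smooth = x$tau_smooth)
}

#' @method glance effect_estimate
#' @export
glance.effect_estimate <- function(x, ...) {
  tibble::tibble(ate = x$ate,
                 contrast = paste(x$contrast, collapse = " vs "),
                 n = length(x$pseudo))
}

#' @method glance titan_model
#' @export
glance.titan_model <- function(x, ...) {
  lt <- x$loss_trace
  tibble::tibble(epochs_trained = nrow(lt),
                 final_train_bce = utils::tail(lt$train_bce, 1),
                 best_val_bce = min(lt$val_bce),
                 hidden = x$config$hidden, layers = x$config$layers)
}

#' Plot the distribution of estimated individual effects
#'
#' Histogram of the blended per-unit effects with the estimated ATE marked;
#' the conventional first look at effect heterogeneity.
#'
#' @param object a `causal_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot causal_study
#' @export
autoplot.causal_study <- function(object, ...) {
  pr <- object$predictions
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$ite)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(pr$ite), linetype = 2) +
    ggplot2::labs(x = "estimated individual effect (probability scale)",
                  y = "units",
                  title = "Distribution of estimated individual effects",
                  subtitle = paste0("estimated ATE = ",
                                    signif(mean(pr$ite), 3))) +
    ggplot2::theme_minimal()
}

#' Plot the training loss trace of the attention branch
#'
#' @param object a `titan_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot titan_model
#' @export
autoplot.titan_model <- function(object, ...) {
  lt <- tidyr::pivot_longer(object$loss_trace, -"epoch",
                            names_to = "split", values_to = "bce")
  ggplot2::ggplot(lt, ggplot2::aes(x = .data$epoch, y = .data$bce,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot a causal DAG
#'
#' @param object a `causal_dag`.
#' @param ... unused.
#' @return a ggplot object (nodes on a circle, directed edges as arrows).
#' @method autoplot causal_dag
#' @export
autoplot.causal_dag <- function(object, ...) {
  nodes <- object$nodes
  th <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes, x = cos(th), y = sin(th))
  ed <- dplyr::left_join(object$edges, pos, by = c(from = "node"))
  ed <- dplyr::left_join(ed, pos, by = c(to = "node"),
                         suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_end, yend = .data$y_end),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      colour = "grey40") +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Causal DAG (", object$provenance, ")"))
}
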