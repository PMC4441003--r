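# broom-style accessors and ggplot2 visualizations for result objects.

#' Per-term metrics of an evaluation
#'
#' @param x A `litgo_eval` from [fmax_eval()].
#' @param ... Unused.
#' @return Tibble of per-term `tp`, `fp`, `fn`, `precision`, `recall`, `f`
#'   at the F-max threshold.
#' @method tidy litgo_eval
#' @export
tidy.litgo_eval <- function(x, ...) {
  as_tibble(x$per_term)
}

#' One-row summary of an evaluation
#'
#' @param x A `litgo_eval` from [fmax_eval()].
#' @param ... Unused.
#' @return One-row tibble: `fmax`, `precision`, `recall`, `threshold`,
#'   `macro_auc`, `n_proteins`, `n_terms`.
#' @method glance litgo_eval
#' @export
glance.litgo_eval <- function(x, ...) {
  tibble(fmax = x$fmax, precision = x$precision, recall = x$recall,
         threshold = x$threshold, macro_auc = x$macro_auc,
         n_proteins = x$n_proteins, n_terms = nrow(x$per_term))
}

#' Precision-recall sweep plot for an evaluation
#'
#' Draws the micro precision/recall curve across the threshold sweep with
#' the F-max operating point highlighted.
#'
#' @param object A `litgo_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot litgo_eval
#' @export
autoplot.litgo_eval <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path(color = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::annotate("point", x = object$recall, y = object$precision,
                      color = "red", size = 3, shape = 18) +
    ggplot2::annotate("text", x = object$recall, y = object$precision,
                      label = sprintf("F-max = %.3f", object$fmax),
                      vjust = -1, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall (micro)", y = "Precision (micro)",
                  title = "Threshold sweep",
                  subtitle = paste0("macro-AUC = ",
                                    signif(object$macro_auc, 3))) +
    ggplot2::theme_minimal()
}

#' Bar plot of a depth/IC-binned report
#'
#' @param object A `litgo_binned` from [binned_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot litgo_binned
#' @export
autoplot.litgo_binned <- function(object, ...) {
  axis_lab <- if (object$axis[1] == "depth") "Term depth"
              else "Information content bin"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$bin_label,
                                          levels = .data$bin_label),
                               y = .data$mean_f)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_terms), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = axis_lab, y = "Macro-averaged F-measure") +
    ggplot2::ylim(0, 1.05) +
    ggplot2::theme_minimal()
}
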