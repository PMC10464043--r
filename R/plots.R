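#' Plot a ROC curve
#'
#' @param object An `edi_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object: sensitivity against 1 - specificity with the
#'   chance diagonal.
#' @examples
#' autoplot(roc_points(simulate_edi_cohort(seed = 3)))
#' @export
autoplot.edi_roc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC curve of the Expiratory Disproportion Index") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.edi_roc
#' @export
plot_roc <- function(object, ...) {
  if (!inherits(object, "edi_roc")) object <- roc_points(object)
  autoplot.edi_roc(object, ...)
}

#' Violin plot of EDI values by condition group
#'
#' The standard display of the two groups' EDI distributions, with the
#' screening cutoff drawn as a horizontal reference line.
#'
#' @param data A data frame with columns `group` and `edi`.
#' @param cutoff Reference cutoff to draw (default 48); `NULL` omits it.
#' @return A ggplot object.
#' @examples
#' plot_edi_violin(compute_edi(make_table2_fixture()))
#' @export
plot_edi_violin <- function(data, cutoff = 48) {
  data <- check_labeled_edi(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$edi,
                                          fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.9,
                         show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "EDI (100 x FEV1 / PEFR)",
                  title = "Expiratory Disproportion Index by condition") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @export
autoplot.edi_accuracy <- function(object, ...) {
  if (is.null(object$roc)) {
    abort_validation("this report carries no ROC table (read from JSON?); plot from the ROC CSV instead.")
  }
  autoplot.edi_roc(object$roc) +
    ggplot2::annotate(
      "text", x = 0.7, y = 0.15,
      label = sprintf("AUC = %.2f (%.0f%% CI %.2f-%.2f)",
                      object$auc$auc, 100 * object$auc$level,
                      object$auc$lower, object$auc$upper)
    )
}

#' Plot a flow-volume curve
#'
#' @param object An `fv_curve`.
#' @param ... Unused.
#' @return A ggplot object of instantaneous flow against expired volume.
#' @export
autoplot.fv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$volume, y = .data$flow)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Expired volume (L)", y = "Flow (L/s)",
                  title = "Expiratory flow-volume curve") +
    ggplot2::theme_minimal()
}
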