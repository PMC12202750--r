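# ggplot2 autoplot methods for the result containers

#' Plot a training-loss history
#'
#' @param object A `kd_fit` or `kd_distilled`.
#' @param ... Unused.
#' @return A ggplot: loss components against epoch.
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "component",
                              values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss",
                  title = paste0("Training history (", object$role,
                                 if (object$model$spec$variant != "none")
                                   paste0(", ", object$model$spec$variant) else "",
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `kd_cv`.
#' @param ... Unused.
#' @return A ggplot: one point per fold and metric, with the fold mean.
#' @method autoplot kd_cv
#' @export
autoplot.kd_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds[c("fold", "sen", "spe", "acc", "mcc")],
                              -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste0(object$k, "-fold cross-validation (",
                                 object$variant, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a positional residue-enrichment table
#'
#' Logo-style: per offset, significantly enriched residues above the axis and
#' depleted residues below, letter size proportional to the frequency
#' difference.
#'
#' @param object A `kd_enrichment` from [residue_enrichment()].
#' @param threshold Significance threshold on the per-cell p-value
#'   (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kd_enrichment
#' @export
autoplot.kd_enrichment <- function(object, threshold = 0.05, ...) {
  sig <- object[object$p_value < threshold & object$diff != 0, , drop = FALSE]
  sig <- dplyr::arrange(sig, .data$offset, dplyr::desc(abs(.data$diff)))
  sig <- dplyr::mutate(
    dplyr::group_by(sig, .data$offset, .data$diff > 0),
    y = cumsum(.data$diff) - .data$diff / 2)
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$offset, y = .data$y,
                                    label = .data$residue,
                                    size = abs(.data$diff),
                                    colour = .data$diff > 0)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue")) +
    ggplot2::labs(x = "window offset from central K",
                  y = "cumulative frequency difference (pos - neg)") +
    ggplot2::theme_minimal()
}

#' Plot a t-SNE projection
#'
#' @param object A `kd_tsne` from [tsne_project()].
#' @param ... Unused.
#' @return A ggplot scatter, coloured by label when present.
#' @method autoplot kd_tsne
#' @export
autoplot.kd_tsne <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tsne1, y = .data$tsne2))
  if ("label" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$label)),
                                 alpha = 0.6, size = 1) +
      ggplot2::labs(colour = "class")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 1)
  }
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") + ggplot2::theme_minimal()
}
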