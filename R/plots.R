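# ggplot2 views of the result tables.

#' Volcano plot of a differential table
#'
#' log2(BafA1:vehicle) fold change on x against -log10 p on y; candidates
#' (p < alpha and fold change > 0) are highlighted.
#'
#' @param object An `lfq_differential`.
#' @param label_candidates Add text labels for candidate proteins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lfq_differential
#' @export
autoplot.lfq_differential <- function(object, label_candidates = FALSE, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                    colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = expression(log[2] * "(BafA1:vehicle)"),
                  y = expression(-log[10] * "(p)")) +
    ggplot2::theme_minimal()
  if (label_candidates && any(object$candidate)) {
    p <- p + ggplot2::geom_text(
      data = object[object$candidate, ],
      ggplot2::aes(label = .data$protein_id),
      vjust = -0.6, size = 2.5, colour = "red3"
    )
  }
  p
}

#' Heat map of replicate reproducibility
#'
#' Tiles of pairwise Pearson correlations per experiment and condition.
#'
#' @param object An `lfq_replicate_cor` from [replicate_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lfq_replicate_cor
#' @export
autoplot.lfq_replicate_cor <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_1, y = .data$sample_2,
                               fill = .data$pearson_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pearson_r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue", na.value = "grey85") +
    ggplot2::facet_wrap(~ .data$experiment + .data$condition,
                        scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Meta-analysis evidence plot
#'
#' Combined z-score against -log10 q; proteins passing the FDR threshold are
#' highlighted.
#'
#' @param object An `lfq_meta`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lfq_meta
#' @export
autoplot.lfq_meta <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$z_meta,
                               y = -log10(.data$q_value),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = expression(z[meta]), y = expression(-log[10] * "(q)")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data %||%
NULL
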