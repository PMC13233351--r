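# ggplot2 helpers for the main result types.

#' ROC curves for one or more score sets
#'
#' @param truth Label table (`sample_id`, `label`) or vector.
#' @param scores A [predict_proba()] tibble, or a named list of them (one
#'   curve per element).
#' @return A ggplot object.
#' @export
plot_roc <- function(truth, scores) {
  if (is.data.frame(scores)) scores <- list(model = scores)
  if (is.data.frame(truth)) {
    truth <- setNames(as.character(truth$label), truth$sample_id)
  }
  pts <- purrr::imap_dfr(scores, function(s, nm) {
    p <- setNames(s$probability, s$sample_id)
    dplyr::mutate(roc_points(truth[names(p)], p), model = nm)
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Genome-wide Z-score profile of one sample
#'
#' @param object A `cnv_features` result.
#' @param sample_id Which sample to draw.
#' @param ... Unused.
#' @return A ggplot object: per-window Z along the genome with the |Z| = 3
#'   reference band.
#' @method autoplot cnv_features
#' @export
autoplot.cnv_features <- function(object, sample_id, ...) {
  z <- feature_matrix(object$z)
  if (!sample_id %in% rownames(z)) {
    abort_invalid(sprintf("unknown sample '%s'", sample_id))
  }
  df <- parse_bin_ids(colnames(z))
  df$z <- z[sample_id, ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$z)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "1-Mb window", y = "Z score", title = sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Youden-index comparison across methods, feature types and strategies
#'
#' @param comparison The metrics tibble from [compare_experiments()] or
#'   [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(.data$feature, .data$youden,
                               fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = "Feature set", y = "Youden index", fill = NULL) +
    ggplot2::theme_minimal()
}
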