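#' Plot a composite profile
#'
#' Mean signal per bin with the bootstrap percentile band as a ribbon.
#'
#' @param object A [composite_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composite_profile <- function(object, ...) {
  df <- object$profile %>%
    mutate(pos = .data$bin_start + object$bin_size / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey75", alpha = 0.7) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = sprintf("mean signal / %d-bp bin", object$bin_size),
                  subtitle = sprintf("%d anchors, %g-%g%% bootstrap band",
                                     object$n_anchors, object$conf[1],
                                     object$conf[2])) +
    ggplot2::theme_minimal()
}

#' Plot a heatmap matrix
#'
#' @param x A [heatmap_matrix()].
#' @param trans Value transform for the fill scale (default `log1p`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_heatmap <- function(x, trans = log1p, ...) {
  m <- x$matrix %||% x$matrix_sense
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    pos = rep(as.numeric(colnames(m)), each = nrow(m)),
    value = trans(as.vector(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = sprintf("elements (sorted by %s)",
                              x$sort_key %||% "input order")) +
    ggplot2::theme_minimal()
}

#' ROC curve of the TRE classifier (cross-validated scores)
#'
#' @param object A [train_tre_classifier()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tre_classifier <- function(object, ...) {
  r <- pROC::roc(object$cv_scores$label, object$cv_scores$score,
                 levels = c("dTRE", "promoter"), direction = "<",
                 quiet = TRUE)
  df <- tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("combined AUC %.3f", object$auc_combined)) +
    ggplot2::theme_minimal()
}

#' Sensitivity-FDR trade-off of the peak-caller grid
#'
#' @param object An [optimize_hd_params()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_tuning <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$fdr, .data$sensitivity,
                               color = factor(signif(.data$lambda, 2)))) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_point(data = object$params %>%
                          mutate(fdr = object$fdr,
                                 sensitivity = object$sensitivity),
                        shape = 1, size = 4, color = "black") +
    ggplot2::labs(x = "FDR", y = "sensitivity", color = "lambda") +
    ggplot2::theme_minimal()
}
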