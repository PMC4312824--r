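#' @exportS3Method ggplot2::autoplot
autoplot.pca_qc <- function(object, colour = c("diagnosis", "batch"), ...) {
  colour <- match.arg(colour)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = factor(.data[[colour]]))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = colour, title = "PCA of samples",
                  subtitle = sprintf("QC dispersion %.3f; %d outlier(s)",
                                     object$qc_dispersion,
                                     length(object$outliers))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rfe_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$size, .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                                      ymax = .data$mean_auc + .data$sd_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "subset size", y = "mean bootstrap-test AUC",
                  title = "Recursive feature elimination profile") +
    ggplot2::theme_minimal()
}

#' Boxplot-style data view of group trends
#'
#' Long-format plot of selected feature levels across the three diagnostic
#' groups, the data behind the classic per-metabolite group boxplots.
#'
#' @param x imputed-scale [feature_matrix()].
#' @param meta sample metadata.
#' @param features feature ids to show.
#' @return a ggplot.
#' @export
plot_group_trends <- function(x, meta, features) {
  meta <- .align_meta(meta, x)
  clin <- meta$diagnosis %in% c("CTL", "MCI", "AD")
  d <- as_tibble(unclass(x)[clin, features, drop = FALSE])
  d$diagnosis <- factor(meta$diagnosis[clin], levels = c("CTL", "MCI", "AD"))
  d <- tidyr::pivot_longer(d, -"diagnosis", names_to = "feature",
                           values_to = "log2_intensity")
  ggplot2::ggplot(d, ggplot2::aes(.data$diagnosis, .data$log2_intensity)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ feature, scales = "free_y") +
    ggplot2::theme_minimal()
}
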