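#' Plot duplicate agreement against abundance
#'
#' Scatter of the absolute duplicate Ct difference against the duplicate
#' mean, with the smoothing-spline trend and the stratum boundaries — the
#' diagnostic motivating the high/medium/low cutoffs.
#'
#' @param points Output of [duplicate_agreement()].
#' @param fit Optional [fit_agreement_spline()] result; fitted on the fly
#'   when `NULL` and enough points are available.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @return A ggplot object.
#' @export
plot_duplicate_agreement <- function(points, fit = NULL,
                                     cutoffs = stratum_cutoffs()) {
  if (is.null(fit) && nrow(points) >= 10 &&
      diff(range(points$mean_ct)) > 2) {
    fit <- fit_agreement_spline(points)
  }
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = mean_ct, y = abs_diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(cutoffs$high_below, cutoffs$low_above),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "Mean Ct of duplicates",
                  y = "|Ct difference| between duplicates") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble(mean_ct = seq(fit$range[1], fit$range[2], length.out = 200))
    grid$abs_diff <- predict(fit, grid$mean_ct)
    p <- p + ggplot2::geom_line(data = grid, colour = "red", linewidth = 0.8)
  }
  p
}

#' Plot stratum occupancy per group
#'
#' @param counts Output of [stratum_counts()].
#' @return A ggplot object (grouped bar chart).
#' @export
plot_stratum_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stratum, y = n, fill = group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Abundance stratum", y = "Number of miRs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot well-failure rates across a series
#'
#' @param failures A tibble with a `percent_failures` column and one
#'   predictor column named in `x` (e.g. `input_rna_conc`).
#' @param x Name of the predictor column.
#' @return A ggplot object.
#' @export
plot_failure_rates <- function(failures, x = "input_rna_conc") {
  ggplot2::ggplot(failures,
                  ggplot2::aes(x = .data[[x]], y = percent_failures)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "% well failures") +
    ggplot2::theme_minimal()
}

#' @rdname ct_pca
#' @param colour_by Optional named vector mapping `condition_id` to a label
#'   used to colour the score plot (e.g. disease state).
#' @method autoplot ct_pca
#' @export
autoplot.ct_pca <- function(object, colour_by = NULL, ...) {
  scores <- object$scores
  if (!is.null(colour_by)) {
    scores$label <- unname(colour_by[scores$condition_id])
  }
  mapping <- if (is.null(colour_by)) {
    ggplot2::aes(x = PC1, y = PC2)
  } else {
    ggplot2::aes(x = PC1, y = PC2, colour = label)
  }
  ggplot2::ggplot(scores, mapping) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
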