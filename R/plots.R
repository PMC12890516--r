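#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_vline
#'   labs autoplot theme_minimal stat_function
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted relaxed decay
#'
#' Observed normalized fluorescence with the fitted double-exponential curve
#' overlaid.
#'
#' @param object A `relax_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.relax_fit <- function(object, ...) {
  df <- object$data
  grid <- seq(min(df$time_s), max(df$time_s), length.out = 200)
  curve <- tibble(
    time_s = grid,
    intensity = decay_model(grid, object$P1, object$T1, object$P2, object$T2)
  )
  ggplot(df, aes(x = .data$time_s, y = .data$intensity)) +
    geom_point(size = 1.4, alpha = 0.8) +
    geom_line(data = curve, colour = "#2166ac") +
    labs(x = "time after chase (s)", y = "normalized fluorescence",
         title = sprintf("P1 = %.1f%% (T1 = %.0f s), P2 = %.1f%% (T2 = %.0f s)",
                         object$P1, object$T1, object$P2, object$T2)) +
    theme_minimal()
}

#' Volcano plot of a differential-abundance result
#'
#' @param diff A result from [differential_abundance()].
#' @param ... Unused.
#' @return A ggplot of -log10 p against log2 fold change, significant
#'   proteins highlighted and the gate thresholds drawn.
#' @export
plot_volcano <- function(diff, ...) {
  check_columns(diff, c("log2_fc", "p", "significant"), "diff result")
  alpha <- attr(diff, "alpha") %||% 0.05
  fc <- attr(diff, "fc") %||% 2
  ggplot(diff, aes(x = .data$log2_fc, y = -log10(.data$p),
                   colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 1.2) +
    geom_vline(xintercept = c(-1, 1) * log2(fc), linetype = "dashed") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b")) +
    labs(x = "log2 fold change", y = "-log10 p", colour = "significant") +
    theme_minimal()
}

#' Plot PCA sample scores
#'
#' @param object A `pca_scores` result from [pca_scores()].
#' @param ... Unused.
#' @return A ggplot of the first two components, coloured by group when
#'   available, with explained-variance fractions in the axis labels.
#' @export
autoplot.pca_scores <- function(object, ...) {
  ve <- attr(object, "var_explained")
  p <- if ("group" %in% names(object)) {
    ggplot(object, aes(x = .data$PC1, y = .data$PC2, colour = .data$group))
  } else {
    ggplot(object, aes(x = .data$PC1, y = .data$PC2))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    theme_minimal()
}
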