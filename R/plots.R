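# ggplot2 visualisations for the pipeline's result objects.

#' Volcano plot of a differential methylation fit
#'
#' Group effect (beta-value units, mutation-negative minus
#' mutation-positive) against -log10 of the corrected (or raw) p-value,
#' coloured by FDR significance when q-values are present.
#'
#' @param object A `dmp_fit`.
#' @param fdr_threshold Significance threshold for colouring (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmp_fit
#' @export
autoplot.dmp_fit <- function(object, fdr_threshold = 0.05, ...) {
  tab <- object$table
  pcol <- if ("p_corrected" %in% names(tab)) "p_corrected" else "p_raw"
  tab$neglogp <- -log10(pmax(tab[[pcol]], 1e-300))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta_hat, y = .data$neglogp))
  if ("q_value" %in% names(tab)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$q_value < fdr_threshold), alpha = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
        name = sprintf("q < %.2g", fdr_threshold))
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, colour = "grey40")
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey70") +
    ggplot2::labs(
      x = "group effect (beta, negative - positive)",
      y = sprintf("-log10 %s", pcol)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of z-scores with the fitted empirical null
#'
#' @param object An `inflation_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot inflation_fit
#' @export
autoplot.inflation_fit <- function(object, bins = 80, ...) {
  df <- tibble(z = object$z)
  grid <- tibble(z = seq(min(df$z), max(df$z), length.out = 400))
  grid$null <- object$pi0 * stats::dnorm(grid$z, object$mu0, object$sigma0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$null),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::labs(
      x = "z-score",
      y = "density",
      title = sprintf("empirical null N(%.3f, %.3f^2), lambda = %.4f",
                      object$mu0, object$sigma0, object$lambda_gc)
    ) +
    ggplot2::theme_minimal()
}

#' Relative feature importance bar chart for a classifier report
#'
#' @param object An `ml_report`.
#' @param top_n Number of top probes to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ml_report
#' @export
autoplot.ml_report <- function(object, top_n = 20, ...) {
  imp <- head(object$importance, top_n)
  if (nrow(imp) == 0L) abort("no scored features to plot")
  imp$probe_id <- factor(imp$probe_id, levels = rev(imp$probe_id))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$relative_importance,
                                    y = .data$probe_id,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(hyper = "firebrick", hypo = "steelblue"),
      na.value = "grey60") +
    ggplot2::labs(
      x = "relative feature importance (top = 100)", y = NULL,
      title = sprintf("test AUC %.2f +/- %.2f", object$auc_mean, object$auc_sd)
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of a methylation PCA
#'
#' @param object A `methyl_pca` from [pca_summary()].
#' @param k Components to display (default 8).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot methyl_pca
#' @export
autoplot.methyl_pca <- function(object, k = 8, ...) {
  df <- head(object$explained, k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::scale_x_continuous(breaks = df$component) +
    ggplot2::labs(x = "principal component", y = "explained variance fraction") +
    ggplot2::theme_minimal()
}
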