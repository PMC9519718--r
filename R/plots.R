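#' Plot rotated factor loadings
#'
#' @param object A `met_rotation`.
#' @param ... Unused.
#' @return A ggplot: environments against loadings, one panel per factor.
#' @export
autoplot.met_rotation <- function(object, ...) {
  df <- tidy(object)
  df$env <- factor(df$env, levels = object$envs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$env)) +
    ggplot2::geom_col(orientation = "y", fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~factor, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "loading", y = NULL)
}

#' Heatmap of between-environment genetic correlations
#'
#' @param object A `met_corr` from [env_correlation()].
#' @param ... Unused.
#' @return A ggplot heatmap in the clustering order.
#' @export
autoplot.met_corr <- function(object, ...) {
  ord <- object$envs[object$order]
  R <- object$correlation[object$order, object$order, drop = FALSE]
  df <- tibble::tibble(row = rep(ord, times = length(ord)),
                       col = rep(ord, each = length(ord)),
                       r = as.numeric(R))
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$row, .data$col, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "r",
                  title = paste0("Additive genetic correlations (",
                                 object$parts, " covariates)")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot cross-validation accuracies
#'
#' @param object A `met_cv`.
#' @param ... Unused.
#' @return A ggplot of per-environment prediction accuracy.
#' @export
autoplot.met_cv <- function(object, ...) {
  df <- object$accuracy
  df$env <- factor(df$env, levels = df$env)
  ggplot2::ggplot(df, ggplot2::aes(.data$env, .data$accuracy)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "prediction accuracy r",
                  title = paste0(object$mode, "-environment prediction")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Genotype regression plots
#'
#' Latent-regression plots of adjusted GE effects against composite factor
#' loadings, with the fitted through-origin line for each genotype and the
#' main-effect marker where the family defines one.
#'
#' @param x A `met_fit` or `met_rotation` of a factor family.
#' @param genotypes Genotype ids to display (default first two).
#' @param factors Factors to display (default all).
#' @return A ggplot.
#' @export
plot_regression <- function(x, genotypes = NULL, factors = NULL) {
  df <- regression_plot_data(x, genotypes)
  markers <- attr(df, "markers")
  if (!is.null(factors)) {
    df <- df[df$factor %in% factors, ]
    if (!is.null(markers)) markers <- markers[markers$factor %in% factors, ]
  }
  gp <- ggplot2::ggplot(df, ggplot2::aes(.data$loading, .data$effect,
                                         colour = .data$genotype)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(~factor, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "environment loading", y = "adjusted GE effect")
  if (!is.null(markers) && nrow(markers)) {
    gp <- gp + ggplot2::geom_point(data = markers,
                                   ggplot2::aes(.data$loading, .data$effect,
                                                colour = .data$genotype),
                                   shape = 16, size = 3)
  }
  gp
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
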