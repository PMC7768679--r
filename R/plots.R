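# ggplot2 views of the result objects.

#' Original-versus-reconstructed loading scatter
#'
#' The pooled (sample, component) loading cloud; a perfect reconstruction
#' lies on the unity line.
#'
#' @param model a [fit_pca()] model.
#' @param recon a [reconstruct_modality()] result from the same model.
#' @return a ggplot object.
#' @export
plot_loading_scatter <- function(model, recon) {
  df <- tibble::tibble(original = as.vector(model$loadings),
                       reconstructed = as.vector(recon$recon_loadings))
  ggplot2::ggplot(df, ggplot2::aes(.data$original, .data$reconstructed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "original loading", y = "reconstructed loading",
                  title = sprintf("%s reconstruction, R = %.3f",
                                  recon$zeroed_modality,
                                  loading_correlation(model$loadings,
                                                      recon$recon_loadings))) +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' Histogram of shuffled loading correlations with the observed value marked.
#'
#' @param x a [permutation_test()] result.
#' @return a ggplot object.
#' @export
plot_null_distribution <- function(x) {
  stopifnot(inherits(x, "facetract_permtest"))
  df <- tibble::tibble(null_r = x$null_r)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = x$observed$r, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "shuffled loading correlation", y = "count",
                  title = sprintf("observed R = %.3f, p = %.3g (%d permutations)",
                                  x$observed$r, x$p_value_correlation,
                                  x$n_perm)) +
    ggplot2::theme_minimal()
}

#' Heat map of a proportion plane
#'
#' @param x a [proportion_plane()] (whole-sequence scope) or a
#'   [bubbles_analysis()] result.
#' @return a ggplot object.
#' @export
plot_proportion_plane <- function(x) {
  if (inherits(x, "facetract_bubbles")) x <- x$plane
  stopifnot(inherits(x, "proportion_plane"))
  df <- tidy.proportion_plane(x)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$proportion)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "proportion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
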