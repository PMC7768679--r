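# Tidy summaries of the result objects, for use with the tidyverse.

#' Tidy a fitted PCA: one row per (sample, component) loading
#'
#' @param x a [fit_pca()] model.
#' @param ... unused.
#' @return tibble with `sample`, `component`, `loading`.
#' @export
tidy.facetract_pca <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    sample = rep(seq_len(nrow(l)), times = ncol(l)),
    component = rep(seq_len(ncol(l)), each = nrow(l)),
    loading = as.vector(l))
}

#' @rdname tidy.facetract_pca
#' @export
glance.facetract_pca <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples,
                 n_components = length(x$sdev),
                 centered = x$centered,
                 total_second_moment = sum(x$sdev^2))
}

#' Tidy a permutation test: one row per permutation
#'
#' @param x a [permutation_test()] result.
#' @param ... unused.
#' @return tibble with `permutation`, `null_r`, `null_sse`.
#' @export
tidy.facetract_permtest <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm),
                 null_r = x$null_r, null_sse = x$null_sse)
}

#' @rdname tidy.facetract_permtest
#' @export
glance.facetract_permtest <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_perm = x$n_perm,
                 observed_r = x$observed$r, observed_sse = x$observed$sse,
                 null_mean = x$null_mean,
                 null_ci_lower = x$null_ci95[1], null_ci_upper = x$null_ci95[2],
                 p_value_correlation = x$p_value_correlation,
                 p_value_sse = x$p_value_sse)
}

#' Tidy a proportion plane: one row per defined pixel
#'
#' @param x a [proportion_plane()] (whole-sequence scope).
#' @param ... unused.
#' @return tibble with `row`, `col`, `proportion`, `correct`, `total`.
#' @export
tidy.proportion_plane <- function(x, ...) {
  if (x$scope != "sequence")
    stop("tidy() supports the whole-sequence plane", call. = FALSE)
  ok <- which(!is.na(x$plane), arr.ind = TRUE)
  tibble::tibble(row = ok[, 1L], col = ok[, 2L],
                 proportion = x$plane[ok],
                 correct = x$correct_plane[ok],
                 total = x$total_plane[ok])
}

# Re-export the generics so tidy()/glance() work without attaching broom.
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
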