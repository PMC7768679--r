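# Uncentered PCA over hybrid samples and cross-modal reconstruction.
#
# The decomposition is uncentered by default (a second-moment decomposition):
# with plain inner-product projection this makes the reconstructed loadings
# exactly additive across modality blocks — zeroing the video block and the
# MR block and projecting each gives loadings that sum, elementwise, to the
# loadings of the full column. A centered mode is provided but breaks that
# identity and is flagged as such in the documentation.

#' Fit a PCA over hybrid samples
#'
#' Computed via the economical route (eigen-decomposition of the sample Gram
#' matrix), appropriate when observations vastly outnumber samples. All
#' components with non-negligible variance are retained. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making reports reproducible across linear-algebra backends.
#'
#' @param h a `hybrid_array`/`paired_hybrid_array` or plain observation-by-
#'   sample matrix with >= 2 columns.
#' @param centered subtract the mean observation vector first? Default
#'   `FALSE`; centering breaks the exact modality-additivity of reconstructed
#'   loadings.
#' @param tol relative eigenvalue cutoff for discarding null components.
#' @return object of class `facetract_pca`: `components` (p x k, orthonormal),
#'   `loadings` (n x k), `sdev` (singular values), `centered`, `mean_vector`
#'   (if centered), `block_map` (if fit on a hybrid).
#' @export
fit_pca <- function(h, centered = FALSE, tol = 1e-10) {
  x <- if (is.matrix(h)) h else h$data
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- NULL
  if (centered) {
    mu <- rowMeans(x)
    x <- x - mu
  }
  g <- crossprod(x)
  eg <- eigen(g, symmetric = TRUE)
  lam <- eg$values
  keep <- which(lam > max(lam, 0) * tol & lam > 0)
  if (length(keep) == 0L) stop("data matrix has no non-null component", call. = FALSE)
  d <- sqrt(lam[keep])
  w <- eg$vectors[, keep, drop = FALSE]
  loadings <- w %*% diag(d, nrow = length(d))            # n x k
  comps <- x %*% w %*% diag(1 / d, nrow = length(d))     # p x k
  for (k in seq_along(d)) {                              # sign convention
    jmax <- which.max(abs(loadings[, k]))
    if (loadings[jmax, k] < 0) {
      loadings[, k] <- -loadings[, k]
      comps[, k] <- -comps[, k]
    }
  }
  structure(list(components = comps, loadings = loadings, sdev = d,
                 centered = centered, mean_vector = mu,
                 block_map = if (is.matrix(h)) NULL else h$block_map,
                 paired = inherits(h, "paired_hybrid_array"),
                 base_nrow = if (inherits(h, "paired_hybrid_array")) h$base_nrow else NULL,
                 n_samples = ncol(x), tol = tol),
            class = "facetract_pca")
}

#' @export
print.facetract_pca <- function(x, ...) {
  cat(sprintf("<facetract_pca: %d observations, %d samples, %d components%s>\n",
              nrow(x$components), x$n_samples, length(x$sdev),
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Project observation-space columns onto the components
#'
#' Plain inner products against each component; no mean subtraction in the
#' uncentered default (the mean is subtracted first in centered mode).
#'
#' @param model a [fit_pca()] model.
#' @param columns observation-space vector or p x m matrix.
#' @return m x k loading matrix.
#' @export
project <- function(model, columns) {
  stopifnot(inherits(model, "facetract_pca"))
  if (is.vector(columns)) columns <- matrix(columns, ncol = 1L)
  if (nrow(columns) != nrow(model$components))
    stop("column length does not match the observation dimension", call. = FALSE)
  if (model$centered) columns <- columns - model$mean_vector
  crossprod(columns, model$components)
}

#' Reconstruct one modality from the other
#'
#' Zeroes the named modality's blocks, projects the partial columns into the
#' PCA space, and forms reconstructed observation vectors from the resulting
#' loadings; both modalities' blocks of the reconstruction are deserialized
#' back into images and warp fields. Optionally the reconstructed loadings
#' are augmented by the mean original/reconstructed loading ratio before
#' vector formation (off by default).
#'
#' @param model a [fit_pca()] model fit on `h`.
#' @param h the hybrid the model was fit on.
#' @param zeroed modality to remove before projection (`"video"` or `"mr"`):
#'   the reconstruction is driven by the *other* modality.
#' @param apply_mean_scaling multiply reconstructed loadings by the mean
#'   original/reconstructed ratio across all samples and components.
#' @return object of class `facetract_recon`: `recon_loadings` (n x k),
#'   `recon_vectors` (p x n, in the span of the components), `modalities`
#'   (deserialized images + fields per modality), `zeroed_modality`,
#'   `scaling_factor` (1 unless `apply_mean_scaling`).
#' @export
reconstruct_modality <- function(model, h, zeroed, apply_mean_scaling = FALSE) {
  stopifnot(inherits(model, "facetract_pca"))
  bmap <- h$block_map
  if (is.null(bmap[[zeroed]]))
    stop("unknown modality: ", zeroed, call. = FALSE)
  partial <- h$data
  partial[block_rows(h, zeroed), ] <- 0
  recon_loadings <- project(model, partial)
  sf <- 1
  if (apply_mean_scaling) {
    ok <- abs(recon_loadings) > 1e-12
    sf <- mean(model$loadings[ok] / recon_loadings[ok])
    recon_loadings <- recon_loadings * sf
  }
  recon_vectors <- model$components %*% t(recon_loadings)
  if (model$centered) recon_vectors <- recon_vectors + model$mean_vector
  cols <- if (inherits(h, "paired_hybrid_array"))
    recon_vectors[seq_len(h$base_nrow), , drop = FALSE] else recon_vectors
  structure(list(recon_loadings = recon_loadings,
                 recon_vectors = recon_vectors,
                 modalities = deserialize_hybrid(cols, bmap),
                 zeroed_modality = zeroed,
                 scaling_factor = sf),
            class = "facetract_recon")
}

#' @export
print.facetract_recon <- function(x, ...) {
  cat(sprintf("<facetract_recon: %s zeroed, %d samples x %d components>\n",
              x$zeroed_modality, nrow(x$recon_loadings), ncol(x$recon_loadings)))
  invisible(x)
}

#' Loading correlation between original and reconstructed loadings
#'
#' Pearson correlation over all (sample, component) pairs pooled together —
#' the package's primary reconstruction-fidelity metric. Invariant to a
#' common positive rescaling of either loading set.
#'
#' @param orig,recon loading matrices of identical shape (>= 3 values).
#' @return scalar correlation in \[-1, 1\].
#' @export
loading_correlation <- function(orig, recon) {
  if (!all(dim(as.matrix(orig)) == dim(as.matrix(recon))))
    stop("loading sets differ in shape", call. = FALSE)
  o <- as.vector(as.matrix(orig)); r <- as.vector(as.matrix(recon))
  if (length(o) < 3L)
    stop("need at least 3 loading values", call. = FALSE)
  if (sd(o) == 0 || sd(r) == 0)
    stop("loading correlation undefined: zero variance in a loading set",
         call. = FALSE)
  cor(o, r)
}

#' Sum of squared errors between loading sets
#'
#' @param orig,recon loading matrices (samples x components) of identical
#'   shape.
#' @return list with `total` (the SSE) and `per_sample` (SSE per sample,
#'   summed over components only).
#' @export
loading_sse <- function(orig, recon) {
  orig <- as.matrix(orig); recon <- as.matrix(recon)
  if (!all(dim(orig) == dim(recon)))
    stop("loading sets differ in shape", call. = FALSE)
  d2 <- (orig - recon)^2
  list(total = sum(d2), per_sample = rowSums(d2))
}

#' Fidelity metrics of a reconstruction against its model
#'
#' @param model the [fit_pca()] model.
#' @param recon a [reconstruct_modality()] result (or a loading matrix).
#' @return list with `loading_correlation`, `loading_sse`, `per_frame_sse`.
#' @export
fidelity_metrics <- function(model, recon) {
  rl <- if (inherits(recon, "facetract_recon")) recon$recon_loadings else recon
  sse <- loading_sse(model$loadings, rl)
  list(loading_correlation = loading_correlation(model$loadings, rl),
       loading_sse = sse$total, per_frame_sse = sse$per_sample)
}
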