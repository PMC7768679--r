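# Frame-order permutation nulls for reconstruction fidelity.
#
# For each permutation the MR frame order is shuffled while the video order
# is kept, the PCA is refit on the shuffled hybrid, the MR modality is
# reconstructed from the video, and the loading correlation / SSE against
# that shuffled fit's own loadings are recorded. The refit never forms
# observation-space components: shuffling MR frames only permutes MR columns,
# so the sample Gram matrix of the shuffled hybrid is Gv + Gm[perm, perm] and
# loadings (W * d) and video-only reconstructed loadings (Gpart * W / d) are
# exact functions of the precomputed Gram blocks. The component-sign rule
# (largest-magnitude loading positive) matches fit_pca(), so the observed
# metrics agree exactly with the explicit reconstruct_modality() route.

# Loadings-space metrics from a sample Gram matrix and the Gram block of the
# partial (video-only) columns against the full columns.
#' @keywords internal
metrics_from_gram <- function(g, gpart, tol = 1e-10) {
  eg <- eigen(g, symmetric = TRUE)
  lam <- eg$values
  keep <- which(lam > max(lam, 0) * tol & lam > 0)
  d <- sqrt(lam[keep])
  w <- eg$vectors[, keep, drop = FALSE]
  l <- w %*% diag(d, nrow = length(d))                     # n x k
  rl <- gpart %*% w %*% diag(1 / d, nrow = length(d))      # n x k
  for (k in seq_along(d)) {
    jmax <- which.max(abs(l[, k]))
    if (l[jmax, k] < 0) { l[, k] <- -l[, k]; rl[, k] <- -rl[, k] }
  }
  d2 <- (l - rl)^2
  list(r = cor(as.vector(l), as.vector(rl)),
       sse = sum(d2), per_frame_sse = rowSums(d2),
       loadings = l, recon_loadings = rl)
}

# Gram matrices for a paired-frame arrangement: sample j stacks frames
# (j, j+1) of the video and frames (a[j], b[j]) of the MR sequence.
#' @keywords internal
paired_grams <- function(gv, gm, a, b) {
  ns <- length(a)
  i1 <- seq_len(ns)
  gvp <- gv[i1, i1, drop = FALSE] + gv[i1 + 1L, i1 + 1L, drop = FALSE]
  g <- gvp + gm[a, a, drop = FALSE] + gm[b, b, drop = FALSE]
  list(g = g, gpart = gvp)
}

#' Frame-order permutation test of cross-modal reconstruction fidelity
#'
#' Shuffles the MR frame order while keeping the video order, refits the PCA
#' on each shuffled hybrid, reconstructs the MR modality from the video, and
#' compares the observed loading correlation and SSE with the null
#' distribution. Identity permutations are rejected and redrawn; p-values use
#' the add-one estimator `(count + 1) / (n_perm + 1)`.
#'
#' Modes: `"single"` shuffles MR frames before building the hybrid;
#' `"paired_keep_pairs"` builds paired-frame samples first and shuffles the
#' (t, t+1) MR pairs as units; `"paired_shuffle_before"` shuffles MR frames
#' and then pairs them, destroying within-pair order.
#'
#' @param video,mr lists with `seq` and `fields` as in [build_hybrid()].
#' @param plan optional [match_frames()] plan applied to the video.
#' @param n_perm number of permutations (default 1000).
#' @param mode see above.
#' @param seed seed for the permutation draws.
#' @param channel_weights as in [build_hybrid()].
#' @return object of class `facetract_permtest`: `observed` (list `r`, `sse`,
#'   `per_frame_sse`), `null_r`, `null_sse` (length `n_perm`),
#'   `p_value_correlation`, `p_value_sse`, `null_mean`, `null_ci95`
#'   (percentile 2.5-97.5 of the null correlations), `mode`, `n_perm`, `seed`.
#' @export
permutation_test <- function(video, mr, plan = NULL, n_perm = 1000L,
                             mode = c("single", "paired_keep_pairs",
                                      "paired_shuffle_before"),
                             seed = 1L, channel_weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L)
  h <- build_hybrid(video, mr, plan, channel_weights)
  n <- h$n_frames
  if (n <= 2L)
    stop("sequence too short to permute (need more than 2 matched frames)",
         call. = FALSE)
  vrows <- block_rows(h, "video")
  gv <- crossprod(h$data[vrows, , drop = FALSE])
  gm <- crossprod(h$data[-vrows, , drop = FALSE])
  tol <- 1e-10
  if (mode == "single") {
    observed <- metrics_from_gram(gv + gm, gv, tol)
    draw <- function() sample.int(n)
    metrics_for <- function(s)
      metrics_from_gram(gv + gm[s, s, drop = FALSE], gv, tol)
    is_identity <- function(s) all(s == seq_len(n))
  } else if (mode == "paired_keep_pairs") {
    ns <- n - 1L
    gr <- paired_grams(gv, gm, seq_len(ns), seq_len(ns) + 1L)
    observed <- metrics_from_gram(gr$g, gr$gpart, tol)
    draw <- function() sample.int(ns)
    metrics_for <- function(s) {
      gr <- paired_grams(gv, gm, s, s + 1L)
      metrics_from_gram(gr$g, gr$gpart, tol)
    }
    is_identity <- function(s) all(s == seq_len(ns))
  } else {
    ns <- n - 1L
    gr <- paired_grams(gv, gm, seq_len(ns), seq_len(ns) + 1L)
    observed <- metrics_from_gram(gr$g, gr$gpart, tol)
    draw <- function() sample.int(n)
    metrics_for <- function(s) {
      gr <- paired_grams(gv, gm, s[seq_len(ns)], s[2:n])
      metrics_from_gram(gr$g, gr$gpart, tol)
    }
    is_identity <- function(s) all(s == seq_len(n))
  }
  set.seed(seed)
  null_r <- numeric(n_perm); null_sse <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- draw()
    while (is_identity(s)) s <- draw()
    m <- metrics_for(s)
    null_r[b] <- m$r
    null_sse[b] <- m$sse
  }
  structure(list(
    observed = list(r = observed$r, sse = observed$sse,
                    per_frame_sse = observed$per_frame_sse),
    null_r = null_r, null_sse = null_sse,
    p_value_correlation = (sum(null_r >= observed$r) + 1) / (n_perm + 1),
    p_value_sse = (sum(null_sse <= observed$sse) + 1) / (n_perm + 1),
    null_mean = mean(null_r),
    null_ci95 = unname(quantile(null_r, c(0.025, 0.975))),
    null_sse_mean = mean(null_sse),
    null_sse_ci95 = unname(quantile(null_sse, c(0.025, 0.975))),
    mode = mode, n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "facetract_permtest")
}

#' @export
print.facetract_permtest <- function(x, ...) {
  cat(sprintf("<facetract_permtest (%s): observed R = %.4f, null mean = %.4f [%.4f, %.4f]\n",
              x$mode, x$observed$r, x$null_mean, x$null_ci95[1], x$null_ci95[2]))
  cat(sprintf("  p(correlation) = %.4g, p(SSE) = %.4g, %d permutations>\n",
              x$p_value_correlation, x$p_value_sse, x$n_perm))
  invisible(x)
}
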