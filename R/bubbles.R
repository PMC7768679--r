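# Bubbles occlusion-importance mapping.
#
# Which regions of one modality drive faithful reconstruction of the other?
# Random disc masks occlude the driving modality (multiplying its pixel
# channels and both warp planes by the Boolean mask — no mean fill, matching
# the uncentered PCA), the occluded columns are projected into the ORIGINAL
# PCA space, and iterations are ranked by loading SSE. Masks of the
# best-performing (lowest-SSE) iterations are summed (CorrectPlane) and
# divided by the sum of all masks (TotalPlane) to give the ProportionPlane.

#' Generate a random bubble mask
#'
#' Hard-edged Boolean discs: `n_bubbles` centers drawn uniformly over the
#' pixel grid; a pixel is visible iff its Euclidean distance to some center
#' is at most `diameter / 2`. Discs may overlap and may be clipped at the
#' image border.
#'
#' @param height,width mask geometry (px).
#' @param n_bubbles number of discs (default 46).
#' @param diameter disc diameter in px (default 12).
#' @param seed integer seed.
#' @return object of class `bubble_mask`: `mask` (logical height x width),
#'   `centers` (n x 2 matrix of row, col), `diameter`, `n_bubbles`, `seed`.
#' @export
generate_mask <- function(height, width, n_bubbles = 46L, diameter = 12L,
                          seed = 1L) {
  if (height < 1L || width < 1L)
    stop("mask dimensions must be positive", call. = FALSE)
  stopifnot(n_bubbles >= 1L, diameter >= 1L)
  set.seed(seed)
  centers <- cbind(row = sample.int(height, n_bubbles, replace = TRUE),
                   col = sample.int(width, n_bubbles, replace = TRUE))
  structure(list(mask = mask_from_centers(height, width, centers, diameter / 2),
                 centers = centers, diameter = as.integer(diameter),
                 n_bubbles = as.integer(n_bubbles), seed = as.integer(seed)),
            class = "bubble_mask")
}

#' @keywords internal
mask_from_centers <- function(height, width, centers, radius) {
  mask <- matrix(FALSE, height, width)
  ir <- ceiling(radius)
  off_r <- rep(-ir:ir, times = 2L * ir + 1L)
  off_c <- rep(-ir:ir, each = 2L * ir + 1L)
  in_disc <- off_r^2 + off_c^2 <= radius^2
  off_r <- off_r[in_disc]; off_c <- off_c[in_disc]
  for (i in seq_len(nrow(centers))) {
    rr <- centers[i, 1L] + off_r
    cc <- centers[i, 2L] + off_c
    ok <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Occlude one modality with a bubble mask and reconstruct
#'
#' Applies the same mask to every frame's pixel channels and both warp
#' planes of the occluded modality, zeroes the other modality's blocks
#' entirely, projects into the (unoccluded) model, and scores the resulting
#' loadings against the model's original loadings.
#'
#' @param model [fit_pca()] model fit on the *unoccluded* hybrid `h`.
#' @param h the hybrid array.
#' @param mask a [generate_mask()] mask in the occluded modality's geometry
#'   (or a logical matrix).
#' @param occluded_modality the modality the mask is applied to; the other
#'   one is zeroed.
#' @return list: `recon_loadings`, `loading_correlation` (`NA` when the
#'   occluded columns are all zero), `loading_sse`, `per_frame_sse`.
#' @export
occlude_and_reconstruct <- function(model, h, mask, occluded_modality) {
  m <- if (inherits(mask, "bubble_mask")) mask$mask else mask
  bm <- h$block_map[[occluded_modality]]
  if (is.null(bm)) stop("unknown modality: ", occluded_modality, call. = FALSE)
  g <- bm$geometry
  if (nrow(m) != g$height || ncol(m) != g$width)
    stop("mask geometry does not match the occluded modality", call. = FALSE)
  mv <- rep(as.vector(m), g$channels + 2L)
  partial <- h$data
  other <- setdiff(names(h$block_map), occluded_modality)
  for (mod in other) partial[block_rows(h, mod), ] <- 0
  occ_rows <- block_rows(h, occluded_modality)
  nrep <- length(occ_rows) / length(mv)  # 2 for paired arrays
  partial[occ_rows, ] <- partial[occ_rows, , drop = FALSE] *
    rep(mv, times = nrep)
  rl <- project(model, partial)
  sse <- loading_sse(model$loadings, rl)
  r <- if (sd(as.vector(rl)) == 0) NA_real_
       else loading_correlation(model$loadings, rl)
  list(recon_loadings = rl, loading_correlation = r,
       loading_sse = sse$total, per_frame_sse = sse$per_sample)
}

#' Proportion plane from scored bubble iterations
#'
#' Selects the `floor(top_frac * n)` iterations with the lowest SSE (ties
#' broken by iteration index), sums their masks into the CorrectPlane, and
#' divides by the sum of all masks (TotalPlane). With a matrix of per-frame
#' SSEs the selection is re-ranked independently for each frame.
#'
#' @param masks list of [generate_mask()] masks (or logical matrices).
#' @param sses numeric vector (whole-sequence scope) or iterations x frames
#'   matrix (per-frame scope) of loading SSEs, aligned with `masks`.
#' @param top_frac fraction of iterations to select (default 0.1).
#' @return object of class `proportion_plane`: `plane` (per-pixel map in
#'   \[0, 1\], `NA` where no mask ever covered the pixel; an H x W x frames
#'   array in per-frame scope), `correct_plane`, `total_plane`, `scope`,
#'   `top_frac`.
#' @export
proportion_plane <- function(masks, sses, top_frac = 0.1) {
  mats <- lapply(masks, function(m) if (inherits(m, "bubble_mask")) m$mask else m)
  n <- length(mats)
  per_frame <- is.matrix(sses)
  n_sse <- if (per_frame) nrow(sses) else length(sses)
  if (n_sse != n) stop("masks and sses lengths differ", call. = FALSE)
  if (n < 10L) stop("need at least 10 iterations", call. = FALSE)
  n_top <- floor(top_frac * n)
  if (n_top < 1L) stop("top_frac selects no iterations", call. = FALSE)
  total <- Reduce(`+`, mats)
  sum_selected <- function(sse_vec) {
    sel <- order(sse_vec, seq_len(n))[seq_len(n_top)]
    Reduce(`+`, mats[sel])
  }
  if (!per_frame) {
    correct <- sum_selected(sses)
    plane <- ifelse(total > 0, correct / total, NA_real_)
    scope <- "sequence"
  } else {
    nf <- ncol(sses)
    correct <- array(0L, dim = c(dim(total), nf))
    plane <- array(NA_real_, dim = c(dim(total), nf))
    for (f in seq_len(nf)) {
      cf <- sum_selected(sses[, f])
      correct[, , f] <- cf
      plane[, , f] <- ifelse(total > 0, cf / total, NA_real_)
    }
    scope <- "frame"
  }
  structure(list(plane = plane, correct_plane = correct, total_plane = total,
                 scope = scope, top_frac = top_frac, n_iter = n),
            class = "proportion_plane")
}

#' Run a full Bubbles analysis
#'
#' Repeats mask generation + occluded reconstruction `n_iter` times against
#' a fixed model and returns whole-sequence (and optionally per-frame)
#' proportion planes.
#'
#' @param model [fit_pca()] model fit on `h`.
#' @param h the unoccluded hybrid.
#' @param occluded_modality modality the masks occlude (the reconstruction
#'   driver).
#' @param n_iter number of mask iterations.
#' @param n_bubbles,diameter,top_frac Bubbles parameters.
#' @param seed master seed; iteration i uses `seed + i`.
#' @param per_frame also compute per-frame planes?
#' @return object of class `facetract_bubbles`: `plane` (whole-sequence
#'   [proportion_plane()]), `plane_per_frame` (or `NULL`), `sse` (per
#'   iteration), `per_frame_sse` (iterations x frames), `masks`, parameters.
#' @export
bubbles_analysis <- function(model, h, occluded_modality, n_iter = 1000L,
                             n_bubbles = 46L, diameter = 12L, top_frac = 0.1,
                             seed = 1L, per_frame = FALSE) {
  bm <- h$block_map[[occluded_modality]]
  if (is.null(bm)) stop("unknown modality: ", occluded_modality, call. = FALSE)
  g <- bm$geometry
  occ_rows <- block_rows(h, occluded_modality)
  # precompute the occluded-modality slices once; per iteration the masked
  # projection is a single crossprod
  u_occ <- model$components[occ_rows, , drop = FALSE]
  x_occ <- h$data[occ_rows, , drop = FALSE]
  if (model$centered)
    stop("bubbles analysis requires the uncentered model", call. = FALSE)
  l <- model$loadings
  n <- ncol(x_occ)
  nrep <- length(occ_rows) / ((g$channels + 2L) * g$height * g$width)
  masks <- vector("list", n_iter)
  sse <- numeric(n_iter)
  pf <- matrix(0, n_iter, n)
  for (i in seq_len(n_iter)) {
    bmask <- generate_mask(g$height, g$width, n_bubbles, diameter,
                           seed = seed + i)
    masks[[i]] <- bmask
    mv <- rep(rep(as.vector(bmask$mask), g$channels + 2L), times = nrep)
    rl <- crossprod(x_occ * mv, u_occ)
    d2 <- (l - rl)^2
    sse[i] <- sum(d2)
    pf[i, ] <- rowSums(d2)
  }
  structure(list(
    plane = proportion_plane(masks, sse, top_frac),
    plane_per_frame = if (per_frame) proportion_plane(masks, pf, top_frac),
    sse = sse, per_frame_sse = pf, masks = masks,
    occluded_modality = occluded_modality, n_iter = as.integer(n_iter),
    n_bubbles = as.integer(n_bubbles), diameter = as.integer(diameter),
    top_frac = top_frac, seed = as.integer(seed)),
    class = "facetract_bubbles")
}

#' @export
print.facetract_bubbles <- function(x, ...) {
  cat(sprintf("<facetract_bubbles: %s occluded, %d iterations, %d bubbles of %d px, top %.0f%%>\n",
              x$occluded_modality, x$n_iter, x$n_bubbles, x$diameter,
              100 * x$top_frac))
  invisible(x)
}
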