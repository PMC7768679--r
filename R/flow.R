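# Dense two-frame optic flow and reference-frame selection.
#
# The pipeline only relies on the semantics of the warp field: a per-pixel
# (dx, dy) displacement, in pixels, that maps the current frame onto the
# reference frame, rendered by backward bilinear sampling with border clamp.
# The default estimator is a multi-scale, iteratively refined, dense
# Lucas-Kanade-style gradient scheme; any estimator with the same contract
# can be substituted via the `estimator` argument of select_reference().

#' Construct a warp field
#'
#' @param dx,dy numeric matrices of per-pixel column/row displacements (px).
#' @return object of class `warp_field`.
#' @export
warp_field <- function(dx, dy) {
  stopifnot(is.matrix(dx), is.matrix(dy), all(dim(dx) == dim(dy)))
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stop("warp field must be finite everywhere", call. = FALSE)
  structure(list(dx = dx, dy = dy), class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  cat(sprintf("<warp_field %d x %d, mean |d| = %.3f px>\n",
              nrow(x$dx), ncol(x$dx), mean(sqrt(x$dx^2 + x$dy^2))))
  invisible(x)
}

#' Estimate the dense warp of a frame onto a reference
#'
#' Multi-scale iterative gradient-based flow. At each pyramid level the
#' current field backward-warps the frame onto the reference grid, the
#' residual is linearized against the warped frame's spatial gradients, and a
#' windowed least-squares update is solved per pixel; the field is lightly
#' smoothed between iterations. Constant (untextured) inputs yield a zero
#' field with a warning.
#'
#' @param frame,reference frames of identical geometry (matrix or H x W x C;
#'   channels are averaged before estimation).
#' @param n_levels pyramid depth; `NULL` picks `log2(min(H, W) / 16)` levels
#'   (at least 1, at most 4).
#' @param n_iter refinement iterations per level.
#' @param window_radius radius of the least-squares window (px).
#' @param smooth_sigma Gaussian sigma for inter-iteration field smoothing.
#' @return a [warp_field()] mapping `frame` onto `reference`.
#' @export
estimate_warp <- function(frame, reference, n_levels = NULL, n_iter = 3L,
                          window_radius = 4L, smooth_sigma = 1) {
  if (!same_geometry(frame, reference))
    stop("frame and reference geometry differ", call. = FALSE)
  f <- as_gray(frame); r <- as_gray(reference)
  H <- nrow(f); W <- ncol(f)
  if (sd(f) < 1e-10 && sd(r) < 1e-10) {
    warning("untextured (constant) inputs; returning zero field")
    return(warp_field(matrix(0, H, W), matrix(0, H, W)))
  }
  if (is.null(n_levels))
    n_levels <- max(1L, min(4L, floor(log2(min(H, W) / 16)) + 1L))
  fp <- list(f); rp <- list(r)
  for (l in seq_len(n_levels - 1L)) {
    fp[[l + 1L]] <- downsample2(fp[[l]])
    rp[[l + 1L]] <- downsample2(rp[[l]])
  }
  dx <- matrix(0, nrow(fp[[n_levels]]), ncol(fp[[n_levels]]))
  dy <- dx
  for (l in rev(seq_len(n_levels))) {
    fl <- gauss_blur(fp[[l]], 0.8)
    rl <- gauss_blur(rp[[l]], 0.8)
    h <- nrow(fl); w <- ncol(fl)
    if (nrow(dx) != h || ncol(dx) != w) {
      dx <- 2 * resize_bilinear(dx, h, w)
      dy <- 2 * resize_bilinear(dy, h, w)
    }
    for (it in seq_len(n_iter)) {
      wimg <- warp_bilinear_cpp(fl, dx, dy)
      gx <- 0.5 * (wimg[, c(2:w, w), drop = FALSE] - wimg[, c(1, seq_len(w - 1)), drop = FALSE])
      gy <- 0.5 * (wimg[c(2:h, h), , drop = FALSE] - wimg[c(1, seq_len(h - 1)), , drop = FALSE])
      e <- wimg - rl
      a11 <- box_sum_cpp(gx * gx, window_radius)
      a12 <- box_sum_cpp(gx * gy, window_radius)
      a22 <- box_sum_cpp(gy * gy, window_radius)
      b1 <- box_sum_cpp(gx * e, window_radius)
      b2 <- box_sum_cpp(gy * e, window_radius)
      reg <- 1e-3 * mean(a11 + a22) + 1e-12
      det <- (a11 + reg) * (a22 + reg) - a12 * a12
      ux <- -((a22 + reg) * b1 - a12 * b2) / det
      uy <- -((a11 + reg) * b2 - a12 * b1) / det
      # cap per-iteration updates at 1 px for stability
      ux <- pmin(pmax(ux, -1), 1)
      uy <- pmin(pmax(uy, -1), 1)
      dx <- dx + ux
      dy <- dy + uy
      if (smooth_sigma > 0) {
        dx <- gauss_blur(dx, smooth_sigma)
        dy <- gauss_blur(dy, smooth_sigma)
      }
    }
  }
  warp_field(dx, dy)
}

#' Backward-warp an image by a warp field
#'
#' Samples the image at displaced coordinates with bilinear interpolation;
#' out-of-bounds samples clamp to the border. With the field produced by
#' [estimate_warp()] this renders the frame onto the reference grid.
#'
#' @param image matrix or H x W x C array.
#' @param field a [warp_field()] with matching geometry.
#' @return warped image with the geometry and channels of `image`.
#' @export
warp_image <- function(image, field) {
  stopifnot(inherits(field, "warp_field"))
  g <- img_geometry(image)
  if (g$height != nrow(field$dx) || g$width != ncol(field$dx))
    stop("image and warp field geometry differ", call. = FALSE)
  if (is.matrix(image)) return(warp_bilinear_cpp(image, field$dx, field$dy))
  out <- image
  for (k in seq_len(g$channels))
    out[, , k] <- warp_bilinear_cpp(image[, , k], field$dx, field$dy)
  out
}

#' Select a reference frame by iterated mean texture
#'
#' Iteration 1 uses a seeded random frame as reference. Each iteration warps
#' every frame onto the current reference and sets the next reference to the
#' mean of the warped textures; after `n_iterations` rounds the reference used
#' in the final round and the warp fields estimated against it are returned.
#' Three iterations give a reference that is nearly independent of the random
#' starting frame while keeping the cost fixed.
#'
#' @param seq H x W x C x n sequence (or list of frames).
#' @param n_iterations number of mean-texture iterations (default 3).
#' @param seed seed for the random initial reference.
#' @param estimator flow estimator, `function(frame, reference) -> warp_field`.
#' @return object of class `reference_selection` with elements `reference`
#'   (the reference the returned fields map onto), `fields` (final-iteration
#'   warp fields, one per frame), `references` (the reference at the start of
#'   each iteration plus the final mean texture), `n_iterations`, `seed`.
#' @export
select_reference <- function(seq, n_iterations = 3L, seed = 1L,
                             estimator = estimate_warp) {
  if (is.list(seq)) seq <- image_seq(seq)
  n <- n_frames(seq)
  if (is.null(n) || n < 2L) stop("sequence must contain at least 2 frames", call. = FALSE)
  stopifnot(n_iterations >= 1L)
  set.seed(seed)
  ref <- get_frame(seq, sample.int(n, 1L))
  refs <- list(ref)
  fields <- NULL
  for (it in seq_len(n_iterations)) {
    ref_gray <- as_gray(ref)
    fields <- lapply(seq_len(n), function(j)
      estimator(as_gray(get_frame(seq, j)), ref_gray))
    warped <- lapply(seq_len(n), function(j)
      warp_image(get_frame(seq, j), fields[[j]]))
    mean_tex <- Reduce(`+`, warped) / n
    refs[[it + 1L]] <- mean_tex
    if (it < n_iterations) ref <- mean_tex
  }
  structure(list(reference = ref, fields = fields, references = refs,
                 n_iterations = n_iterations, seed = seed),
            class = "reference_selection")
}

#' @export
print.reference_selection <- function(x, ...) {
  g <- img_geometry(x$reference)
  cat(sprintf("<reference_selection %d x %d, %d frames, %d iterations, seed %d>\n",
              g$height, g$width, length(x$fields), x$n_iterations, x$seed))
  invisible(x)
}
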