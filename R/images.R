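# Image and sequence containers.
#
# Conventions used throughout the package:
#   * a frame is a numeric H x W matrix (grayscale) or H x W x C array;
#   * a sequence is a 4-D numeric array H x W x C x n_frames;
#   * pixel intensities live on their native 0-255 scale;
#   * warp fields are in pixel units, (dx, dy) = (column, row) displacement
#     that maps the current frame onto the reference (backward sampling).

#' Geometry of an image or sequence
#'
#' @param x a matrix (H x W), an H x W x C frame, or an H x W x C x n sequence.
#' @return named list with `height`, `width`, `channels`.
#' @export
img_geometry <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    stop("expected a matrix, an H x W x C frame, or an H x W x C x n sequence",
         call. = FALSE)
  list(height = d[1L], width = d[2L],
       channels = if (length(d) >= 3L) d[3L] else 1L)
}

#' @keywords internal
same_geometry <- function(a, b) {
  ga <- img_geometry(a); gb <- img_geometry(b)
  ga$height == gb$height && ga$width == gb$width
}

#' Collapse a frame to grayscale
#'
#' Channels are averaged; a matrix passes through unchanged.
#' @param frame matrix or H x W x C array.
#' @return numeric matrix.
#' @export
as_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  d <- dim(frame)
  if (length(d) == 3L) {
    if (d[3L] == 1L) return(frame[, , 1L])
    g <- frame[, , 1L]
    for (k in 2:d[3L]) g <- g + frame[, , k]
    return(g / d[3L])
  }
  stop("expected a single frame", call. = FALSE)
}

#' Build a sequence array from a list of frames
#'
#' @param frames list of frames, all with identical geometry.
#' @return H x W x C x n array.
#' @export
image_seq <- function(frames) {
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  f1 <- frames[[1L]]
  g <- img_geometry(f1)
  arr <- array(0, dim = c(g$height, g$width, g$channels, length(frames)))
  for (j in seq_along(frames)) {
    fj <- frames[[j]]
    gj <- img_geometry(fj)
    if (gj$height != g$height || gj$width != g$width || gj$channels != g$channels)
      stop("inconsistent frame geometry at frame ", j, call. = FALSE)
    if (is.matrix(fj)) dim(fj) <- c(g$height, g$width, 1L)
    arr[, , , j] <- fj
  }
  arr
}

#' @keywords internal
n_frames <- function(seq) dim(seq)[4L]

#' @keywords internal
get_frame <- function(seq, j) array(seq[, , , j], dim = dim(seq)[1:3])

# --- low-level resampling helpers (used by the flow pyramid) ----------------

#' @keywords internal
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' @keywords internal
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sep_conv_cpp(m, gauss_kernel(sigma))
}

# Halve resolution: blur then keep every other pixel (odd indices).
#' @keywords internal
downsample2 <- function(m) {
  b <- gauss_blur(m, 1)
  b[seq(1L, nrow(m), by = 2L), seq(1L, ncol(m), by = 2L), drop = FALSE]
}

# Bilinear resize with align-corners index mapping.
#' @keywords internal
resize_bilinear <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  rr <- if (h2 == 1L) rep(1, h2) else (seq_len(h2) - 1) * (h - 1) / (h2 - 1) + 1
  cc <- if (w2 == 1L) rep(1, w2) else (seq_len(w2) - 1) * (w - 1) / (w2 - 1) + 1
  r0 <- pmin(pmax(floor(rr), 1L), h - 1L); fr <- rr - r0
  c0 <- pmin(pmax(floor(cc), 1L), w - 1L); fc <- cc - c0
  if (h == 1L) { r0 <- rep(1L, h2); fr <- rep(0, h2) }
  if (w == 1L) { c0 <- rep(1L, w2); fc <- rep(0, w2) }
  a <- m[r0, c0, drop = FALSE]; b <- m[pmin(r0 + 1L, h), c0, drop = FALSE]
  cmat <- m[r0, pmin(c0 + 1L, w), drop = FALSE]
  dmat <- m[pmin(r0 + 1L, h), pmin(c0 + 1L, w), drop = FALSE]
  FR <- matrix(fr, h2, w2); FC <- matrix(fc, h2, w2, byrow = TRUE)
  (1 - FR) * (1 - FC) * a + FR * (1 - FC) * b + (1 - FR) * FC * cmat + FR * FC * dmat
}
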