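# Temporal frame matching and hybrid observation arrays.
#
# Serialization layout per modality (one column per matched frame):
# channel 1 column-major, channel 2, channel 3, then dx column-major, then
# dy — (C + 2) * H * W rows for a C-channel frame. The two modalities'
# blocks are stacked video-first. Intensities stay on their native 0-255
# scale and warps in pixels; `channel_weights` exposes rebalancing of the
# mixed units but defaults to 1 everywhere.

#' Plan the temporal matching of a video to a shorter MR sequence
#'
#' The video runs at a higher frame rate, so it is decimated to the MR frame
#' count: with scale factor `s = n_vid / n_mr`, retained video index `i` is
#' `round(1 + (i - 1) * s)` for `i = 1..n_mr`, with halves rounded away from
#' zero. The first frame is always retained.
#'
#' @param n_vid,n_mr frame counts; the MR sequence must not be longer.
#' @return object of class `frame_match_plan` with `scale_factor` and the
#'   1-based `retained_indices` into the video sequence.
#' @export
match_frames <- function(n_vid, n_mr) {
  if (!is.numeric(n_vid) || !is.numeric(n_mr) || n_vid < 1L || n_mr < 1L)
    stop("frame counts must be positive integers", call. = FALSE)
  if (n_mr > n_vid)
    stop("n_mr must not exceed n_vid (the MR sequence is the shorter one)",
         call. = FALSE)
  s <- n_vid / n_mr
  raw <- 1 + (seq_len(n_mr) - 1) * s
  idx <- as.integer(sign(raw) * floor(abs(raw) + 0.5))  # half away from zero
  idx <- pmin(idx, as.integer(n_vid))
  structure(list(n_vid = as.integer(n_vid), n_mr = as.integer(n_mr),
                 scale_factor = s, retained_indices = idx),
            class = "frame_match_plan")
}

#' @export
print.frame_match_plan <- function(x, ...) {
  cat(sprintf("<frame_match_plan: %d video -> %d MR frames, scale %.4g>\n",
              x$n_vid, x$n_mr, x$scale_factor))
  cat("retained:", x$retained_indices, "\n")
  invisible(x)
}

#' Serialize one frame and its warp field into an observation vector
#'
#' @param image matrix or H x W x C frame.
#' @param field a [warp_field()] of the same geometry.
#' @return numeric vector of length `(C + 2) * H * W`.
#' @export
serialize_frame <- function(image, field) {
  stopifnot(inherits(field, "warp_field"))
  g <- img_geometry(image)
  if (g$height != nrow(field$dx) || g$width != ncol(field$dx))
    stop("image and warp field geometry differ", call. = FALSE)
  if (is.matrix(image)) dim(image) <- c(g$height, g$width, 1L)
  c(as.vector(image), as.vector(field$dx), as.vector(field$dy))
}

#' Invert [serialize_frame()]
#'
#' @param vec observation vector.
#' @param geometry list with `height`, `width`, `channels`.
#' @return list with `image` (H x W x C array) and `field` ([warp_field()]).
#' @export
deserialize_frame <- function(vec, geometry) {
  h <- geometry$height; w <- geometry$width; ch <- geometry$channels
  if (length(vec) != (ch + 2L) * h * w)
    stop("vector length does not match the geometry record", call. = FALSE)
  np <- h * w * ch
  img <- array(vec[seq_len(np)], dim = c(h, w, ch))
  dx <- matrix(vec[np + seq_len(h * w)], h, w)
  dy <- matrix(vec[np + h * w + seq_len(h * w)], h, w)
  list(image = img, field = warp_field(dx, dy))
}

# Serialize a whole modality: seq H x W x C x n plus a list of n warp fields.
#' @keywords internal
serialize_modality <- function(seq, fields) {
  n <- n_frames(seq)
  stopifnot(length(fields) == n)
  d <- dim(seq)
  np <- d[1L] * d[2L] * d[3L]
  out <- matrix(0, (d[3L] + 2L) * d[1L] * d[2L], n)
  for (j in seq_len(n)) {
    out[seq_len(np), j] <- seq[, , , j]
    out[np + seq_len(d[1L] * d[2L]), j] <- fields[[j]]$dx
    out[np + d[1L] * d[2L] + seq_len(d[1L] * d[2L]), j] <- fields[[j]]$dy
  }
  out
}

#' @keywords internal
normalize_weights <- function(w) {
  if (is.null(w)) return(c(pixel = 1, warp = 1))
  if (is.numeric(w) && length(w) == 1L) return(c(pixel = w, warp = w))
  c(pixel = if (is.null(w[["pixel"]])) 1 else w[["pixel"]],
    warp = if (is.null(w[["warp"]])) 1 else w[["warp"]])
}

#' Build the multimodality hybrid array
#'
#' Applies the frame-match plan to the video modality, serializes both
#' modalities and stacks them (video block on top) into one observation-by-
#' frame array with a block map recording each modality's row ranges and
#' geometry.
#'
#' @param video,mr lists with `seq` (H x W x C x n array) and `fields` (list
#'   of [warp_field()], one per frame). The video may carry `plan$n_vid`
#'   frames (they are decimated by `plan`) or already exactly `n_mr` frames.
#' @param plan optional [match_frames()] plan; `NULL` requires equal counts.
#' @param channel_weights optional per-modality weights: a list like
#'   `list(video = c(pixel = 1, warp = 1), mr = 1)`. A scalar weights a whole
#'   modality block.
#' @return object of class `hybrid_array` with `data` (observations x
#'   frames), `block_map`, `n_frames`.
#' @export
build_hybrid <- function(video, mr, plan = NULL, channel_weights = NULL) {
  nv <- n_frames(video$seq); nm <- n_frames(mr$seq)
  if (!is.null(plan)) {
    stopifnot(inherits(plan, "frame_match_plan"))
    if (nv == plan$n_vid && nm == plan$n_mr) {
      keep <- plan$retained_indices
      video <- list(seq = video$seq[, , , keep, drop = FALSE],
                    fields = video$fields[keep])
      nv <- length(keep)
    }
  }
  if (nv != nm)
    stop("modalities do not have matching frame counts after applying the plan",
         call. = FALSE)
  wv <- normalize_weights(channel_weights$video)
  wm <- normalize_weights(channel_weights$mr)
  gv <- img_geometry(video$seq); gm <- img_geometry(mr$seq)
  bv <- serialize_modality(video$seq, video$fields)
  bm <- serialize_modality(mr$seq, mr$fields)
  apply_w <- function(block, g, w) {
    np <- g$height * g$width * g$channels
    block[seq_len(np), ] <- block[seq_len(np), , drop = FALSE] * w[["pixel"]]
    block[(np + 1L):nrow(block), ] <-
      block[(np + 1L):nrow(block), , drop = FALSE] * w[["warp"]]
    block
  }
  bv <- apply_w(bv, gv, wv); bm <- apply_w(bm, gm, wm)
  block_map <- list(
    video = list(offset = 0L, nrow = nrow(bv),
                 geometry = gv, weights = wv),
    mr = list(offset = nrow(bv), nrow = nrow(bm),
              geometry = gm, weights = wm))
  structure(list(data = rbind(bv, bm), block_map = block_map,
                 n_frames = nv),
            class = "hybrid_array")
}

#' Row indices of a modality's block
#'
#' @param h a `hybrid_array` or `paired_hybrid_array`.
#' @param modality `"video"` or `"mr"`.
#' @param which_copy for paired arrays, `1` (frame t) or `2` (frame t + 1) or
#'   `"both"`.
#' @return integer vector of row indices into `h$data`.
#' @export
block_rows <- function(h, modality, which_copy = "both") {
  bm <- h$block_map[[modality]]
  if (is.null(bm)) stop("unknown modality: ", modality, call. = FALSE)
  rows <- bm$offset + seq_len(bm$nrow)
  if (inherits(h, "paired_hybrid_array")) {
    base_p <- h$base_nrow
    rows <- switch(as.character(which_copy),
                   "1" = rows,
                   "2" = rows + base_p,
                   both = c(rows, rows + base_p))
  }
  rows
}

#' Deserialize hybrid columns back into images and warp fields
#'
#' Undoes the block weights, so the round trip through [build_hybrid()] is
#' exact whenever the weights are nonzero.
#'
#' @param columns observation-space matrix (e.g. `h$data` or reconstructed
#'   columns), rows laid out as in `block_map`.
#' @param block_map the `block_map` of the hybrid the columns refer to.
#' @return named list per modality: `images` (H x W x C x n), `dx`, `dy`
#'   (H x W x n arrays).
#' @export
deserialize_hybrid <- function(columns, block_map) {
  if (is.vector(columns)) columns <- matrix(columns, ncol = 1L)
  out <- list()
  for (mod in names(block_map)) {
    bm <- block_map[[mod]]
    g <- bm$geometry
    n <- ncol(columns)
    np <- g$height * g$width * g$channels
    block <- columns[bm$offset + seq_len(bm$nrow), , drop = FALSE]
    w <- bm$weights
    if (w[["pixel"]] != 0)
      block[seq_len(np), ] <- block[seq_len(np), , drop = FALSE] / w[["pixel"]]
    if (w[["warp"]] != 0)
      block[(np + 1L):nrow(block), ] <-
        block[(np + 1L):nrow(block), , drop = FALSE] / w[["warp"]]
    imgs <- array(block[seq_len(np), ], dim = c(g$height, g$width, g$channels, n))
    hw <- g$height * g$width
    dx <- array(block[np + seq_len(hw), ], dim = c(g$height, g$width, n))
    dy <- array(block[np + hw + seq_len(hw), ], dim = c(g$height, g$width, n))
    out[[mod]] <- list(images = imgs, dx = dx, dy = dy)
  }
  out
}

#' Stack consecutive frames into a paired-frame hybrid
#'
#' Column `j` of the result stacks columns `j` and `j + 1` of the input, so
#' each sample carries the current and the next frame and the representation
#' implicitly encodes motion direction. The sample count drops to
#' `n_frames - 1`.
#'
#' @param h a `hybrid_array` with at least 2 columns.
#' @return object of class `paired_hybrid_array`.
#' @export
build_paired <- function(h) {
  stopifnot(inherits(h, "hybrid_array"))
  n <- ncol(h$data)
  if (n < 2L) stop("need at least 2 frames to build paired samples", call. = FALSE)
  data2 <- rbind(h$data[, seq_len(n - 1L), drop = FALSE],
                 h$data[, 2:n, drop = FALSE])
  structure(list(data = data2, block_map = h$block_map,
                 base_nrow = nrow(h$data), n_frames = n,
                 n_samples = n - 1L),
            class = c("paired_hybrid_array", "hybrid_array"))
}

#' Recover the two stacked columns of a paired sample
#'
#' @param ph a `paired_hybrid_array`.
#' @param j sample index.
#' @return matrix with two columns: frames `j` and `j + 1` in single-frame
#'   layout.
#' @export
unstack_paired <- function(ph, j) {
  stopifnot(inherits(ph, "paired_hybrid_array"))
  p <- ph$base_nrow
  cbind(ph$data[seq_len(p), j], ph$data[p + seq_len(p), j])
}

#' @export
print.hybrid_array <- function(x, ...) {
  cat(sprintf("<%s: %d observations x %d samples (%s)>\n",
              class(x)[1L], nrow(x$data), ncol(x$data),
              paste(names(x$block_map), collapse = " + ")))
  invisible(x)
}
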