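# Synthetic paired-sequence generator.
#
# Stands in for temporally aligned face-video / vocal-tract-MR recordings:
# two image sequences whose frame-to-frame variation is driven partly by
# shared latent "articulation" trajectories (the common cause), partly by
# modality-private latents, plus pixel noise. Every latent channel maps to a
# disjoint image region in each modality it drives, so ground-truth
# informative regions are known exactly and pixels outside all regions are
# constant across frames (the static background of real recordings).

#' Generate latent articulation trajectories
#'
#' Latents follow a stationary AR(1) walk with unit innovation variance:
#' `x[t] = smoothness * x[t-1] + e[t]`, `e ~ N(0, 1)`, with `x[1]` drawn from
#' the stationary distribution. The lag-1 autocorrelation of every channel
#' equals `smoothness`; at `smoothness = 0` successive values are independent.
#' Shared and private channels are mutually independent.
#'
#' @param n_frames number of frames (>= 2).
#' @param k_shared,k_priv_a,k_priv_b channel counts for the shared cause and
#'   the two modality-private causes (any may be 0).
#' @param smoothness AR(1) coefficient in \[0, 1\].
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return object of class `latent_trajectory` with matrices `shared`
#'   (`n_frames` x `k_shared`), `private_a`, `private_b`.
#' @export
generate_latents <- function(n_frames, k_shared = 2L, k_priv_a = 1L,
                             k_priv_b = 1L, smoothness = 0.85, seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 2L)
    stop("n_frames must be a positive integer >= 2", call. = FALSE)
  stopifnot(k_shared >= 0L, k_priv_a >= 0L, k_priv_b >= 0L,
            smoothness >= 0, smoothness <= 1)
  n_frames <- as.integer(n_frames)
  set.seed(seed)
  ar1 <- function(k) {
    x <- matrix(0, n_frames, k)
    if (k == 0L) return(x)
    e <- matrix(rnorm(n_frames * k), n_frames, k)
    sd0 <- if (smoothness < 1) 1 / sqrt(1 - smoothness^2) else 1
    x[1L, ] <- sd0 * e[1L, ]
    for (t in 2:n_frames) x[t, ] <- smoothness * x[t - 1L, ] + e[t, ]
    x
  }
  structure(list(shared = ar1(k_shared), private_a = ar1(k_priv_a),
                 private_b = ar1(k_priv_b), smoothness = smoothness,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "latent_trajectory")
}

# Fixed fractional slot centers per modality; shared channel i occupies slot i
# in both modalities, private channels take the following slots. Slots are
# spaced so that disc regions of the default radius never overlap.
.face_slots <- rbind(
  mouth = c(0.70, 0.50), cheek_l = c(0.52, 0.25), cheek_r = c(0.52, 0.75),
  brow_l = c(0.21, 0.34), brow_r = c(0.21, 0.66), jaw_l = c(0.83, 0.16))
.tract_slots <- rbind(
  jaw = c(0.75, 0.38), tongue = c(0.54, 0.59), velum = c(0.29, 0.66),
  larynx = c(0.83, 0.75), lips = c(0.50, 0.16), nasal = c(0.17, 0.34))

#' Specify the synthetic scene
#'
#' Maps each latent channel to a rendered deformation: a soft-edged Gaussian
#' intensity blob, confined to a disc-shaped region, whose amplitude and
#' vertical position are affine in (a squashed copy of) the latent value.
#' Regions for distinct channels are disjoint by construction.
#'
#' @param k_shared,k_priv_a,k_priv_b latent channel counts (must match the
#'   trajectories rendered later).
#' @param face_shape,tract_shape `c(height, width)` in px.
#' @param noise_sd pixel-noise standard deviation (intensity units, 0-255
#'   scale); the same noise realization is applied to all RGB channels.
#' @param region_radius disc radius of each latent's region (px); default
#'   scales with the geometry.
#' @param blob_sd Gaussian blob sigma (px).
#' @param amp_base,amp_gain blob amplitude `amp_base + amp_gain * tanh(z/2)`.
#' @param pos_gain vertical blob displacement `pos_gain * tanh(z/2)` (px).
#' @param seed seed for the rendering noise.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(k_shared = 2L, k_priv_a = 1L, k_priv_b = 1L,
                       face_shape = c(120L, 160L), tract_shape = c(120L, 160L),
                       noise_sd = 1, region_radius = NULL, blob_sd = NULL,
                       amp_base = 120, amp_gain = 60, pos_gain = NULL,
                       seed = 1L) {
  stopifnot(k_shared >= 0L, k_priv_a >= 0L, k_priv_b >= 0L, noise_sd >= 0)
  n_a <- k_shared + k_priv_a
  n_b <- k_shared + k_priv_b
  if (n_a > nrow(.face_slots) || n_b > nrow(.tract_slots))
    stop("too many latent channels for the available scene slots", call. = FALSE)
  scale_a <- min(face_shape) / 120
  scale_b <- min(tract_shape) / 120
  if (is.null(region_radius)) region_radius <- round(15 * min(scale_a, scale_b))
  if (is.null(blob_sd)) blob_sd <- 3.5 * min(scale_a, scale_b)
  if (is.null(pos_gain)) pos_gain <- 6 * min(scale_a, scale_b)
  if (region_radius < 1) stop("geometry too small for any region", call. = FALSE)
  centers <- function(slots, k, shape) {
    if (k == 0L) return(matrix(0, 0L, 2L))
    cbind(round(slots[seq_len(k), 1L] * shape[1L]),
          round(slots[seq_len(k), 2L] * shape[2L]))
  }
  ca <- centers(.face_slots, n_a, face_shape)
  cb <- centers(.tract_slots, n_b, tract_shape)
  check_disjoint <- function(cc, what) {
    if (nrow(cc) < 2L) return(invisible())
    d <- as.matrix(dist(cc))
    diag(d) <- Inf
    if (min(d) <= 2 * region_radius)
      stop("latent regions overlap in the ", what, " scene", call. = FALSE)
  }
  check_disjoint(ca, "face"); check_disjoint(cb, "tract")
  structure(list(k_shared = as.integer(k_shared),
                 k_priv_a = as.integer(k_priv_a),
                 k_priv_b = as.integer(k_priv_b),
                 face_shape = as.integer(face_shape),
                 tract_shape = as.integer(tract_shape),
                 centers_a = ca, centers_b = cb,
                 noise_sd = noise_sd, region_radius = region_radius,
                 blob_sd = blob_sd, amp_base = amp_base, amp_gain = amp_gain,
                 pos_gain = pos_gain, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @keywords internal
disc_mask <- function(shape, center, radius) {
  rg <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cg <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  (rg - center[1L])^2 + (cg - center[2L])^2 <= radius^2
}

#' Render paired synthetic sequences
#'
#' Each frame is a deterministic function of that frame's latent values plus
#' seeded pixel noise. Intensities are clamped to \[0, 255\] and replicated
#' across three equal RGB channels.
#'
#' @param spec a [scene_spec()].
#' @param latents a [generate_latents()] trajectory whose channel counts match
#'   `spec`.
#' @return object of class `paired_sequence_bundle` with `seq_a` (face-like),
#'   `seq_b` (tract-like), `latents`, `region_masks` (per-channel boolean
#'   masks per modality), and `spec`.
#' @export
render_paired_sequences <- function(spec, latents) {
  stopifnot(inherits(spec, "scene_spec"), inherits(latents, "latent_trajectory"))
  if (ncol(latents$shared) != spec$k_shared ||
      ncol(latents$private_a) != spec$k_priv_a ||
      ncol(latents$private_b) != spec$k_priv_b)
    stop("latent dimensions do not match the scene channel mappings", call. = FALSE)
  n <- latents$n_frames
  render_modality <- function(shape, centers, zmat) {
    H <- shape[1L]; W <- shape[2L]
    bg <- matrix(25 + 15 * (seq_len(H) / H), H, W)  # static gradient backdrop
    masks <- lapply(seq_len(ncol(zmat)), function(k)
      disc_mask(shape, centers[k, ], spec$region_radius))
    rowg <- matrix(seq_len(H), H, W)
    colg <- matrix(seq_len(W), H, W, byrow = TRUE)
    arr <- array(0, dim = c(H, W, 3L, n))
    for (t in seq_len(n)) {
      img <- bg
      for (k in seq_len(ncol(zmat))) {
        u <- tanh(zmat[t, k] / 2)
        amp <- spec$amp_base + spec$amp_gain * u
        cr <- centers[k, 1L] + spec$pos_gain * u
        blob <- amp * exp(-((rowg - cr)^2 + (colg - centers[k, 2L])^2) /
                            (2 * spec$blob_sd^2))
        m <- masks[[k]]
        img[m] <- img[m] + blob[m]
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
      img <- pmin(pmax(img, 0), 255)
      for (ch in 1:3) arr[, , ch, t] <- img
    }
    list(seq = arr, masks = masks)
  }
  za <- cbind(latents$shared, latents$private_a)
  zb <- cbind(latents$shared, latents$private_b)
  set.seed(spec$seed)
  a <- render_modality(spec$face_shape, spec$centers_a, za)
  b <- render_modality(spec$tract_shape, spec$centers_b, zb)
  nm <- function(k_sh, k_pr, tag) c(
    if (k_sh > 0L) paste0("shared", seq_len(k_sh)),
    if (k_pr > 0L) paste0(tag, seq_len(k_pr)))
  names(a$masks) <- nm(spec$k_shared, spec$k_priv_a, "priv_a")
  names(b$masks) <- nm(spec$k_shared, spec$k_priv_b, "priv_b")
  structure(list(seq_a = a$seq, seq_b = b$seq, latents = latents,
                 region_masks = list(a = a$masks, b = b$masks), spec = spec),
            class = "paired_sequence_bundle")
}

#' Simulate a full synthetic bundle in one call
#'
#' Convenience wrapper: generates latents and renders the paired sequences.
#' The latent seed and rendering-noise seed are derived from `seed`.
#'
#' @param n_frames frames per sequence.
#' @param smoothness AR(1) coefficient of the latent walk.
#' @param seed master seed.
#' @param ... passed to [scene_spec()].
#' @return a `paired_sequence_bundle`.
#' @export
simulate_bundle <- function(n_frames = 40L, smoothness = 0.85, seed = 1L, ...) {
  spec <- scene_spec(seed = as.integer(seed) + 1L, ...)
  lat <- generate_latents(n_frames, k_shared = spec$k_shared,
                          k_priv_a = spec$k_priv_a, k_priv_b = spec$k_priv_b,
                          smoothness = smoothness, seed = seed)
  render_paired_sequences(spec, lat)
}

#' @export
print.paired_sequence_bundle <- function(x, ...) {
  cat(sprintf(paste0("<paired_sequence_bundle: %d frames, face %dx%d, ",
                     "tract %dx%d, k_shared=%d, k_priv_a=%d, k_priv_b=%d>\n"),
              x$latents$n_frames,
              x$spec$face_shape[1L], x$spec$face_shape[2L],
              x$spec$tract_shape[1L], x$spec$tract_shape[2L],
              x$spec$k_shared, x$spec$k_priv_a, x$spec$k_priv_b))
  invisible(x)
}
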