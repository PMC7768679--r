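# Sequence I/O, configuration and the end-to-end pipeline.
#
# Numbered-PNG frame directories are the canonical lossless interchange
# format (8-bit per channel; integer 0-255 intensities round-trip exactly).
# Bundle sidecars (scene spec, seeds) are YAML; pipeline reports are JSON.

#' Read an image sequence from a directory of numbered PNG frames
#'
#' Frames are ordered by the number embedded in their file names (falling
#' back to lexicographic order). Grayscale frames are promoted to three
#' equal RGB channels; intensities are returned on the 0-255 scale.
#'
#' @param path directory containing `*.png` frames.
#' @return H x W x C x n sequence array.
#' @export
read_sequence <- function(path) {
  if (!dir.exists(path)) stop("not a readable directory: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) stop("no PNG frames found in ", path, call. = FALSE)
  nums <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  files <- if (anyNA(nums)) sort(files) else files[order(nums)]
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f) * 255
    if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(img)[3L] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
    img
  })
  geo <- lapply(frames, dim)
  if (length(unique(vapply(geo, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent frame geometry in ", path, call. = FALSE)
  image_seq(frames)
}

#' Write an image sequence as numbered PNG frames
#'
#' Intensities are clamped to \[0, 255\] and quantized to 8 bits; integer
#' inputs round-trip exactly through [read_sequence()].
#'
#' @param seq H x W x C x n array (or matrix sequence).
#' @param path output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_sequence <- function(seq, path, prefix = "frame") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(seq)
  files <- file.path(path, sprintf("%s_%04d.png", prefix, seq_len(n)))
  for (j in seq_len(n)) {
    img <- get_frame(seq, j)
    png::writePNG(pmin(pmax(img, 0), 255) / 255, files[j])
  }
  invisible(files)
}

#' Write a synthetic bundle to disk
#'
#' One PNG frame directory per modality, region masks as PNG, and a YAML
#' sidecar with the scene parameters and seeds.
#'
#' @param bundle a [render_paired_sequences()] bundle.
#' @param path output directory.
#' @return invisibly, `path`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "paired_sequence_bundle"))
  write_sequence(bundle$seq_a, file.path(path, "face"))
  write_sequence(bundle$seq_b, file.path(path, "tract"))
  for (mod in names(bundle$region_masks)) {
    mdir <- file.path(path, paste0("masks_", mod))
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle$region_masks[[mod]]))
      png::writePNG(bundle$region_masks[[mod]][[nm]] * 1,
                    file.path(mdir, paste0(nm, ".png")))
  }
  spec <- bundle$spec
  side <- list(
    k_shared = spec$k_shared, k_priv_a = spec$k_priv_a,
    k_priv_b = spec$k_priv_b,
    face_shape = spec$face_shape, tract_shape = spec$tract_shape,
    noise_sd = spec$noise_sd, region_radius = spec$region_radius,
    blob_sd = spec$blob_sd, amp_base = spec$amp_base,
    amp_gain = spec$amp_gain, pos_gain = spec$pos_gain,
    scene_seed = spec$seed, latent_seed = bundle$latents$seed,
    smoothness = bundle$latents$smoothness,
    n_frames = bundle$latents$n_frames)
  yaml::write_yaml(side, file.path(path, "bundle.yaml"))
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Each stochastic stage derives
#' its seed deterministically from the master `seed`, so identical configs
#' give identical results.
#'
#' @param n_frames frames to simulate.
#' @param k_shared,k_priv_a,k_priv_b latent channel counts.
#' @param smoothness latent AR(1) coefficient.
#' @param noise_sd rendering noise SD.
#' @param face_shape,tract_shape geometries.
#' @param centered centered PCA?
#' @param paired use paired-frame samples for the main reconstruction?
#' @param permutation `NULL` or list with `n_perm` and `mode`.
#' @param bubbles `NULL` or list with `occluded_modality`, `n_iter`,
#'   `n_bubbles`, `diameter`, `top_frac`, `per_frame`.
#' @param n_iterations reference-selection iterations.
#' @param seed master seed.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_frames = 40L, k_shared = 2L, k_priv_a = 1L,
                            k_priv_b = 1L, smoothness = 0.85, noise_sd = 1,
                            face_shape = c(120L, 160L),
                            tract_shape = c(120L, 160L),
                            centered = FALSE, paired = FALSE,
                            permutation = NULL, bubbles = NULL,
                            n_iterations = 3L, seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), k_shared = as.integer(k_shared),
              k_priv_a = as.integer(k_priv_a), k_priv_b = as.integer(k_priv_b),
              smoothness = smoothness, noise_sd = noise_sd,
              face_shape = as.integer(face_shape),
              tract_shape = as.integer(tract_shape),
              centered = isTRUE(centered), paired = isTRUE(paired),
              permutation = permutation, bubbles = bubbles,
              n_iterations = as.integer(n_iterations), seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stage seeds derived from the master seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, reference_a = 2L, reference_b = 3L,
            permutation = 4L, bubbles = 5L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

#' Run the end-to-end pipeline
#'
#' simulate -> reference selection per modality -> warping -> hybrid ->
#' PCA -> reconstruction in both directions -> optional permutation test and
#' Bubbles analysis. A machine-readable report of the fidelity metrics and
#' seeds is written when `out_dir` is given.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param out_dir optional output directory for `report.json`.
#' @param verbose log each stage?
#' @return list with `report` (plain metric list), `bundle`, `refsel`,
#'   `hybrid`, `model`, `recon_mr`, `recon_video`, `permutation`, `bubbles`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[facetract] ", ...)

  say("simulate")
  spec <- scene_spec(k_shared = config$k_shared, k_priv_a = config$k_priv_a,
                     k_priv_b = config$k_priv_b,
                     face_shape = config$face_shape,
                     tract_shape = config$tract_shape,
                     noise_sd = config$noise_sd,
                     seed = stage_seed(config$seed, "simulate"))
  lat <- generate_latents(config$n_frames, config$k_shared, config$k_priv_a,
                          config$k_priv_b, config$smoothness,
                          seed = config$seed)
  bundle <- render_paired_sequences(spec, lat)

  say("reference selection + warping")
  rs_a <- select_reference(bundle$seq_a, config$n_iterations,
                           seed = stage_seed(config$seed, "reference_a"))
  rs_b <- select_reference(bundle$seq_b, config$n_iterations,
                           seed = stage_seed(config$seed, "reference_b"))
  video <- list(seq = bundle$seq_a, fields = rs_a$fields)
  mr <- list(seq = bundle$seq_b, fields = rs_b$fields)

  say("hybrid + PCA")
  plan <- match_frames(config$n_frames, config$n_frames)
  h <- build_hybrid(video, mr, plan)
  if (config$paired) h <- build_paired(h)
  model <- fit_pca(h, centered = config$centered)

  say("reconstruction")
  recon_mr <- reconstruct_modality(model, h, zeroed = "mr")
  recon_video <- reconstruct_modality(model, h, zeroed = "video")
  fm_mr <- fidelity_metrics(model, recon_mr)
  fm_video <- fidelity_metrics(model, recon_video)

  perm <- NULL
  if (!is.null(config$permutation)) {
    say("permutation test")
    pc <- config$permutation
    perm <- permutation_test(video, mr, plan,
                             n_perm = pc$n_perm %||% 1000L,
                             mode = pc$mode %||% "single",
                             seed = stage_seed(config$seed, "permutation"))
  }
  bub <- NULL
  if (!is.null(config$bubbles)) {
    say("bubbles analysis")
    bc <- config$bubbles
    if (config$paired || config$centered)
      stop("bubbles stage runs on the single-frame uncentered model", call. = FALSE)
    bub <- bubbles_analysis(model, h,
                            occluded_modality = bc$occluded_modality %||% "video",
                            n_iter = bc$n_iter %||% 1000L,
                            n_bubbles = bc$n_bubbles %||% 46L,
                            diameter = bc$diameter %||% 12L,
                            top_frac = bc$top_frac %||% 0.1,
                            seed = stage_seed(config$seed, "bubbles"),
                            per_frame = isTRUE(bc$per_frame))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("facetract")),
    seed = config$seed,
    n_frames = config$n_frames,
    paired = config$paired,
    centered = config$centered,
    loading_correlation_mr_recon = fm_mr$loading_correlation,
    loading_correlation_video_recon = fm_video$loading_correlation,
    loading_sse_mr_recon = fm_mr$loading_sse,
    loading_sse_video_recon = fm_video$loading_sse)
  if (!is.null(perm)) {
    report$permutation <- list(
      mode = perm$mode, n_perm = perm$n_perm,
      observed_r = perm$observed$r,
      null_values = perm$null_r,
      null_mean = perm$null_mean, null_ci95 = perm$null_ci95,
      p_value_correlation = perm$p_value_correlation,
      p_value_sse = perm$p_value_sse)
  }
  if (!is.null(bub)) {
    report$bubbles <- list(
      occluded_modality = bub$occluded_modality, n_iter = bub$n_iter,
      plane_max = max(bub$plane$plane, na.rm = TRUE),
      plane_mean = mean(bub$plane$plane, na.rm = TRUE))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(report = report, bundle = bundle,
                 refsel = list(video = rs_a, mr = rs_b), hybrid = h,
                 model = model, recon_mr = recon_mr,
                 recon_video = recon_video, permutation = perm,
                 bubbles = bub))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
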