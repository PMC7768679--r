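test_that("frame matching reproduces the worked example and rounds halves away from zero", {
  p <- match_frames(9, 6)
  expect_equal(p$scale_factor, 1.5)
  expect_equal(p$retained_indices, c(1L, 3L, 4L, 6L, 7L, 9L))

  expect_equal(match_frames(5, 5)$retained_indices, 1:5)
  # scale 2.5: raw indices 1, 3.5, 6, 8.5 -> half away from zero
  expect_equal(match_frames(10, 4)$retained_indices, c(1L, 4L, 6L, 9L))

  expect_error(match_frames(6, 9), "n_mr")
  expect_error(match_frames(0, 0), "positive")
})

test_that("frame matching invariants hold over a grid of frame counts", {
  for (n_vid in c(5L, 9L, 16L, 25L, 40L, 100L)) {
    for (n_mr in unique(pmin(n_vid, c(1L, 2L, 5L, 13L, n_vid)))) {
      p <- match_frames(n_vid, n_mr)
      idx <- p$retained_indices
      expect_length(idx, n_mr)
      expect_equal(idx[1], 1L)
      expect_true(all(diff(idx) > 0))
      expect_lte(max(idx), n_vid)
    }
  }
})

test_that("frame serialization follows the documented layout and round-trips", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)         # column-major: 1 2 3 4
  f <- warp_field(matrix(c(5, 6, 7, 8), 2, 2), matrix(c(9, 10, 11, 12), 2, 2))
  v <- serialize_frame(img, f)
  expect_equal(v, as.numeric(1:12))

  zero <- serialize_frame(array(0, dim = c(3, 4, 3)),
                          warp_field(matrix(0, 3, 4), matrix(0, 3, 4)))
  expect_equal(zero, rep(0, 5 * 3 * 4))

  set.seed(1)
  rgb <- array(runif(4 * 5 * 3, 0, 255), dim = c(4, 5, 3))
  fld <- warp_field(matrix(rnorm(20), 4, 5), matrix(rnorm(20), 4, 5))
  back <- deserialize_frame(serialize_frame(rgb, fld),
                            list(height = 4L, width = 5L, channels = 3L))
  expect_equal(back$image, rgb)
  expect_equal(back$field$dx, fld$dx)
  expect_equal(back$field$dy, fld$dy)

  expect_error(serialize_frame(matrix(0, 2, 2),
                               warp_field(matrix(0, 3, 3), matrix(0, 3, 3))),
               "geometry")
})

test_that("build_hybrid stacks blocks video-first and honors weights", {
  vid <- tiny_modality(c(1, 2, 3))
  mr <- tiny_modality(c(1, 2, 3))
  h <- build_hybrid(vid, mr)
  # 1x1 RGB frame serializes to 5 rows per modality -> 10 x 3
  expect_equal(dim(h$data), c(10L, 3L))
  expect_equal(h$data[1:5, ], h$data[6:10, ])
  expect_equal(h$data[1, ], c(1, 2, 3))

  hz <- build_hybrid(vid, mr, channel_weights = list(mr = 0))
  expect_equal(max(abs(hz$data[block_rows(hz, "mr"), ])), 0)

  expect_error(build_hybrid(vid, tiny_modality(c(1, 2))), "matching frame counts")
})

test_that("the plan decimates the video modality before stacking", {
  vid <- tiny_modality(1:9)
  mr <- tiny_modality(101:106)
  p <- match_frames(9, 6)
  h <- build_hybrid(vid, mr, p)
  expect_equal(h$n_frames, 6L)
  expect_equal(h$data[1, ], c(1, 3, 4, 6, 7, 9))
  expect_equal(h$data[6, ], as.numeric(101:106))
})

test_that("block map ranges recover the original images through deserialization", {
  b <- small_bundle(n_frames = 4, seed = 13)
  vid <- list(seq = b$seq_a, fields = zero_fields(b$seq_a))
  mr <- list(seq = b$seq_b, fields = zero_fields(b$seq_b))
  h <- build_hybrid(vid, mr, channel_weights = list(video = c(pixel = 2, warp = 1)))
  out <- deserialize_hybrid(h$data, h$block_map)
  expect_equal(out$video$images, b$seq_a)
  expect_equal(out$mr$images, b$seq_b)
  expect_equal(max(abs(out$video$dx)), 0)
})

test_that("paired-frame stacking doubles rows, drops one sample, and unstacks exactly", {
  vid <- tiny_modality(c(1, 2, 3))
  mr <- tiny_modality(c(4, 5, 6))
  h <- build_hybrid(vid, mr)
  ph <- build_paired(h)
  expect_equal(dim(ph$data), c(20L, 2L))
  expect_equal(nrow(ph$data), 2L * nrow(h$data))
  for (j in 1:2) {
    u <- unstack_paired(ph, j)
    expect_equal(u[, 1], h$data[, j])
    expect_equal(u[, 2], h$data[, j + 1])
  }

  hconst <- build_hybrid(tiny_modality(c(2, 2, 2)), tiny_modality(c(3, 3, 3)))
  pconst <- build_paired(hconst)
  expect_equal(pconst$data[, 1], pconst$data[, 2])

  h1 <- build_hybrid(tiny_modality(1), tiny_modality(2))
  expect_error(build_paired(h1), "at least 2")
})
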