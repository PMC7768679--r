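test_that("bubble masks are seeded discs with the exact membership rule", {
  m1 <- generate_mask(40, 50, n_bubbles = 10, diameter = 12, seed = 9)
  m2 <- generate_mask(40, 50, n_bubbles = 10, diameter = 12, seed = 9)
  expect_identical(m1$mask, m2$mask)
  expect_equal(dim(m1$mask), c(40L, 50L))

  # saturation: one disc wider than the diagonal covers everything
  big <- generate_mask(20, 30, n_bubbles = 1, diameter = 80, seed = 1)
  expect_true(all(big$mask))

  # single interior disc: pixel count equals the brute-force count
  one <- generate_mask(40, 50, n_bubbles = 1, diameter = 12, seed = 2)
  ctr <- one$centers[1, ]
  rr <- matrix(seq_len(40), 40, 50)
  cc <- matrix(seq_len(50), 40, 50, byrow = TRUE)
  brute <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= 6^2
  expect_identical(one$mask, brute)
  expect_equal(sum(one$mask), sum(brute))

  expect_error(generate_mask(0, 10), "positive")
})

test_that("mask coverage grows with the number of bubbles", {
  cov <- vapply(c(5, 15, 46, 100), function(nb) {
    mean(vapply(1:20, function(s)
      mean(generate_mask(60, 80, n_bubbles = nb, diameter = 12,
                         seed = s)$mask), 0))
  }, 0)
  expect_true(all(diff(cov) > 0))
})

test_that("an all-true mask reproduces the unoccluded cross-modal reconstruction", {
  b <- small_bundle(n_frames = 6, seed = 61)
  vid <- list(seq = b$seq_a, fields = zero_fields(b$seq_a))
  mr <- list(seq = b$seq_b, fields = zero_fields(b$seq_b))
  h <- build_hybrid(vid, mr)
  m <- fit_pca(h)
  full <- matrix(TRUE, 48, 64)
  occ <- occlude_and_reconstruct(m, h, full, "video")
  ref <- reconstruct_modality(m, h, "mr")
  expect_equal(occ$recon_loadings, ref$recon_loadings, tolerance = 1e-10)
  expect_equal(occ$loading_correlation,
               loading_correlation(m$loadings, ref$recon_loadings),
               tolerance = 1e-10)

  none <- occlude_and_reconstruct(m, h, matrix(FALSE, 48, 64), "video")
  expect_equal(max(abs(none$recon_loadings)), 0)
  expect_true(is.na(none$loading_correlation))

  expect_error(occlude_and_reconstruct(m, h, matrix(TRUE, 10, 10), "video"),
               "geometry")
})

test_that("a mask over the informative region beats a same-area mask elsewhere", {
  b <- small_bundle(n_frames = 12, k_shared = 1, k_priv_a = 0, k_priv_b = 0,
                    noise_sd = 0.5, seed = 62)
  vid <- list(seq = b$seq_a, fields = zero_fields(b$seq_a))
  mr <- list(seq = b$seq_b, fields = zero_fields(b$seq_b))
  h <- build_hybrid(vid, mr)
  m <- fit_pca(h)
  informative <- b$region_masks$a$shared1
  # same-shape mask translated into quiet background
  elsewhere <- matrix(FALSE, 48, 64)
  shift <- which(informative, arr.ind = TRUE)
  shift[, 2] <- shift[, 2] - min(shift[, 2]) + 2L
  shift[, 1] <- shift[, 1] - min(shift[, 1]) + 2L
  elsewhere[shift] <- TRUE
  sse_inf <- occlude_and_reconstruct(m, h, informative, "video")$loading_sse
  sse_els <- occlude_and_reconstruct(m, h, elsewhere, "video")$loading_sse
  expect_lt(sse_inf, sse_els)
})

test_that("proportion plane selects the lowest-SSE masks", {
  # 10 disjoint single-disc masks, SSEs 1..10, top 10% -> only mask 1 counts
  masks <- lapply(1:10, function(i) {
    m <- matrix(FALSE, 20, 100)
    m[8:12, (i - 1) * 10 + 3:7] <- TRUE
    m
  })
  pp <- proportion_plane(masks, sses = 1:10, top_frac = 0.1)
  expect_equal(pp$plane[10, 5], 1)
  expect_equal(pp$plane[10, 15], 0)
  expect_true(all(is.na(pp$plane[1, ])))
  expect_true(all(pp$plane >= 0 & pp$plane <= 1, na.rm = TRUE))

  # all masks identical: plane = top_frac on covered pixels
  same <- lapply(1:20, function(i) masks[[3]])
  pp2 <- proportion_plane(same, sses = rnorm(20), top_frac = 0.1)
  expect_equal(unique(pp2$plane[!is.na(pp2$plane)]), 0.1)

  # ties at the boundary are broken by iteration index
  pp3 <- proportion_plane(masks, sses = rep(1, 10), top_frac = 0.1)
  expect_equal(pp3$plane[10, 5], 1)   # iteration 1 wins the tie
  expect_equal(pp3$plane[10, 15], 0)

  expect_error(proportion_plane(masks, 1:9), "lengths differ")
  expect_error(proportion_plane(masks[1:5], 1:5), "at least 10")
})

test_that("per-frame planes re-rank per frame and broadly agree with the sequence plane", {
  masks <- lapply(1:20, function(i)
    generate_mask(30, 40, n_bubbles = 8, diameter = 10, seed = i)$mask)
  set.seed(1)
  pf_sse <- matrix(runif(20 * 3), 20, 3)
  pp <- proportion_plane(masks, pf_sse, top_frac = 0.2)
  expect_equal(dim(pp$plane), c(30L, 40L, 3L))
  for (f in 1:3) {
    direct <- proportion_plane(masks, pf_sse[, f], top_frac = 0.2)
    expect_equal(pp$plane[, , f], direct$plane)
  }
})

test_that("bubbles analysis localizes the shared-cause region on synthetic data", {
  b <- small_bundle(n_frames = 15, k_shared = 1, k_priv_a = 0, k_priv_b = 0,
                    noise_sd = 0.5, seed = 63)
  vid <- list(seq = b$seq_a, fields = zero_fields(b$seq_a))
  mr <- list(seq = b$seq_b, fields = zero_fields(b$seq_b))
  h <- build_hybrid(vid, mr)
  m <- fit_pca(h)
  ba <- bubbles_analysis(m, h, "video", n_iter = 150, n_bubbles = 20,
                         diameter = 10, seed = 7)
  plane <- ba$plane$plane
  region <- b$region_masks$a$shared1
  expect_gt(mean(plane[region], na.rm = TRUE),
            mean(plane[!region], na.rm = TRUE))
  # plane is a proportion everywhere it is defined
  expect_true(all(plane >= 0 & plane <= 1, na.rm = TRUE))
  # determinism
  ba2 <- bubbles_analysis(m, h, "video", n_iter = 150, n_bubbles = 20,
                          diameter = 10, seed = 7)
  expect_identical(ba$sse, ba2$sse)
})

test_that("uninformative pixels are selected at roughly the top fraction rate", {
  # with SSEs independent of the masks, every pixel is uninformative
  masks <- lapply(1:400, function(i)
    generate_mask(25, 30, n_bubbles = 6, diameter = 8, seed = i)$mask)
  set.seed(2)
  pp <- proportion_plane(masks, sses = rnorm(400), top_frac = 0.1)
  vals <- pp$plane[pp$total_plane >= 20]
  expect_lt(abs(mean(vals) - 0.1), 0.03)
})
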