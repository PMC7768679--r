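test_that("fit_pca matches an independent singular value decomposition up to sign", {
  set.seed(10)
  for (dims in list(c(50, 6), c(200, 12))) {
    x <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    m <- fit_pca(x)
    sv <- svd(x)                                   # independent oracle
    expect_equal(m$sdev, sv$d, tolerance = 1e-8)
    for (k in seq_along(sv$d)) {
      # same subspace direction up to sign
      expect_equal(abs(sum(m$components[, k] * sv$u[, k])), 1, tolerance = 1e-8)
      s <- sign(sum(m$components[, k] * sv$u[, k]))
      expect_equal(m$loadings[, k], s * sv$d[k] * sv$v[, k], tolerance = 1e-8)
    }
    expect_equal(max(abs(crossprod(m$components) - diag(ncol(m$components)))),
                 0, tolerance = 1e-8)
  }
})

test_that("rank-1 data yields one component and exact reconstruction", {
  pattern <- c(3, 1, 4, 1, 5)
  x <- outer(pattern, c(1, 2, 0.5, -1))
  m <- fit_pca(x)
  expect_equal(length(m$sdev), 1L)
  xr <- m$components %*% t(m$loadings)
  expect_equal(xr, x, tolerance = 1e-10)
})

test_that("full projection of the training data is the identity", {
  set.seed(2)
  x <- matrix(runif(300 * 8, 0, 255), 300, 8)
  m <- fit_pca(x)
  l <- project(m, x)
  expect_equal(l, unclass(m$loadings), tolerance = 1e-8, ignore_attr = TRUE)
  xr <- m$components %*% t(l)
  expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
})

test_that("projection behaves on zero columns and on the components themselves", {
  set.seed(3)
  x <- matrix(rnorm(100 * 5), 100, 5)
  m <- fit_pca(x)
  expect_equal(as.vector(project(m, rep(0, 100))), rep(0, length(m$sdev)))
  lk <- project(m, m$components[, 2])
  expect_equal(as.vector(lk), as.numeric(seq_along(m$sdev) == 2), tolerance = 1e-8)
  expect_error(project(m, rep(0, 99)), "dimension")
  expect_error(fit_pca(matrix(1, 5, 1)), "2 samples")
})

test_that("reconstructed loadings from the two zeroed projections sum to the originals", {
  set.seed(4)
  for (rep in 1:3) {
    vid <- tiny_modality(runif(6, 0, 255), dx = rnorm(6), dy = rnorm(6))
    mr <- tiny_modality(runif(6, 0, 255), dx = rnorm(6), dy = rnorm(6))
    h <- build_hybrid(vid, mr)
    # pad with extra structure: weight video pixels to mix units
    m <- fit_pca(h)
    ra <- reconstruct_modality(m, h, "video")
    rb <- reconstruct_modality(m, h, "mr")
    expect_equal(ra$recon_loadings + rb$recon_loadings, unclass(m$loadings),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a hybrid whose MR block duplicates the video block splits loadings in half", {
  vals <- c(10, 40, 25, 60)
  vid <- tiny_modality(vals, dx = vals / 10)
  mr <- tiny_modality(vals, dx = vals / 10)
  h <- build_hybrid(vid, mr)
  m <- fit_pca(h)
  r <- reconstruct_modality(m, h, "mr")
  expect_equal(r$recon_loadings, unclass(m$loadings) / 2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(loading_correlation(m$loadings, r$recon_loadings), 1,
               tolerance = 1e-10)
})

test_that("centering breaks exact additivity but reconstructs the training data", {
  b <- small_bundle(n_frames = 6, seed = 31)
  vid <- list(seq = b$seq_a, fields = zero_fields(b$seq_a))
  mr <- list(seq = b$seq_b, fields = zero_fields(b$seq_b))
  h <- build_hybrid(vid, mr)
  mc <- fit_pca(h, centered = TRUE)
  xr <- mc$components %*% t(project(mc, h$data)) + mc$mean_vector
  expect_lt(max(abs(xr - h$data)) / max(abs(h$data)), 1e-8)
  ra <- reconstruct_modality(mc, h, "video")
  rb <- reconstruct_modality(mc, h, "mr")
  expect_gt(max(abs(ra$recon_loadings + rb$recon_loadings - mc$loadings)), 1e-6)
})

test_that("mean scaling rescales reconstructed loadings by the mean original/recon ratio", {
  vid <- tiny_modality(c(10, 40, 25, 60), dx = c(1, 2, 3, 4))
  mr <- tiny_modality(c(12, 38, 30, 55), dx = c(2, 1, 4, 3))
  h <- build_hybrid(vid, mr)
  m <- fit_pca(h)
  r0 <- reconstruct_modality(m, h, "mr")
  r1 <- reconstruct_modality(m, h, "mr", apply_mean_scaling = TRUE)
  ok <- abs(r0$recon_loadings) > 1e-12
  sf <- mean(m$loadings[ok] / r0$recon_loadings[ok])
  expect_equal(r1$scaling_factor, sf)
  expect_equal(r1$recon_loadings, r0$recon_loadings * sf)
  # correlation is invariant to the common positive rescaling
  if (sf > 0)
    expect_equal(loading_correlation(m$loadings, r1$recon_loadings),
                 loading_correlation(m$loadings, r0$recon_loadings))
})

test_that("loading correlation follows the textbook Pearson formula", {
  expect_equal(loading_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(loading_correlation(c(1, 2, 3, 4), 0.5 * c(1, 2, 3, 4)), 1)
  o <- c(1, 2, 3, 4); r <- c(1.1, 1.9, 3.2, 3.9)
  pearson <- sum((o - mean(o)) * (r - mean(r))) /
    sqrt(sum((o - mean(o))^2) * sum((r - mean(r))^2))
  expect_equal(loading_correlation(o, r), pearson)
  expect_error(loading_correlation(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(loading_correlation(1:4, 1:5), "shape")
})

test_that("loading SSE sums squared differences with a per-sample breakdown", {
  expect_equal(loading_sse(c(1, 2), c(1, 2))$total, 0)
  expect_equal(loading_sse(c(1, 2), c(0, 0))$total, 5)
  set.seed(6)
  o <- matrix(rnorm(8 * 3), 8, 3); r <- matrix(rnorm(8 * 3), 8, 3)
  s <- loading_sse(o, r)
  expect_equal(sum(s$per_sample), s$total, tolerance = 1e-10)
  expect_length(s$per_sample, 8)
})

test_that("reconstruction deserializes into images and fields in the component span", {
  b <- small_bundle(n_frames = 5, seed = 41)
  mods <- list(video = list(seq = b$seq_a, fields = zero_fields(b$seq_a)),
               mr = list(seq = b$seq_b, fields = zero_fields(b$seq_b)))
  h <- build_hybrid(mods$video, mods$mr)
  m <- fit_pca(h)
  r <- reconstruct_modality(m, h, "mr")
  expect_equal(dim(r$modalities$mr$images), dim(b$seq_b))
  # recon vectors lie in the span: projecting then re-forming is a no-op
  rp <- m$components %*% t(project(m, r$recon_vectors))
  expect_equal(rp, r$recon_vectors, tolerance = 1e-8)
  expect_error(reconstruct_modality(m, h, "audio"), "unknown modality")
})
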