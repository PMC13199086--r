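test_that("body mask recovers a bright ellipsoid as one component", {
  d <- c(32, 32, 20)
  a <- array(0, d)
  cs <- (d + 1) / 2
  idx <- which(a == 0, arr.ind = TRUE)
  inside <- ((idx[, 1] - cs[1]) / 10)^2 + ((idx[, 2] - cs[2]) / 10)^2 +
    ((idx[, 3] - cs[3]) / 6)^2 <= 1
  a[idx[inside, ]] <- 1
  v <- volume_grid(a)
  bm <- compute_body_mask(v)
  expect_identical(bm$data, a == 1)
  lab <- vesseltrace:::label_components(bm$data)
  expect_equal(max(lab), 1)
})

test_that("body mask keeps only the largest of two blobs", {
  a <- array(0, c(40, 20, 10))
  a[2:11, 2:11, 2:6] <- 1          # 500 voxels
  a[30:34, 10:13, 3:4] <- 1        # 40 voxels
  bm <- compute_body_mask(volume_grid(a),
                          preprocess_params(close_radius_vox = 0L))
  expect_equal(sum(bm$data), 500)
  expect_true(all(bm$data[2:11, 2:11, 2:6]))
})

test_that("body mask rejects constant volumes", {
  expect_error(compute_body_mask(volume_grid(array(3, c(5, 5, 5)))),
               "constant")
})

test_that("robust normalization maps percentile anchors to [0,1]", {
  d <- c(101, 1, 1)
  a <- array(0:100, d)
  mask <- binary_mask(array(TRUE, d))
  out <- normalize_within_mask(volume_grid(a), mask,
                               preprocess_params(robust_percentiles = c(0, 100)))
  expect_equal(out$data[51, 1, 1], 0.5)
  expect_equal(range(out$data), c(0, 1))

  # outliers clip; bulk maps into the interior (direct percentile oracle)
  vals <- c(rep(10, 98), 0, 1000)
  d2 <- c(100, 1, 1)
  a2 <- array(vals, d2)
  m2 <- binary_mask(array(TRUE, d2))
  pr <- preprocess_params(robust_percentiles = c(1, 99))
  q <- stats::quantile(vals, c(0.01, 0.99), names = FALSE)
  out2 <- normalize_within_mask(volume_grid(a2), m2, pr)
  expect_equal(out2$data[100, 1, 1], 1)               # 1000 clips to 1
  expect_equal(out2$data[1, 1, 1],
               min(max((10 - q[1]) / (q[2] - q[1]), 0), 1))
  expect_true(out2$data[1, 1, 1] > 0 && out2$data[1, 1, 1] < 1)
})

test_that("normalization zeroes outside the mask and rejects flat input", {
  a <- array(runif(4^3), c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[1:2, , ] <- TRUE
  out <- normalize_within_mask(volume_grid(a), binary_mask(m))
  expect_true(all(out$data[!m] == 0))
  expect_true(all(out$data >= 0 & out$data <= 1))
  flat <- volume_grid(array(5, c(4, 4, 4)))
  expect_error(normalize_within_mask(flat, binary_mask(m)), "degenerate")
})

test_that("Gaussian denoising preserves constants and kernel mass", {
  cv <- volume_grid(array(2.5, c(10, 10, 10)))
  expect_equal(gaussian_denoise(cv)$data, cv$data, tolerance = 1e-9)

  d <- c(21, 21, 21)
  imp <- array(0, d); imp[11, 11, 11] <- 1
  out <- gaussian_denoise(volume_grid(imp, spacing = c(1, 1, 1)),
                          preprocess_params(denoise_sigma_mm = 1.5))
  expect_equal(sum(out$data), 1, tolerance = 1e-3)
  expect_equal(which.max(out$data), which.max(imp))
})

test_that("denoising converts physical sigma to per-axis voxel sigmas", {
  d <- c(15, 15, 15)
  imp <- array(0, d); imp[8, 8, 8] <- 1
  v <- volume_grid(imp, spacing = c(0.1, 0.1, 0.5))
  out <- gaussian_denoise(v, preprocess_params(denoise_sigma_mm = 0.2))
  manual <- vesseltrace:::gauss_smooth3(imp, c(2, 2, 0.4))
  expect_equal(out$data, manual, tolerance = 1e-12)
})

test_that("denoising never widens the value range and keeps the mean", {
  set.seed(11)
  a <- array(runif(16^3), c(16, 16, 16))
  out <- gaussian_denoise(volume_grid(a),
                          preprocess_params(denoise_sigma_mm = 0.24))
  expect_gte(min(out$data), min(a))
  expect_lte(max(out$data), max(a))
  expect_equal(mean(out$data), mean(a), tolerance = 0.005 * mean(a))
})

test_that("per-slice normalization equalizes qualifying slice medians", {
  d <- c(10, 10, 2)
  a <- array(0, d)
  a[, , 1] <- 2; a[, , 2] <- 4
  m <- binary_mask(array(TRUE, d))
  out <- per_slice_normalize(volume_grid(a), m,
                             preprocess_params(min_slice_mask_voxels = 1L))
  expect_equal(median(out$data[, , 1]), 3)
  expect_equal(median(out$data[, , 2]), 3)

  # already homogeneous input passes through unchanged
  b <- array(rep(c(1, 2, 3), length.out = prod(d)), d)
  outb <- per_slice_normalize(volume_grid(b), m,
                              preprocess_params(min_slice_mask_voxels = 1L))
  expect_equal(outb$data, b, tolerance = 1e-6)
})

test_that("sparsely masked slices are exempt from per-slice scaling", {
  d <- c(10, 10, 3)
  a <- array(1, d); a[, , 2] <- 7
  m <- array(TRUE, d)
  m[, , 2] <- FALSE; m[1:2, 1:5, 2] <- TRUE   # 10 mask voxels < 50
  out <- per_slice_normalize(volume_grid(a), binary_mask(m),
                             preprocess_params(min_slice_mask_voxels = 50L))
  expect_equal(out$data[, , 2], a[, , 2])
  zvol <- array(rep(c(0, 1), each = 100), c(10, 10, 2))  # slice 1 all-zero
  expect_error(
    per_slice_normalize(volume_grid(zvol),
                        binary_mask(array(TRUE, c(10, 10, 2))),
                        preprocess_params(min_slice_mask_voxels = 1L)),
    "zero within-mask median")
})

test_that("body masks have no interior holes", {
  a <- array(0, c(20, 20, 20))
  a[5:15, 5:15, 5:15] <- 1
  a[10, 10, 10] <- 0   # interior hole
  bm <- compute_body_mask(volume_grid(a))
  expect_true(bm$data[10, 10, 10])
})
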