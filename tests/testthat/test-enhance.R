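full_mask <- function(d, sp = c(1, 1, 1)) binary_mask(array(TRUE, d), sp)

test_that("vesselness is zero on constant volumes", {
  d <- c(16, 16, 16)
  v <- volume_grid(array(0.5, d))
  out <- vesselness(v, full_mask(d), vesselness_params(scales_mm = c(1, 2)))
  expect_true(all(out$data == 0))
})

test_that("bright cylinders outscore equal-contrast plates; dark tubes gate to zero", {
  d <- c(21, 21, 40)
  sp <- c(1, 1, 1)
  pars <- vesselness_params(scales_mm = c(1, 2, 3))
  tube <- gaussian_denoise(volume_grid(make_tube(d, radius = 2), sp),
                           preprocess_params(denoise_sigma_mm = 0.8))
  plate <- gaussian_denoise(volume_grid(make_plate(d), sp),
                            preprocess_params(denoise_sigma_mm = 0.8))
  vt <- vesselness(tube, full_mask(d, sp), pars)
  vp <- vesselness(plate, full_mask(d, sp), pars)
  axis_resp <- mean(vt$data[11, 11, 10:30])
  plate_resp <- mean(vp$data[5:17, 5:17, 20])
  expect_gt(axis_resp, plate_resp)
  expect_gt(axis_resp, 0.1)

  # oracle: finite-difference Hessian eigenvalues at probe voxels show the
  # tube signature (two strongly negative, one near-zero eigenvalue) and a
  # plate signature (one dominant negative eigenvalue)
  probe_eigs <- function(arr, x, y, z) {
    sm <- vesseltrace:::gauss_smooth3(arr, c(2, 2, 2))
    H <- matrix(0, 3, 3)
    step <- function(dx, dy, dz) sm[x + dx, y + dy, z + dz]
    H[1, 1] <- step(1, 0, 0) - 2 * step(0, 0, 0) + step(-1, 0, 0)
    H[2, 2] <- step(0, 1, 0) - 2 * step(0, 0, 0) + step(0, -1, 0)
    H[3, 3] <- step(0, 0, 1) - 2 * step(0, 0, 0) + step(0, 0, -1)
    H[1, 2] <- H[2, 1] <- (step(1, 1, 0) - step(1, -1, 0) -
                           step(-1, 1, 0) + step(-1, -1, 0)) / 4
    H[1, 3] <- H[3, 1] <- (step(1, 0, 1) - step(1, 0, -1) -
                           step(-1, 0, 1) + step(-1, 0, -1)) / 4
    H[2, 3] <- H[3, 2] <- (step(0, 1, 1) - step(0, 1, -1) -
                           step(0, -1, 1) + step(0, -1, -1)) / 4
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ev[order(abs(ev))]
  }
  et <- probe_eigs(tube$data, 11, 11, 20)
  expect_lt(et[2], 0); expect_lt(et[3], 0)
  expect_gt(abs(et[2]) / abs(et[3]), 0.5)         # cross-section isotropy
  ep <- probe_eigs(plate$data, 11, 11, 20)
  expect_lt(abs(ep[2]) / abs(ep[3]), 0.3)         # plate: lambda2 << lambda3

  dark <- gaussian_denoise(volume_grid(1 - make_tube(d, radius = 2), sp),
                           preprocess_params(denoise_sigma_mm = 0.8))
  vd <- vesselness(dark, full_mask(d, sp), pars)
  expect_true(all(vd$data[11, 11, 10:30] == 0))
})

test_that("analytic eigensolver matches LAPACK on random symmetric matrices", {
  set.seed(3)
  n <- 200
  xx <- rnorm(n); yy <- rnorm(n); zz <- rnorm(n)
  xy <- rnorm(n); xz <- rnorm(n); yz <- rnorm(n)
  mine <- vesseltrace:::eig_sym3_cpp(xx, yy, zz, xy, xz, yz)
  for (i in seq_len(n)) {
    H <- matrix(c(xx[i], xy[i], xz[i], xy[i], yy[i], yz[i],
                  xz[i], yz[i], zz[i]), 3, 3)
    ref <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ref <- ref[order(abs(ref))]
    expect_equal(as.vector(mine[i, ]), ref, tolerance = 1e-8)
  }
})

test_that("vesselness is equivariant under axis-aligned 90-degree rotation", {
  set.seed(5)
  d <- c(20, 20, 20)
  a <- vesseltrace:::gauss_smooth3(array(runif(prod(d)), d), c(1.5, 1.5, 1.5))
  pars <- vesselness_params(scales_mm = c(1, 2))
  v1 <- vesselness(volume_grid(a), full_mask(d), pars)
  rot <- function(x) aperm(x[, dim(x)[2]:1, ], c(2, 1, 3))  # 90 deg about z
  v2 <- vesselness(volume_grid(rot(a)), full_mask(d), pars)
  expect_equal(rot(v1$data), v2$data, tolerance = 1e-6)
})

test_that("per-scale response peaks at the scale matching the tube radius", {
  d <- c(25, 25, 30)
  resp_at <- function(radius, sigma) {
    tube <- gaussian_denoise(volume_grid(make_tube(d, radius = radius)),
                             preprocess_params(denoise_sigma_mm = 0.7))
    pars <- vesselness_params(scales_mm = sigma, c_mode = "fixed",
                              c_value = 0.1)
    mean(vesselness(tube, full_mask(d), pars)$data[13, 13, 10:20])
  }
  expect_gt(resp_at(1, 1), resp_at(1, 3))
  expect_gt(resp_at(3, 3), resp_at(3, 1))
})

test_that("support maps are truncated sliding means", {
  d <- c(8, 8, 12)
  v <- volume_grid(array(0.4, d))
  sup <- orthogonal_support_maps(v, fusion_params(support_window_slices = 5L))
  for (s in sup) expect_equal(s$data, v$data, tolerance = 1e-12)

  a <- array(0, d); a[, , 6] <- 1
  supz <- orthogonal_support_maps(volume_grid(a))$support_z
  expect_equal(supz$data[1, 1, 4:8], rep(0.2, 5))
  expect_equal(supz$data[1, 1, c(3, 9)], c(0, 0))

  expect_error(fusion_params(support_window_slices = 4L), "odd")
})

test_that("fusion is a convex combination with exact identity weights", {
  d <- c(6, 6, 6)
  mk <- function(val) volume_grid(array(val, d))
  v <- volume_grid(array(runif(prod(d)), d))
  sup_self <- list(support_x = v, support_y = v, support_z = v)
  expect_equal(fuse_maps(v, sup_self)$data, v$data)

  w_only <- fusion_params(weights = c(vesselness = 1, support_x = 0,
                                      support_y = 0, support_z = 0))
  sup0 <- list(support_x = mk(0), support_y = mk(0), support_z = mk(0))
  expect_identical(fuse_maps(v, sup0, w_only)$data, v$data)

  sup <- list(support_x = mk(0.2), support_y = mk(0.4), support_z = mk(0.6))
  out <- fuse_maps(mk(0.8), sup)
  expect_equal(out$data[1, 1, 1], 0.6, tolerance = 1e-12)

  # never exceeds the voxelwise max of its inputs
  sup_r <- list(support_x = volume_grid(array(runif(prod(d)), d)),
                support_y = volume_grid(array(runif(prod(d)), d)),
                support_z = volume_grid(array(runif(prod(d)), d)))
  fo <- fuse_maps(v, sup_r)
  mx <- pmax(v$data, sup_r$support_x$data, sup_r$support_y$data,
             sup_r$support_z$data)
  expect_true(all(fo$data <= mx + 1e-12))
})

test_that("invalid fusion weights are rejected", {
  expect_error(fusion_params(weights = c(vesselness = 0.6, support_x = 0.2,
                                         support_y = 0.2, support_z = 0.2)),
               "sum to 1")
  expect_error(fusion_params(weights = c(vesselness = 1.2, support_x = -0.2,
                                         support_y = 0, support_z = 0)),
               "nonnegative|sum to 1")
})
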