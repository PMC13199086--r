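test_that("tree sampling: segment counts, determinism, taper", {
  p0 <- tree_params(max_depth = 0L)
  expect_equal(nrow(sample_vessel_tree(1, p0)), 1)

  # depth 3 with a radius floor far below reach: full binary tree
  p3 <- tree_params(max_depth = 3L, min_radius_mm = 1e-4)
  t3 <- sample_vessel_tree(5, p3)
  expect_equal(nrow(t3), 2^4 - 1)

  expect_identical(sample_vessel_tree(7, p3), sample_vessel_tree(7, p3))

  # radii never increase from parent to child
  for (i in which(!is.na(t3$parent_id)))
    expect_lte(t3$radius_mm[i], t3$radius_mm[t3$parent_id[i]])
  # children start where the parent ends
  for (i in which(!is.na(t3$parent_id))) {
    p <- t3$parent_id[i]
    expect_equal(c(t3$x0[i], t3$y0[i], t3$z0[i]),
                 c(t3$x1[p], t3$y1[p], t3$z1[p]))
  }
})

test_that("voxelization: per-slice discs, trunk levels, Y ground truth", {
  grid <- volume_grid(array(0, c(21, 21, 30)), spacing = c(1, 1, 1))
  seg <- data.frame(id = 1L, parent_id = NA_integer_, depth = 0L,
                    x0 = 10, y0 = 10, z0 = 4, x1 = 10, y1 = 10, z1 = 24,
                    radius_mm = 3)
  class(seg) <- c("vessel_tree", class(seg))
  vox <- voxelize_tree(seg, grid)
  for (z in c(8, 15, 20)) {
    sl <- vox$vessel_mask$data[, , z + 1]
    idx <- which(sl, arr.ind = TRUE)
    r <- sqrt((idx[, 1] - 11)^2 + (idx[, 2] - 11)^2)
    expect_true(all(r <= 3 + 1e-9))
    expect_equal(sum(sl), sum(outer(1:21, 1:21, function(x, y)
      (x - 11)^2 + (y - 11)^2 <= 9)))
  }
  lv <- vox$branch_levels$data[vox$branch_levels$data >= 0]
  expect_true(all(lv == 0))   # single segment: everything is trunk

  # Y tree: long path is the trunk, short arm is level 1
  ytree <- data.frame(
    id = 1:3, parent_id = c(NA, 1L, 1L), depth = c(0L, 1L, 1L),
    x0 = c(4, 14, 14), y0 = c(10, 10, 10), z0 = c(10, 10, 10),
    x1 = c(14, 14, 14), y1 = c(10, 18, 4), z1 = c(10, 10, 10),
    radius_mm = c(1.2, 1, 1))
  class(ytree) <- c("vessel_tree", class(ytree))
  voy <- voxelize_tree(ytree, volume_grid(array(0, c(21, 21, 21))))
  laby <- voy$branch_levels$data
  expect_true(all(laby[5:14, 11, 11] == 0))     # root on trunk
  expect_true(all(laby[15, 12:19, 11] == 0))    # longer arm on trunk
  expect_true(all(laby[15, 5:9, 11] == 1))      # shorter arm level 1
})

test_that("voxelized capsule volume approximates the analytic volume", {
  grid <- volume_grid(array(0, c(40, 40, 40)), spacing = c(0.5, 0.5, 0.5))
  seg <- data.frame(id = 1L, parent_id = NA_integer_, depth = 0L,
                    x0 = 10, y0 = 10, z0 = 3, x1 = 10, y1 = 10, z1 = 16,
                    radius_mm = 1.5)  # 3 voxels
  class(seg) <- c("vessel_tree", class(seg))
  vox <- voxelize_tree(seg, grid)
  analytic <- pi * 1.5^2 * 13 + 4 / 3 * pi * 1.5^3  # cylinder + caps
  voxvol <- sum(vox$vessel_mask$data) * 0.5^3
  expect_lt(abs(voxvol - analytic) / analytic, 0.15)
})

test_that("TOF simulation: drift bounds, determinism, containment", {
  ps <- phantom_preset("small")
  grid <- volume_grid(array(0, ps$dim), spacing = ps$spacing)
  tree <- sample_vessel_tree(3, ps$tree)

  quiet <- simulate_tof_volume(tree, grid,
                               tof_params(drift_amplitude = 0,
                                          noise_sigma = 0), seed = 3)
  med <- vesseltrace:::slice_mask_medians(quiet$volume, quiet$body_mask, 50L)
  med <- med[!is.na(med)]
  # identical up to the tanh partial-volume tail of the vessel profile
  expect_lt(diff(range(med)), 1e-3)

  drifted <- simulate_tof_volume(tree, grid,
                                 tof_params(drift_amplitude = 0.2,
                                            noise_sigma = 0), seed = 3)
  expect_true(all(drifted$slice_drift >= 0.8 - 1e-9))
  expect_true(all(drifted$slice_drift <= 1.2 + 1e-9))
  medd <- vesseltrace:::slice_mask_medians(drifted$volume, drifted$body_mask,
                                           50L)
  medd <- medd[!is.na(medd)]
  expect_lte(max(medd) / min(medd), 1.5 + 1e-6)

  again <- simulate_tof_volume(tree, grid,
                               tof_params(drift_amplitude = 0.2,
                                          noise_sigma = 0), seed = 3)
  expect_identical(drifted$volume$data, again$volume$data)

  expect_error(tof_params(body_level = 0.5, vessel_level = 0.4),
               "inflow contrast")
})

test_that("containment chain centerline <= vessel <= body holds across seeds", {
  for (seed in 1:12) {
    ph <- suppressWarnings(make_phantom_bundle(seed, "small"))
    expect_true(all(ph$vessel_mask$data[ph$centerline_mask$data]))
    expect_true(all(ph$body_mask$data[ph$vessel_mask$data]))
    expect_true(all(ph$slice_drift > 0))
  }
})

test_that("phantom bundles are deterministic and presets differ", {
  a <- suppressWarnings(make_phantom_bundle(4, "small"))
  b <- suppressWarnings(make_phantom_bundle(4, "small"))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$branch_levels$data, b$branch_levels$data)

  dflt <- phantom_preset("default")
  expect_equal(dflt$spacing, c(0.117, 0.117, 0.5))
  expect_equal(dflt$dim, c(128L, 128L, 96L))
  expect_gt(phantom_preset("stress")$tree$max_depth,
            dflt$tree$max_depth)
  expect_error(phantom_preset("huge"), "arg")
})

test_that("bundle writing produces truth volumes and a manifest", {
  od <- file.path(tempdir(), "bundle_out")
  ph <- suppressWarnings(make_phantom_bundle(2, "small", outdir = od))
  expect_true(file.exists(file.path(od, "volume.nii.gz")))
  expect_true(file.exists(file.path(od, "phantom_manifest.json")))
  man <- jsonlite::read_json(file.path(od, "phantom_manifest.json"))
  expect_equal(man$seed, 2)
  expect_equal(length(man$slice_drift), dim(ph$volume$data)[3])
})

test_that("geometry report reproduces the emulated acquisition numbers", {
  g <- tof_geometry_report()
  expect_equal(round(g$in_plane_mm, 3), 0.117)
  expect_equal(g$overlap_percent, 40)
  expect_equal(g$overlap_mm, 0.2)
})
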