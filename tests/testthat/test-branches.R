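test_that("skeleton graphs carry physical edge lengths", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:4, 3, 3] <- TRUE
  sg <- skeleton_to_graph(binary_mask(m, spacing = c(0.117, 0.117, 0.5)))
  expect_equal(nrow(sg$coords), 3)
  expect_equal(igraph::ecount(sg$graph), 2)
  expect_equal(igraph::E(sg$graph)$weight, rep(0.117, 2))

  m2 <- array(FALSE, c(8, 8, 8))
  m2[2, 3, 3] <- TRUE; m2[3, 3, 4] <- TRUE   # x-z diagonal
  sg2 <- skeleton_to_graph(binary_mask(m2, spacing = c(0.117, 0.117, 0.5)))
  expect_equal(igraph::ecount(sg2$graph), 1)
  expect_equal(igraph::E(sg2$graph)$weight, sqrt(0.117^2 + 0.5^2))

  sg0 <- skeleton_to_graph(binary_mask(array(FALSE, c(4, 4, 4))))
  expect_equal(nrow(sg0$coords), 0)
  expect_equal(igraph::ecount(sg0$graph), 0)
})

test_that("trunk of a simple path is the whole path; singletons are trivial", {
  m <- array(FALSE, c(30, 6, 6))
  m[3:22, 3, 3] <- TRUE
  sg <- skeleton_to_graph(binary_mask(m))
  tr <- identify_trunk(sg, 1)
  expect_equal(nrow(tr$coords), 20)
  expect_equal(tr$length_mm, 19)

  m1 <- array(FALSE, c(4, 4, 4)); m1[2, 2, 2] <- TRUE
  sg1 <- skeleton_to_graph(binary_mask(m1))
  tr1 <- identify_trunk(sg1, 1)
  expect_equal(tr1$length_mm, 0)
  expect_equal(nrow(tr1$coords), 1)
})

test_that("trunk of a Y-skeleton joins the two longest arms", {
  m <- make_y_skeleton(arms = c(10, 8, 6))
  sg <- skeleton_to_graph(binary_mask(m))
  tr <- identify_trunk(sg, 1)
  expect_equal(nrow(tr$coords), 10 + 1 + 8)
  expect_equal(tr$length_mm, 18)
  # the short arm is not on the trunk
  expect_false(any(tr$coords[, 2] > 16))
})

test_that("trunk length equals the brute-force tree diameter (oracle)", {
  for (i in 1:25) {
    m <- make_random_voxel_tree(sample(20:150, 1), seed = 1000 + i)
    sp <- c(0.2, 0.3, 0.5)
    sg <- skeleton_to_graph(binary_mask(m, spacing = sp), spacing = sp)
    expect_equal(max(sg$component), 1)
    tr <- identify_trunk(sg, 1)
    dd <- igraph::distances(sg$graph)
    expect_equal(tr$length_mm, max(dd), tolerance = 1e-9)
  }
})

test_that("level propagation: pure path, Y and caterpillar", {
  path <- array(FALSE, c(20, 5, 5)); path[3:17, 3, 3] <- TRUE
  sg <- skeleton_to_graph(binary_mask(path))
  pb <- propagate_branch_levels(sg, list(identify_trunk(sg, 1)))
  lv <- pb$labels$data[pb$labels$data >= 0]
  expect_true(all(lv == 0))

  y <- make_y_skeleton(arms = c(10, 8, 6))
  sgy <- skeleton_to_graph(binary_mask(y))
  pby <- propagate_branch_levels(sgy, list(identify_trunk(sgy, 1)))
  tab <- table(pby$labels$data[pby$labels$data >= 0])
  expect_equal(as.integer(tab["0"]), 19)
  expect_equal(as.integer(tab["1"]), 6)
  expect_true(is.na(tab["2"]))

  cat_m <- make_caterpillar()
  sgc <- skeleton_to_graph(binary_mask(cat_m))
  pbc <- propagate_branch_levels(sgc, list(identify_trunk(sgc, 1)))
  labc <- pbc$labels$data
  expect_equal(labc[10, 9, 4], 1L)   # twig A
  expect_equal(labc[20, 9, 4], 1L)   # twig B
  expect_equal(labc[21, 11, 4], 2L)  # sub-twig emerges from a twig
  expect_true(all(labc[5:30, 8, 4] == 0L))
})

test_that("levels partition the skeleton with exclusion across components", {
  for (i in 1:5) {
    m <- make_random_voxel_tree(80, seed = 300 + i)
    m2 <- make_random_voxel_tree(30, dims = c(40, 40, 40), seed = 400 + i)
    # place second tree in a disjoint corner volume
    big <- array(FALSE, c(90, 40, 40))
    big[1:40, , ] <- m
    big[51:90, , ] <- m2
    sg <- skeleton_to_graph(binary_mask(big))
    nc <- max(sg$component)
    trunks <- lapply(seq_len(nc), function(cc) identify_trunk(sg, cc))
    pb <- propagate_branch_levels(sg, trunks)
    lab <- pb$labels$data
    expect_equal(sum(lab >= 0L), sum(big))       # exactly one level each
    expect_true(all(lab[!big] == -1L))
    # every level-k branch contains a voxel 26-adjacent to level k-1
    for (k in seq_len(max(lab))) {
      sel <- lab == k
      parts <- vesseltrace:::label_components(sel)
      prev_dil <- vesseltrace:::dilate_box1(lab == (k - 1L))
      for (p in seq_len(max(parts)))
        expect_true(any(prev_dil[parts == p]))
    }
  }
})

test_that("labeling is deterministic across repeated runs", {
  m <- make_random_voxel_tree(120, seed = 99)
  run <- function() {
    sg <- skeleton_to_graph(binary_mask(m))
    trunks <- lapply(seq_len(max(sg$component)),
                     function(cc) identify_trunk(sg, cc))
    propagate_branch_levels(sg, trunks)$labels$data
  }
  expect_identical(run(), run())
})

test_that("color scheme maps levels and tumor per the rendering taxonomy", {
  d <- c(6, 6, 1)
  lab <- array(-1L, d)
  lab[1, 1, 1] <- 0L; lab[2, 1, 1] <- 1L; lab[3, 1, 1] <- 2L
  lab[4, 1, 1] <- 3L; lab[5, 1, 1] <- 4L
  bl <- branch_labels(lab)
  rgb <- colorize_labels(bl)
  expect_equal(rgb[1, 1, 1, ], c(1, 0, 0))    # trunk red
  expect_equal(rgb[2, 1, 1, ], c(0, 1, 0))    # level 1 green
  expect_equal(rgb[3, 1, 1, ], c(0, 0, 1))    # level 2 blue
  expect_equal(rgb[4, 1, 1, ], c(1, 0, 1))    # level 3 magenta
  expect_equal(rgb[5, 1, 1, ], c(1, 0, 1))    # level 4 collapses to magenta
  expect_equal(rgb[6, 1, 1, ], c(0, 0, 0))

  # no tumor -> no purple anywhere
  expect_false(any(apply(rgb, 1:3, function(px)
    all(px == c(0.5, 0, 0.5)))))

  tm <- array(FALSE, d); tm[1, 1, 1] <- TRUE; tm[6, 1, 1] <- TRUE
  rgb2 <- colorize_labels(bl, binary_mask(tm))
  expect_equal(rgb2[1, 1, 1, ], c(1, 0, 0))     # vessel wins over tumor
  expect_equal(rgb2[6, 1, 1, ], c(0.5, 0, 0.5)) # tumor purple elsewhere
})
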