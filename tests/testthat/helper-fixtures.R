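# Fixtures built in code: tubes, plates, toy skeletons, random voxel trees.

# solid axis-aligned cylinder (axis along `axis` through the centre)
make_tube <- function(dims = c(21, 21, 40), radius = 2, axis = 3,
                      value = 1, background = 0) {
  a <- array(background, dims)
  cs <- (dims + 1) / 2
  pl <- setdiff(1:3, axis)
  idx <- which(a == background, arr.ind = TRUE)
  r2 <- (idx[, pl[1]] - cs[pl[1]])^2 + (idx[, pl[2]] - cs[pl[2]])^2
  a[idx[r2 <= radius^2, , drop = FALSE]] <- value
  a
}

# one-voxel-thick plate spanning the x-y mid-plane
make_plate <- function(dims = c(21, 21, 40), value = 1) {
  a <- array(0, dims)
  a[, , round(dims[3] / 2)] <- value
  a
}

# Y-shaped skeleton: three straight arms meeting at one junction voxel.
# Arm voxel counts exclude the junction.
make_y_skeleton <- function(arms = c(10, 8, 6), dims = c(32, 32, 8)) {
  m <- array(FALSE, dims)
  j <- c(12, 16, 4)
  m[j[1], j[2], j[3]] <- TRUE
  for (i in seq_len(arms[1])) m[j[1] - i, j[2], j[3]] <- TRUE      # -x arm
  for (i in seq_len(arms[2])) m[j[1] + i, j[2], j[3]] <- TRUE      # +x arm
  for (i in seq_len(arms[3])) m[j[1], j[2] + i, j[3]] <- TRUE      # +y arm
  m
}

# caterpillar: trunk along x, two one-voxel-offset twigs, one twig with a
# sub-twig hanging off it
make_caterpillar <- function(dims = c(40, 16, 8)) {
  m <- array(FALSE, dims)
  m[5:30, 8, 4] <- TRUE                 # trunk, 26 voxels
  m[10, 9:11, 4] <- TRUE                # twig A, 3 voxels
  m[20, 9:13, 4] <- TRUE                # twig B, 5 voxels
  m[20 + 1, 11, 4] <- FALSE
  m[21, 11, 4] <- TRUE                  # sub-twig off twig B, 1 voxel
  m
}

# random voxel tree: grow by repeatedly attaching a voxel 26-adjacent to
# exactly one existing voxel, so the adjacency graph is a tree
make_random_voxel_tree <- function(n, dims = c(40, 40, 40), seed = 1) {
  set.seed(seed)
  m <- array(FALSE, dims)
  start <- ceiling(dims / 2)
  m[start[1], start[2], start[3]] <- TRUE
  vox <- matrix(start, ncol = 3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n_nb <- function(p) {
    nb <- sweep(offs, 2, p, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    sum(m[nb[ok, , drop = FALSE]])
  }
  tries <- 0
  while (nrow(vox) < n && tries < n * 60) {
    tries <- tries + 1
    base <- vox[sample.int(nrow(vox), 1), ]
    cand <- base + offs[sample.int(26, 1), ]
    if (any(cand < 1) || any(cand > dims)) next
    if (m[cand[1], cand[2], cand[3]]) next
    if (n_nb(cand) != 1) next
    m[cand[1], cand[2], cand[3]] <- TRUE
    vox <- rbind(vox, cand)
  }
  m
}

# brute-force Otsu oracle: same equal-width binning, direct evaluation of
# the between-class variance at every interior bin edge
otsu_brute <- function(values, bins = 256L) {
  mn <- min(values); mx <- max(values)
  width <- (mx - mn) / bins
  idx <- pmin(floor((values - mn) / width) + 1L, bins)
  centers <- mn + (seq_len(bins) - 0.5) * width
  mapped <- centers[idx]
  best <- -Inf; best_thr <- NA_real_
  for (k in seq_len(bins - 1L)) {
    thr <- mn + k * width
    lo <- mapped[idx <= k]; hi <- mapped[idx > k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) { best <- bcv; best_thr <- thr }
  }
  best_thr
}

expect_same_mask <- function(a, b) {
  expect_identical(as.vector(a$data), as.vector(b$data))
}
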