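# Internal wrappers around the compiled voxel kernels.

# Sampled Gaussian kernel and its first/second derivatives, in voxel units.
# DC response is corrected so that smoothing preserves constants exactly and
# derivative kernels annihilate them.
gauss_kernels <- function(sigma_vox, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -t / sigma_vox^2 * g
    return(k - mean(k))
  }
  k <- (t^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}

conv_axis <- function(arr, kernel, axis, mode = c("replicate", "zero")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  out <- conv1d_axis_cpp(as.double(arr), as.integer(d), as.double(kernel),
                         as.integer(axis - 1L), if (mode == "replicate") 0L else 1L)
  array(out, dim = d)
}

# Separable Gaussian smoothing, per-axis sigma in voxels, replicate edges.
gauss_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3)
    arr <- conv_axis(arr, gauss_kernels(sigma_vox[ax]), ax)
  arr
}

# 26-connected component labels (integer array, 0 = background).
label_components <- function(mask_arr) {
  d <- dim(mask_arr)
  array(cc_label_26_cpp(as.logical(mask_arr), as.integer(d)), dim = d)
}

fill_holes <- function(mask_arr) {
  d <- dim(mask_arr)
  array(fill_holes_cpp(as.logical(mask_arr), as.integer(d)), dim = d)
}

# Euclidean distance (not squared) to the nearest TRUE voxel, physical units.
distance_to_mask <- function(mask_arr, spacing) {
  d <- dim(mask_arr)
  sqrt(array(edt_sq_cpp(as.logical(mask_arr), as.integer(d),
                        as.double(spacing)), dim = d))
}

# Ball dilation/erosion by radius in voxel units (isotropic index-space ball).
dilate_ball <- function(mask_arr, radius_vox) {
  if (radius_vox <= 0) return(mask_arr)
  d <- distance_to_mask(mask_arr, c(1, 1, 1))
  d <= radius_vox + 1e-9
}

erode_ball <- function(mask_arr, radius_vox) {
  if (radius_vox <= 0) return(mask_arr)
  !dilate_ball(!mask_arr, radius_vox)
}

close_ball <- function(mask_arr, radius_vox) {
  erode_ball(dilate_ball(mask_arr, radius_vox), radius_vox)
}

# Keep only the largest 26-connected component.
largest_component <- function(mask_arr) {
  lab <- label_components(mask_arr)
  if (!any(lab > 0L)) return(mask_arr & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# One-step 26-neighbourhood dilation (3x3x3 box), used for adjacency tests.
dilate_box1 <- function(mask_arr) {
  a <- mask_arr
  for (ax in 1:3)
    a <- conv_axis(a * 1, c(1, 1, 1), ax, mode = "zero")
  a > 0
}
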