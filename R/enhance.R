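#' Vesselness filter parameters
#'
#' Multiscale Hessian tube-enhancement for bright vessels on a dark
#' background. At each scale sigma the image is convolved with
#' sigma^2-normalized Gaussian second-derivative kernels; the Hessian
#' eigenvalues (|l1| <= |l2| <= |l3|) feed the classic three-factor
#' tubularity response with plate/blob discriminants R_A = |l2|/|l3|,
#' R_B = |l1|/sqrt(|l2 l3|) and structure energy S = sqrt(l1^2+l2^2+l3^2).
#'
#' @param scales_mm strictly increasing sigmas in mm; the default
#'   `c(0.12, 0.24, 0.36)` targets vessels of roughly 1-3 in-plane voxels
#'   radius at 0.117 mm resolution.
#' @param alpha sensitivity of the plate-vs-line discriminant (default 0.5).
#' @param beta sensitivity of the blob discriminant (default 0.5).
#' @param c_mode `"auto"` sets the structure-energy constant c to half the
#'   maximum S within the body mask at each scale; `"fixed"` uses `c_value`.
#' @param c_value positive constant used when `c_mode = "fixed"`.
#' @return A list of class `vesselness_params`.
#' @export
vesselness_params <- function(scales_mm = c(0.12, 0.24, 0.36),
                              alpha = 0.5, beta = 0.5,
                              c_mode = c("auto", "fixed"),
                              c_value = NULL) {
  c_mode <- match.arg(c_mode)
  stopifnot(length(scales_mm) >= 1, all(scales_mm > 0),
            all(diff(scales_mm) > 0), alpha > 0, beta > 0)
  if (c_mode == "fixed" && (is.null(c_value) || c_value <= 0))
    stop("vesselness_params: fixed c_mode needs a positive c_value",
         call. = FALSE)
  structure(list(scales_mm = as.numeric(scales_mm), alpha = alpha,
                 beta = beta, c_mode = c_mode, c_value = c_value),
            class = "vesselness_params")
}

#' Fusion parameters
#'
#' @param support_window_slices odd window (>= 3) of the slice-wise sliding
#'   mean that builds each orthogonal-plane support map.
#' @param weights named nonnegative weights `vesselness`, `support_x`,
#'   `support_y`, `support_z` summing to 1.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(support_window_slices = 5L,
                          weights = c(vesselness = 0.5, support_x = 1 / 6,
                                      support_y = 1 / 6, support_z = 1 / 6)) {
  support_window_slices <- as.integer(support_window_slices)
  if (support_window_slices < 3L || support_window_slices %% 2L == 0L)
    stop("fusion_params: support window must be an odd integer >= 3",
         call. = FALSE)
  req <- c("vesselness", "support_x", "support_y", "support_z")
  if (!all(req %in% names(weights)))
    stop("fusion_params: weights must be named ",
         paste(req, collapse = ", "), call. = FALSE)
  weights <- weights[req]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("fusion_params: weights must be nonnegative and sum to 1",
         call. = FALSE)
  structure(list(support_window_slices = support_window_slices,
                 weights = weights),
            class = "fusion_params")
}

# Hessian of `arr` at physical scale sigma_mm: Gaussian smoothing with
# per-axis sigma in voxel units followed by central-difference derivatives
# in physical units (together a discrete Gaussian-derivative convolution;
# well behaved even at sub-voxel sigma along a coarse axis), then
# sigma^2-normalized. Returns the six upper-triangle components in mm^-2.
hessian_at_scale <- function(arr, spacing, sigma_mm) {
  sm <- gauss_smooth3(arr, sigma_mm / spacing)
  s2 <- sigma_mm^2
  d2 <- function(a, ax) conv_axis(a, c(1, -2, 1), ax) / spacing[ax]^2
  d1 <- function(a, ax) conv_axis(a, c(-1, 0, 1), ax) / (2 * spacing[ax])
  list(
    xx = d2(sm, 1) * s2,
    yy = d2(sm, 2) * s2,
    zz = d2(sm, 3) * s2,
    xy = d1(d1(sm, 1), 2) * s2,
    xz = d1(d1(sm, 1), 3) * s2,
    yz = d1(d1(sm, 2), 3) * s2
  )
}

#' Multiscale vesselness enhancement
#'
#' Computes the bright-tube vesselness response at each scale and takes the
#' per-voxel maximum over scales; the response is zero outside the body
#' mask and wherever the second or third Hessian eigenvalue is positive
#' (dark-tube polarity gate). Voxels within the filter support (twice the
#' largest scale) of the mask boundary are also zeroed: there the Hessian
#' is dominated by the body/air edge rather than by anatomy, and the edge
#' would otherwise shed spurious tube-like responses along the whole body
#' outline.
#'
#' @param volume a preprocessed [volume_grid()] (finite, \[0, 1\] within the
#'   mask).
#' @param mask the body [binary_mask()].
#' @param params a [vesselness_params()].
#' @return A [volume_grid()] with values in \[0, 1\] (a probability-like
#'   tubularity map).
#' @export
vesselness <- function(volume, mask, params = vesselness_params()) {
  stop_if_grid_mismatch(volume, mask, "volume and mask")
  if (!any(mask$data)) stop("vesselness: empty mask", call. = FALSE)
  d <- dim(volume$data)
  core <- mask$data
  if (any(!mask$data)) {
    margin <- 2 * max(params$scales_mm)
    core <- mask$data &
      (distance_to_mask(!mask$data, volume$spacing) > margin)
    if (!any(core)) core <- mask$data  # mask thinner than the margin
  }
  inmask <- which(core)
  best <- numeric(length(inmask))
  for (sigma in params$scales_mm) {
    H <- hessian_at_scale(volume$data, volume$spacing, sigma)
    ev <- eig_sym3_cpp(H$xx[inmask], H$yy[inmask], H$zz[inmask],
                       H$xy[inmask], H$xz[inmask], H$yz[inmask])
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- if (params$c_mode == "auto") max(S) / 2 else params$c_value
    resp <- numeric(length(l1))
    ok <- l2 < 0 & l3 < 0
    if (any(ok) && cc > 0) {
      a2 <- abs(l2[ok]); a3 <- abs(l3[ok]); a1 <- abs(l1[ok])
      ra <- a2 / a3
      rb <- a1 / sqrt(a2 * a3)
      resp[ok] <- (1 - exp(-ra^2 / (2 * params$alpha^2))) *
        exp(-rb^2 / (2 * params$beta^2)) *
        (1 - exp(-S[ok]^2 / (2 * cc^2)))
    }
    best <- pmax(best, resp)
  }
  out <- array(0, dim = d)
  out[inmask] <- best
  with_data(volume, out)
}

#' Orthogonal-plane support maps
#'
#' For each axis, the sliding mean of the vesselness map over
#' `support_window_slices` consecutive slices perpendicular to that axis
#' (window centred, truncated at the volume boundary). These slice-wise
#' averages reward structures that persist across neighbouring slices and
#' so improve slice-to-slice continuity of thin vessels.
#'
#' @param vness a vesselness [volume_grid()] with values in \[0, 1\].
#' @param params a [fusion_params()].
#' @return A list of three [volume_grid()]s: `support_x`, `support_y`,
#'   `support_z`.
#' @export
orthogonal_support_maps <- function(vness, params = fusion_params()) {
  stopifnot(inherits(vness, "volume_grid"))
  w <- params$support_window_slices
  if (w %% 2L == 0L)
    stop("orthogonal_support_maps: window must be odd", call. = FALSE)
  kern <- rep(1, w)
  d <- dim(vness$data)
  out <- lapply(1:3, function(ax) {
    num <- conv_axis(vness$data, kern, ax, mode = "zero")
    # effective window length at each position along the axis
    cnt1d <- as.vector(conv1d_axis_cpp(rep(1, d[ax]), c(d[ax], 1L, 1L),
                                       kern, 0L, 1L))
    shape <- c(1L, 1L, 1L); shape[ax] <- d[ax]
    cnt <- array(rep(1, 1), dim = shape)
    cnt[] <- cnt1d
    with_data(vness, sweep_divide(num, cnt, ax))
  })
  names(out) <- c("support_x", "support_y", "support_z")
  out
}

# divide `arr` by a per-position vector along axis `ax`
sweep_divide <- function(arr, cnt, ax) {
  d <- dim(arr)
  rep_each <- prod(d[seq_len(ax - 1)])
  rep_times <- prod(d[seq(ax + 1, 4)[seq_len(3 - ax)]])
  div <- rep(rep(as.vector(cnt), each = rep_each), times = max(1, rep_times))
  array(as.vector(arr) / div, dim = d)
}

#' Fuse vesselness and support maps into one probability volume
#'
#' Voxelwise convex combination of the vesselness map and the three
#' orthogonal-plane support maps. Convexity keeps the result in \[0, 1\]
#' and never above the voxelwise maximum of the inputs.
#'
#' @param vness vesselness [volume_grid()].
#' @param supports list with `support_x`, `support_y`, `support_z` as
#'   returned by [orthogonal_support_maps()].
#' @param params a [fusion_params()].
#' @return A [volume_grid()] probability volume in \[0, 1\].
#' @export
fuse_maps <- function(vness, supports, params = fusion_params()) {
  for (nm in c("support_x", "support_y", "support_z")) {
    if (is.null(supports[[nm]]))
      stop("fuse_maps: missing support map `", nm, "`", call. = FALSE)
    stop_if_grid_mismatch(vness, supports[[nm]], "vesselness and supports")
  }
  w <- params$weights
  out <- w[["vesselness"]] * vness$data +
    w[["support_x"]] * supports$support_x$data +
    w[["support_y"]] * supports$support_y$data +
    w[["support_z"]] * supports$support_z$data
  with_data(vness, out)
}
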