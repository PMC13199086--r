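#' Preprocessing parameters
#'
#' Controls body masking and intensity conditioning of the raw TOF
#' magnitude volume.
#'
#' @param close_radius_vox integer >= 0, ball radius (voxels) of the
#'   morphological closing applied to the thresholded body mask.
#' @param denoise_sigma_mm Gaussian denoising sigma in mm (default 0.12,
#'   about one in-plane voxel at 0.117 mm resolution).
#' @param robust_percentiles pair (p_lo, p_hi) in \[0, 100\] used for robust
#'   rescaling of within-mask intensities to \[0, 1\].
#' @param min_slice_mask_voxels slices with fewer within-mask voxels than
#'   this are exempt from per-slice normalization (their median is too
#'   noisy to trust).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(close_radius_vox = 2L,
                              denoise_sigma_mm = 0.12,
                              robust_percentiles = c(1, 99),
                              min_slice_mask_voxels = 50L) {
  stopifnot(close_radius_vox >= 0, denoise_sigma_mm > 0,
            length(robust_percentiles) == 2,
            robust_percentiles[1] < robust_percentiles[2],
            all(robust_percentiles >= 0), all(robust_percentiles <= 100),
            min_slice_mask_voxels >= 1)
  structure(list(close_radius_vox = as.integer(close_radius_vox),
                 denoise_sigma_mm = denoise_sigma_mm,
                 robust_percentiles = as.numeric(robust_percentiles),
                 min_slice_mask_voxels = as.integer(min_slice_mask_voxels)),
            class = "preprocess_params")
}

#' Whole-body mask from a TOF magnitude volume
#'
#' Otsu-thresholds the full volume, closes the result with a ball,
#' fills interior holes in 3D and keeps the largest 26-connected
#' component — the animal's body.
#'
#' @param volume a [volume_grid()].
#' @param params a [preprocess_params()].
#' @return A [binary_mask()] on the same grid.
#' @export
compute_body_mask <- function(volume, params = preprocess_params()) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$data
  if (max(v) == min(v))
    stop("compute_body_mask: constant volume, cannot threshold",
         call. = FALSE)
  thr <- otsu_threshold(as.vector(v))
  m <- v >= thr
  m <- close_ball(m, params$close_radius_vox)
  m <- fill_holes(m)
  m <- largest_component(m)
  if (!any(m))
    stop("compute_body_mask: empty mask after cleanup", call. = FALSE)
  with_data(volume, m, binary_mask)
}

#' Robust intensity normalization within a mask
#'
#' Linearly rescales within-mask intensities so that the `p_lo`/`p_hi`
#' percentiles map to 0 and 1, clipping beyond; voxels outside the mask
#' are set to 0. Percentile (rather than min/max) anchoring keeps the
#' handful of inflow-bright vessel voxels from compressing the body
#' histogram.
#'
#' @param volume a [volume_grid()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @param params a [preprocess_params()].
#' @return A [volume_grid()] with values in \[0, 1\].
#' @export
normalize_within_mask <- function(volume, mask,
                                  params = preprocess_params()) {
  stop_if_grid_mismatch(volume, mask, "volume and mask")
  if (!any(mask$data)) stop("normalize_within_mask: empty mask",
                            call. = FALSE)
  vals <- volume$data[mask$data]
  ab <- stats::quantile(vals, params$robust_percentiles / 100, names = FALSE)
  if (ab[2] <= ab[1])
    stop("normalize_within_mask: degenerate intensity range (p_lo == p_hi)",
         call. = FALSE)
  out <- (volume$data - ab[1]) / (ab[2] - ab[1])
  out <- pmin(pmax(out, 0), 1)
  out[!mask$data] <- 0
  with_data(volume, out)
}

#' 3D Gaussian denoising
#'
#' Separable Gaussian smoothing with a physical sigma, converted per axis
#' to voxel units (`sigma_mm / spacing`), so anisotropic grids are smoothed
#' isotropically in mm. Edges are handled by replication.
#'
#' @inheritParams normalize_within_mask
#' @return A [volume_grid()].
#' @export
gaussian_denoise <- function(volume, params = preprocess_params()) {
  stopifnot(inherits(volume, "volume_grid"))
  if (params$denoise_sigma_mm <= 0)
    stop("gaussian_denoise: sigma must be positive", call. = FALSE)
  sig_vox <- params$denoise_sigma_mm / volume$spacing
  with_data(volume, gauss_smooth3(volume$data, sig_vox))
}

#' Per-slice intensity normalization within the body mask
#'
#' Sequential-excitation multi-slice TOF with overlapping slices suffers
#' slice crosstalk/saturation that modulates the per-slice signal level.
#' Each axial slice with at least `min_slice_mask_voxels` within-mask
#' voxels is divided by its within-mask median and multiplied by the
#' global within-mask median, so qualifying slice medians become equal
#' while the overall intensity scale is preserved; sparsely masked slices
#' are left unchanged.
#'
#' @inheritParams normalize_within_mask
#' @return A [volume_grid()].
#' @export
per_slice_normalize <- function(volume, mask, params = preprocess_params()) {
  stop_if_grid_mismatch(volume, mask, "volume and mask")
  if (!any(mask$data)) stop("per_slice_normalize: empty mask", call. = FALSE)
  v <- volume$data
  m <- mask$data
  nz <- dim(v)[3]
  M <- stats::median(v[m])
  out <- v
  for (z in seq_len(nz)) {
    mz_mask <- m[, , z]
    if (sum(mz_mask) < params$min_slice_mask_voxels) next
    mz <- stats::median(v[, , z][mz_mask])
    if (mz == 0)
      stop("per_slice_normalize: slice ", z,
           " has zero within-mask median", call. = FALSE)
    out[, , z] <- v[, , z] * (M / mz)
  }
  with_data(volume, out)
}

# Within-mask slice medians for qualifying slices (used by drift QA).
slice_mask_medians <- function(volume, mask, min_voxels = 50L) {
  v <- volume$data; m <- mask$data
  nz <- dim(v)[3]
  med <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    mz <- m[, , z]
    if (sum(mz) >= min_voxels) med[z] <- stats::median(v[, , z][mz])
  }
  med
}
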