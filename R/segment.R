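#' Segmentation parameters
#'
#' @param percentile percentile constraint in (0, 100); the segmentation
#'   threshold is never below this percentile of the within-body fused
#'   probabilities (default 95: vessels occupy well under 5% of the body).
#' @param min_component_voxels components smaller than this are removed
#'   (default 27, a 3x3x3 speck).
#' @param histogram_bins number of equal-width bins for the Otsu histogram.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(percentile = 95, min_component_voxels = 27L,
                           histogram_bins = 256L) {
  stopifnot(percentile > 0, percentile < 100, min_component_voxels >= 1,
            histogram_bins >= 2)
  structure(list(percentile = percentile,
                 min_component_voxels = as.integer(min_component_voxels),
                 histogram_bins = as.integer(histogram_bins)),
            class = "segment_params")
}

#' Otsu threshold of a value multiset
#'
#' Histograms the values into equal-width bins over their range and
#' returns the interior bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` (bin centres as class values); ties are broken
#' by the lowest qualifying threshold.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return The threshold (a bin edge); values `>=` it form the upper class.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- as.numeric(values)
  mn <- min(values); mx <- max(values)
  if (!is.finite(mn) || !is.finite(mx) || mx <= mn)
    stop("otsu_threshold: need at least two distinct finite values",
         call. = FALSE)
  bins <- as.integer(bins)
  width <- (mx - mn) / bins
  idx <- pmin(as.integer(floor((values - mn) / width)) + 1L, bins)
  cnt <- tabulate(idx, nbins = bins)
  centers <- mn + (seq_len(bins) - 0.5) * width
  n <- length(values)
  w0 <- cumsum(cnt)[-bins] / n
  w1 <- 1 - w0
  cum_mu <- cumsum(cnt * centers)[-bins]
  mu0 <- ifelse(w0 > 0, cum_mu / (w0 * n), 0)
  mu1 <- ifelse(w1 > 0, (sum(cnt * centers) - cum_mu) / (w1 * n), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bcv)  # first maximum = lowest qualifying edge
  mn + k * width
}

#' Hybrid Otsu/percentile segmentation of the fused probability map
#'
#' Vessels occupy a tiny fraction of the body (extreme class imbalance in
#' 3D angiography), and plain Otsu over all within-body values degenerates
#' on such skewed distributions, splitting the bright class itself. The
#' hybrid criterion therefore combines the two: the `percentile` order
#' statistic of the within-body fused probabilities constrains the
#' candidate pool, and the Otsu threshold of the candidate values (those
#' at or above the percentile) separates vessel from residual background
#' within it. Candidate values are histogrammed on a log scale: multiscale
#' vesselness responses spread multiplicatively across vessel radii and
#' contrasts, so their classes are far closer to the symmetric-class
#' assumption behind Otsu in the log domain than on the raw scale (where
#' the heavy bright tail pulls the split into the vessel class itself).
#' The final threshold is the larger of the two, so the
#' foreground fraction can never exceed `(100 - percentile)/100` (plus
#' one-bin slack). A constant-within-body map yields an empty mask with a
#' warning rather than an error.
#'
#' @param prob fused probability [volume_grid()] in \[0, 1\].
#' @param body body [binary_mask()].
#' @param params a [segment_params()].
#' @return A [binary_mask()] of vessel candidates.
#' @export
hybrid_threshold_segment <- function(prob, body, params = segment_params()) {
  stop_if_grid_mismatch(prob, body, "probability map and body mask")
  if (!any(body$data))
    stop("hybrid_threshold_segment: empty body mask", call. = FALSE)
  vals <- prob$data[body$data]
  if (max(vals) <= min(vals)) {
    warning("hybrid_threshold_segment: constant probability map, ",
            "returning empty mask")
    return(with_data(prob, array(FALSE, dim(prob$data)), binary_mask))
  }
  t_pct <- stats::quantile(vals, params$percentile / 100, names = FALSE)
  tail_vals <- vals[vals >= t_pct & vals > 0]
  t_otsu <- if (length(unique(tail_vals)) >= 2)
    10^otsu_threshold(log10(tail_vals), params$histogram_bins) else t_pct
  thr <- max(t_otsu, t_pct)
  fg <- prob$data >= thr & body$data
  out <- with_data(prob, fg, binary_mask)
  attr(out, "otsu") <- t_otsu
  attr(out, "percentile_value") <- t_pct
  attr(out, "threshold_used") <- thr
  out
}

#' Remove small connected components
#'
#' Deletes 26-connected components with strictly fewer than
#' `min_component_voxels` voxels.
#'
#' @param mask a [binary_mask()].
#' @param params a [segment_params()].
#' @return A [binary_mask()].
#' @export
remove_small_components <- function(mask, params = segment_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components(mask$data)
  if (!any(lab > 0L)) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_component_voxels)
  with_data(mask, array(lab %in% keep, dim(mask$data)), binary_mask)
}

#' Topology-preserving 3D skeletonization
#'
#' Sequential 6-subiteration thinning deleting simple points (26-connected
#' foreground, 6-connected background) while preserving curve endpoints.
#' The result is a one-voxel-wide centreline: a subset of the input with
#' the same number of 26-connected components, idempotent under repeated
#' application.
#'
#' @param mask a [binary_mask()] (the cleaned vessel mask).
#' @return A [binary_mask()] containing the skeleton.
#' @export
skeletonize_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  out <- array(thin_3d_cpp(as.logical(mask$data), as.integer(d)), dim = d)
  with_data(mask, out, binary_mask)
}
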