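#' 3D image containers
#'
#' `volume_grid()` is the common currency of every pipeline stage: a 3D
#' scalar array together with its voxel spacing (mm) and a 4x4 affine that
#' maps 0-based voxel indices (x, y, z order, z = axial slice axis, voxel
#' centres) to world coordinates in mm. `binary_mask()` and
#' `branch_labels()` are subclasses holding logical and integer data on the
#' same geometry contract.
#'
#' @param data 3D numeric array (logical for masks, integer for labels).
#' @param spacing numeric length-3, per-axis voxel size in mm, all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)`.
#' @return An object of class `volume_grid` (and possibly `binary_mask` or
#'   `branch_labels`): a list with elements `data`, `spacing`, `affine`.
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 4)), spacing = c(0.117, 0.117, 0.5))
#' dim(v$data)
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: `spacing` must be 3 strictly positive values",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume_grid: `affine` must be 4x4", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("volume_grid: affine is singular", call. = FALSE)
  if (!is.logical(data)) {
    nbad <- sum(!is.finite(data))
    if (nbad > 0)
      stop("volume_grid: data contains ", nbad, " non-finite voxel(s)",
           call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "logical"
  if (anyNA(data))
    stop("binary_mask: data contains NA voxels", call. = FALSE)
  v <- volume_grid(data, spacing, affine)
  class(v) <- c("binary_mask", class(v))
  v
}

#' @rdname volume_grid
#' @export
branch_labels <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "integer"
  if (anyNA(data))
    stop("branch_labels: data contains NA voxels", call. = FALSE)
  if (any(data < -1L))
    stop("branch_labels: labels must be >= -1 (-1 = non-skeleton)",
         call. = FALSE)
  v <- volume_grid(data, spacing, affine)
  class(v) <- c("branch_labels", class(v))
  v
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (is.logical(x$data)) {
    cat(sprintf("  %d foreground voxels\n", sum(x$data)))
  } else if (is.integer(x$data)) {
    lv <- sort(unique(x$data[x$data >= 0L]))
    cat(sprintf("  labels present: %s\n", paste(lv, collapse = ", ")))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

# Geometry equality between two grids (shape, spacing, affine).
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$affine - b$affine) <= tol * pmax(1, abs(a$affine)))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (shape/spacing/affine mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

# Carry geometry from `ref`, replace the data array.
with_data <- function(ref, data, constructor = volume_grid) {
  constructor(data, spacing = ref$spacing, affine = ref$affine)
}
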