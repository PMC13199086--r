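#' Read a 3D NIfTI volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a
#' [volume_grid()]. Spacing is taken from the header `pixdim`, the affine
#' from the sform/qform. 4D images with a singleton fourth axis are
#' squeezed; any other dimensionality is rejected, as are volumes with
#' non-finite voxels.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  attributes(arr) <- list(dim = d)  # drop RNifti header attributes
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("read_volume: expected a 3D image, got ", length(d),
         " dimensions in ", path, call. = FALSE)
  storage.mode(arr) <- "double"
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop("read_volume: ", nbad, " non-finite voxel(s) in ", path,
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(arr, spacing = spacing, affine = aff)
}

#' Write a volume, mask or label map as NIfTI
#'
#' Masks are written as unsigned 8-bit, branch labels as signed 16-bit and
#' intensity volumes as 32-bit float; header spacing and sform match the
#' input grid.
#'
#' @param volume a [volume_grid()], [binary_mask()] or [branch_labels()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory is
#'   created if needed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir))
      stop("write_volume: cannot create directory ", dir, call. = FALSE)
  }
  arr <- volume$data
  if (inherits(volume, "binary_mask")) {
    datatype <- "uint8"
    storage.mode(arr) <- "integer"
  } else if (inherits(volume, "branch_labels")) {
    datatype <- "int16"
  } else {
    datatype <- "float"
    storage.mode(arr) <- "double"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) {
    stop("write_volume: failed to write ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!file.exists(path))
    stop("write_volume: failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Resample a binary mask onto another grid
#'
#' Nearest-neighbour resampling through the composed affine transform
#' (target voxel -> world -> source voxel). Used to carry tumour masks,
#' drawn on a morphological acquisition, into TOF space for overlay
#' rendering; labels are never interpolated.
#'
#' @param mask a [binary_mask()] on its own grid.
#' @param target a [volume_grid()] defining the output geometry.
#' @return A [binary_mask()] with the shape, spacing and affine of `target`.
#' @export
resample_mask_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"), inherits(target, "volume_grid"))
  if (abs(det(mask$affine)) < 1e-12 || abs(det(target$affine)) < 1e-12)
    stop("resample_mask_to_grid: singular affine", call. = FALSE)
  td <- dim(target$data)
  sd <- dim(mask$data)
  # all target voxel indices, 0-based, in (x, y, z) raster order
  ix <- rep.int(seq_len(td[1]) - 1L, td[2] * td[3])
  iy <- rep.int(rep(seq_len(td[2]) - 1L, each = td[1]), td[3])
  iz <- rep(seq_len(td[3]) - 1L, each = td[1] * td[2])
  m <- solve(mask$affine) %*% target$affine
  sx <- m[1, 1] * ix + m[1, 2] * iy + m[1, 3] * iz + m[1, 4]
  sy <- m[2, 1] * ix + m[2, 2] * iy + m[2, 3] * iz + m[2, 4]
  sz <- m[3, 1] * ix + m[3, 2] * iy + m[3, 3] * iz + m[3, 4]
  rx <- as.integer(round(sx)); ry <- as.integer(round(sy))
  rz <- as.integer(round(sz))
  inside <- rx >= 0L & rx < sd[1] & ry >= 0L & ry < sd[2] &
            rz >= 0L & rz < sd[3]
  out <- logical(prod(td))
  lin <- rx[inside] + sd[1] * (ry[inside] + sd[2] * rz[inside]) + 1L
  out[inside] <- as.vector(mask$data)[lin]
  binary_mask(array(out, dim = td), spacing = target$spacing,
              affine = target$affine)
}

#' Read a per-animal endpoint table
#'
#' Reads an RFC-4180 CSV with at least `animal_id` and `group` columns;
#' all remaining columns are parsed as numeric endpoints, blank cells
#' becoming `NA`.
#'
#' @param path path to the CSV file.
#' @param groups optional character vector of allowed group labels.
#' @return A `data.frame` with character `animal_id`/`group` and numeric
#'   endpoint columns.
#' @export
read_animal_table <- function(path, groups = NULL) {
  if (!file.exists(path))
    stop("read_animal_table: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = c("", "NA"))
  for (req in c("animal_id", "group"))
    if (!req %in% names(df))
      stop("read_animal_table: required column `", req, "` is missing",
           call. = FALSE)
  df$animal_id <- as.character(df$animal_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$animal_id))
    stop("read_animal_table: duplicate animal_id rows", call. = FALSE)
  if (!is.null(groups) && !all(df$group %in% groups))
    stop("read_animal_table: group labels outside declared set: ",
         paste(setdiff(df$group, groups), collapse = ", "), call. = FALSE)
  endpoint_cols <- setdiff(names(df), c("animal_id", "group"))
  for (col in endpoint_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & is.na(v)
    if (any(bad))
      stop("read_animal_table: non-numeric value(s) in endpoint column `",
           col, "`", call. = FALSE)
    df[[col]] <- v
  }
  df
}
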