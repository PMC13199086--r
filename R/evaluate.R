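#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}

#' Centerline precision and recall at a physical tolerance
#'
#' Precision: fraction of predicted skeleton voxels lying within
#' `tolerance_mm` (Euclidean, physical units) of any true centreline
#' voxel. Recall: fraction of true centreline voxels within the tolerance
#' of any predicted voxel. The default tolerance of twice the largest
#' voxel dimension absorbs the one-voxel jitter expected from thinning.
#'
#' @param pred,truth [binary_mask()]s on the same grid.
#' @param tolerance_mm matching tolerance in mm.
#' @return A list: `precision`, `recall` (precision is `NA` when the
#'   prediction is empty).
#' @export
centerline_precision_recall <- function(pred, truth,
                                        tolerance_mm = 2 * max(pred$spacing)) {
  stop_if_grid_mismatch(pred, truth, "masks")
  stopifnot(tolerance_mm >= 0)
  if (!any(truth$data))
    stop("centerline_precision_recall: empty truth centreline",
         call. = FALSE)
  if (!any(pred$data))
    return(list(precision = NA_real_, recall = 0))
  d_to_truth <- distance_to_mask(truth$data, truth$spacing)
  d_to_pred <- distance_to_mask(pred$data, pred$spacing)
  tol <- tolerance_mm + 1e-9
  list(precision = mean(d_to_truth[pred$data] <= tol),
       recall = mean(d_to_pred[truth$data] <= tol))
}

# Nearest true-centreline voxel for each predicted voxel, within tolerance.
# Chunked brute force in physical units; ties broken by the lexicographic
# (z,y,x) order of the truth voxels. Returns index into the truth list or
# NA when nothing lies within tolerance.
match_to_truth <- function(pred_coords, truth_coords, spacing,
                           tolerance_mm, chunk = 512L) {
  ord <- order(truth_coords[, 3], truth_coords[, 2], truth_coords[, 1])
  tc <- truth_coords[ord, , drop = FALSE]
  tw <- sweep(tc - 1, 2, spacing, `*`)
  np <- nrow(pred_coords)
  out <- rep(NA_integer_, np)
  tol2 <- (tolerance_mm + 1e-9)^2
  for (s in seq(1, np, by = chunk)) {
    e <- min(np, s + chunk - 1L)
    pw <- sweep(pred_coords[s:e, , drop = FALSE] - 1, 2, spacing, `*`)
    d2 <- outer(rowSums(pw^2), rowSums(tw^2), `+`) - 2 * pw %*% t(tw)
    best <- max.col(-d2, ties.method = "first")
    bd <- d2[cbind(seq_len(e - s + 1L), best)]
    hit <- bd <= tol2
    out[(s:e)[hit]] <- ord[best[hit]]
  }
  out
}

#' Branch-level agreement between predicted and true labelings
#'
#' Each predicted skeleton voxel is matched to its nearest true
#' centreline voxel within `tolerance_mm` (unmatched voxels are excluded
#' and counted); levels are compared after collapsing >= 3 into one
#' class. `trunk_overlap` is the recall of true level-0 voxels by
#' predicted level-0 voxels at the same tolerance.
#'
#' @param pred,truth [branch_labels()] volumes on the same grid (-1 off
#'   the skeleton).
#' @param tolerance_mm matching tolerance in mm.
#' @return A list: `level_confusion` (4 x 4 matrix over classes 0, 1, 2,
#'   3+; rows = true class), `level_accuracy` (`NA` if nothing matched),
#'   `trunk_overlap`, `n_matched`, `n_unmatched`.
#' @export
branch_level_agreement <- function(pred, truth,
                                   tolerance_mm = 2 * max(pred$spacing)) {
  stop_if_grid_mismatch(pred, truth, "label volumes")
  if (!any(truth$data >= 0L))
    stop("branch_level_agreement: empty truth labeling", call. = FALSE)
  collapse <- function(v) pmin(v, 3L)
  classes <- 0:3
  pred_idx <- which(pred$data >= 0L)
  truth_idx <- which(truth$data >= 0L)
  d <- dim(pred$data)
  to_coords <- function(idx) cbind(
    ((idx - 1L) %% d[1]) + 1L,
    (((idx - 1L) %/% d[1]) %% d[2]) + 1L,
    ((idx - 1L) %/% (d[1] * d[2])) + 1L)
  conf <- matrix(0L, 4, 4, dimnames = list(true = c(0:2, "3+"),
                                           pred = c(0:2, "3+")))
  n_matched <- 0L; n_unmatched <- 0L
  if (length(pred_idx) > 0) {
    m <- match_to_truth(to_coords(pred_idx), to_coords(truth_idx),
                        pred$spacing, tolerance_mm)
    ok <- !is.na(m)
    n_matched <- sum(ok); n_unmatched <- sum(!ok)
    if (n_matched > 0) {
      tl <- collapse(truth$data[truth_idx[m[ok]]])
      pl <- collapse(pred$data[pred_idx[ok]])
      for (i in classes) for (j in classes)
        conf[i + 1, j + 1] <- sum(tl == i & pl == j)
    }
  }
  acc <- if (n_matched > 0) sum(diag(conf)) / n_matched else NA_real_
  # trunk overlap: true trunk voxels recalled by the predicted trunk
  t0 <- truth$data == 0L
  p0 <- pred$data == 0L
  trunk_overlap <- if (!any(t0)) NA_real_ else if (!any(p0)) 0 else {
    d0 <- distance_to_mask(p0, pred$spacing)
    mean(d0[t0] <= tolerance_mm + 1e-9)
  }
  list(level_confusion = conf, level_accuracy = acc,
       trunk_overlap = trunk_overlap,
       n_matched = n_matched, n_unmatched = n_unmatched)
}

#' Evaluate a pipeline run against phantom ground truth
#'
#' Convenience wrapper producing one metrics report: vessel-mask Dice,
#' centreline precision/recall, trunk overlap and branch-level agreement.
#'
#' @param vessel_mask predicted vessel [binary_mask()].
#' @param labels predicted [branch_labels()] volume.
#' @param truth a `phantom_truth` bundle.
#' @param tolerance_mm centreline matching tolerance in mm (default twice
#'   the largest voxel dimension).
#' @return A list of class `metrics_report`.
#' @export
evaluate_against_truth <- function(vessel_mask, labels, truth,
                                   tolerance_mm = 2 * max(vessel_mask$spacing)) {
  skel_pred <- with_data(labels, labels$data >= 0L, binary_mask)
  pr <- centerline_precision_recall(skel_pred, truth$centerline_mask,
                                    tolerance_mm)
  ba <- branch_level_agreement(labels, truth$branch_levels, tolerance_mm)
  structure(list(
    dice = dice_coefficient(vessel_mask, truth$vessel_mask),
    centerline_precision = pr$precision,
    centerline_recall = pr$recall,
    trunk_overlap = ba$trunk_overlap,
    level_confusion = ba$level_confusion,
    level_accuracy = ba$level_accuracy,
    n_matched = ba$n_matched, n_unmatched = ba$n_unmatched,
    tolerance_mm = tolerance_mm
  ), class = "metrics_report")
}

#' Group-level descriptive summary of per-animal endpoints
#'
#' Per (group, endpoint): the number of non-missing values, their mean
#' and median — the descriptive summary used for TOF-derived endpoints.
#'
#' @param table a [read_animal_table()] result (or equivalent data frame).
#' @return A `data.frame` with columns `group`, `endpoint`, `n`, `mean`,
#'   `median` (empty-cell groups reported with `n = 0` and `NA` stats).
#' @export
summarize_groups <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("animal_id", "group") %in% names(table)))
  endpoints <- setdiff(names(table), c("animal_id", "group"))
  groups <- unique(table$group)
  rows <- list()
  for (g in groups) for (ep in endpoints) {
    v <- table[[ep]][table$group == g]
    v <- v[!is.na(v)]
    rows[[length(rows) + 1]] <- data.frame(
      group = g, endpoint = ep, n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      median = if (length(v)) stats::median(v) else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
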