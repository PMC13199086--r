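#' Pipeline configuration
#'
#' All tunable parameters of the workflow in one nested, validated
#' structure. The defaults are the frozen analysis configuration; runs
#' echo the fully materialized config into their manifest so every run is
#' reconstructable.
#'
#' @param preprocess a [preprocess_params()].
#' @param vesselness a [vesselness_params()].
#' @param fusion a [fusion_params()].
#' @param segment a [segment_params()].
#' @param evaluate list with `tolerance_mm` (centreline match tolerance).
#' @param seed integer seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_params(),
                            vesselness = vesselness_params(),
                            fusion = fusion_params(),
                            segment = segment_params(),
                            evaluate = list(tolerance_mm = 1.0),
                            seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(vesselness, "vesselness_params"),
            inherits(fusion, "fusion_params"),
            inherits(segment, "segment_params"),
            is.numeric(evaluate$tolerance_mm), evaluate$tolerance_mm >= 0)
  structure(list(preprocess = preprocess, vesselness = vesselness,
                 fusion = fusion, segment = segment, evaluate = evaluate,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Strict: keys that no parameter constructor knows are rejected, so a
#' typo cannot silently fall back to a default. Missing sections take
#' their defaults; the materialized config is what the run manifest
#' echoes.
#'
#' @param path YAML file with any of the sections `preprocess`,
#'   `vesselness`, `fusion`, `segment`, `evaluate`, `seed`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("preprocess", "vesselness", "fusion", "segment", "evaluate",
             "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("read_pipeline_config: unknown section(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) return(fn())
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop("read_pipeline_config: unknown key(s) in `", section, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (section == "fusion" && !is.null(args$weights))
      args$weights <- unlist(args$weights)
    do.call(fn, args)
  }
  ev <- raw$evaluate
  if (is.null(ev)) ev <- list(tolerance_mm = 1.0)
  pipeline_config(
    preprocess = build("preprocess", preprocess_params),
    vesselness = build("vesselness", vesselness_params),
    fusion = build("fusion", fusion_params),
    segment = build("segment", segment_params),
    evaluate = ev,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

pipeline_log <- function(outdir, stage, msg, data = list()) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(outdir)) {
    cat(line, "\n", sep = "", file = file.path(outdir, "pipeline.log"),
        append = TRUE)
    event <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage = stage, message = msg), data)
    cat(jsonlite::toJSON(event, auto_unbox = TRUE), "\n", sep = "",
        file = file.path(outdir, "events.jsonl"), append = TRUE)
  }
}

#' Run the full vessel-analysis workflow
#'
#' Executes, in order: body masking; robust normalization; 3D Gaussian
#' denoising; per-slice normalization; multiscale vesselness; orthogonal
#' support maps and fusion; hybrid Otsu/percentile segmentation;
#' small-component removal; skeletonization; trunk identification and
#' branch-level propagation; QA renders. All volumes, a per-component
#' CSV and a deterministic run manifest are written to `outdir`; wall
#' -clock information goes to the run log only, so two identical runs
#' produce byte-identical manifests. On a stage failure the partial
#' outputs are kept and the manifest carries a `FAILED` marker naming the
#' stage.
#'
#' @param input a [volume_grid()] or a path to a NIfTI volume.
#' @param outdir output directory (created).
#' @param config a [pipeline_config()].
#' @param tumor optional [binary_mask()] or NIfTI path; resampled onto the
#'   input grid for the overlay renders.
#' @return Invisibly, a list with the intermediate and final objects:
#'   `body_mask`, `preprocessed`, `fused`, `vessel_mask`, `skeleton`,
#'   `labels`, `manifest`.
#' @export
run_pipeline <- function(input, outdir, config = pipeline_config(),
                         tumor = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    software = paste0("vesseltrace ",
                      as.character(utils::packageVersion("vesseltrace"))),
    config = unclass_config(config),
    inputs = list())
  stage <- "setup"
  fail <- function(e) {
    manifest$FAILED <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage `", stage, "`: ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    if (is.character(input)) {
      manifest$inputs$volume <- list(path = input,
                                     md5 = unname(tools::md5sum(input)))
      input <- read_volume(input)
    } else manifest$inputs$volume <- list(path = NA, md5 = NA)
    if (is.character(tumor)) {
      manifest$inputs$tumor <- list(path = tumor,
                                    md5 = unname(tools::md5sum(tumor)))
      tumor <- read_volume(tumor)
      tumor <- binary_mask(tumor$data > 0.5, tumor$spacing, tumor$affine)
    }
    if (!is.null(tumor) && !same_grid(tumor, input))
      tumor <- resample_mask_to_grid(tumor, input)

    stage <- "body_mask"
    pipeline_log(outdir, stage, "computing whole-body mask")
    body <- compute_body_mask(input, config$preprocess)
    manifest$counts$body_voxels <- sum(body$data)

    stage <- "preprocess"
    pipeline_log(outdir, stage, "normalize + denoise + per-slice normalize")
    v <- normalize_within_mask(input, body, config$preprocess)
    v <- gaussian_denoise(v, config$preprocess)
    v <- per_slice_normalize(v, body, config$preprocess)

    stage <- "vesselness"
    pipeline_log(outdir, stage,
                 sprintf("multiscale vesselness (%d scales)",
                         length(config$vesselness$scales_mm)))
    vn <- vesselness(v, body, config$vesselness)

    stage <- "fusion"
    pipeline_log(outdir, stage, "orthogonal support maps + weighted fusion")
    sup <- orthogonal_support_maps(vn, config$fusion)
    fused <- fuse_maps(vn, sup, config$fusion)
    manifest$thresholds$fusion_weights <- as.list(config$fusion$weights)

    stage <- "segment"
    pipeline_log(outdir, stage, "hybrid threshold + component cleanup")
    vm <- hybrid_threshold_segment(fused, body, config$segment)
    manifest$thresholds$otsu <- attr(vm, "otsu")
    manifest$thresholds$percentile_value <- attr(vm, "percentile_value")
    manifest$thresholds$threshold_used <- attr(vm, "threshold_used")
    vm <- remove_small_components(vm, config$segment)
    manifest$counts$vessel_voxels <- sum(vm$data)

    stage <- "skeletonize"
    pipeline_log(outdir, stage, "topology-preserving 3D thinning")
    skel <- skeletonize_volume(vm)
    manifest$counts$skeleton_voxels <- sum(skel$data)

    stage <- "branches"
    pipeline_log(outdir, stage, "trunk identification + level propagation")
    sg <- skeleton_to_graph(skel)
    ncomp <- if (nrow(sg$coords) > 0) max(sg$component) else 0L
    trunks <- lapply(seq_len(ncomp), function(cc) identify_trunk(sg, cc))
    pb <- propagate_branch_levels(sg, trunks)
    labels <- pb$labels
    lv <- labels$data[labels$data >= 0L]
    manifest$counts$level_voxels <- as.list(stats::setNames(
      vapply(0:3, function(k) if (k < 3) sum(lv == k) else sum(lv >= 3L),
             numeric(1)),
      c("level0", "level1", "level2", "level3plus")))
    manifest$counts$n_components <- ncomp

    stage <- "write"
    pipeline_log(outdir, stage, "writing volumes + component table")
    write_volume(body, file.path(outdir, "body_mask.nii.gz"))
    write_volume(fused, file.path(outdir, "fused_probability.nii.gz"))
    write_volume(vm, file.path(outdir, "vessel_mask.nii.gz"))
    write_volume(skel, file.path(outdir, "skeleton.nii.gz"))
    write_volume(labels, file.path(outdir, "branch_labels.nii.gz"))
    comp_tab <- component_table(sg, trunks, labels, pb$main_component)
    utils::write.csv(comp_tab, file.path(outdir, "components.csv"),
                     row.names = FALSE)

    stage <- "render"
    pipeline_log(outdir, stage, "QA maximum-intensity projections")
    render_views(input, labels, tumor, outdir = outdir)

    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log(outdir, "done", "pipeline complete")
    invisible(list(body_mask = body, preprocessed = v, fused = fused,
                   vessel_mask = vm, skeleton = skel, labels = labels,
                   graph = sg, trunks = trunks,
                   main_component = pb$main_component,
                   manifest = manifest, outdir = outdir))
  }, error = fail)
}

unclass_config <- function(config) {
  out <- lapply(unclass(config), function(x)
    if (is.list(x)) lapply(unclass(x), identity) else x)
  out$fusion$weights <- as.list(out$fusion$weights)
  out
}

component_table <- function(sg, trunks, labels, main_component) {
  ncomp <- length(trunks)
  if (ncomp == 0)
    return(data.frame(component = integer(0), n_voxels = integer(0),
                      trunk_length_mm = numeric(0)))
  d <- sg$dim
  lin <- sg$coords[, 1] + d[1] * (sg$coords[, 2] - 1L) +
    d[1] * d[2] * (sg$coords[, 3] - 1L)
  lv <- labels$data[lin]
  do.call(rbind, lapply(seq_len(ncomp), function(cc) {
    sel <- sg$component == cc
    data.frame(component = cc, n_voxels = sum(sel),
               trunk_length_mm = trunks[[cc]]$length_mm,
               level0 = sum(sel & lv == 0L), level1 = sum(sel & lv == 1L),
               level2 = sum(sel & lv == 2L),
               level3plus = sum(sel & lv >= 3L),
               is_main_trunk = cc == main_component)
  }))
}

# --- QA renders -----------------------------------------------------------

# grayscale MIP along an axis, [0,1]
mip_gray <- function(arr, axis) {
  apply(arr, setdiff(1:3, axis), max)
}

# label MIP: per ray the smallest nonnegative level (trunk priority)
mip_label <- function(lab, axis) {
  tmp <- lab
  tmp[tmp < 0L] <- 99L
  m <- apply(tmp, setdiff(1:3, axis), min)
  m[m == 99L] <- -1L
  m
}

rgb_panel <- function(gray, lab_mip, tumor_mip = NULL,
                      scheme = branch_color_scheme()) {
  g <- gray / max(gray, 1e-12)
  h <- dim(g)[1]; w <- dim(g)[2]
  img <- array(rep(g, 3), dim = c(h, w, 3))
  paint <- function(img, sel, col) {
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[sel] <- col[ch]; img[, , ch] <- pl
    }
    img
  }
  if (!is.null(tumor_mip)) img <- paint(img, tumor_mip, scheme$tumor)
  img <- paint(img, lab_mip == 0L, scheme$trunk)
  img <- paint(img, lab_mip == 1L, scheme$level1)
  img <- paint(img, lab_mip == 2L, scheme$level2)
  img <- paint(img, lab_mip >= 3L, scheme$higher)
  img
}

# nearest-neighbour aspect correction: repeat rows/cols so pixels are
# roughly isotropic in mm
aspect_fix <- function(img2d, spacing2) {
  f <- pmax(1L, as.integer(round(spacing2 / min(spacing2))))
  img2d[rep(seq_len(dim(img2d)[1]), each = f[1]),
        rep(seq_len(dim(img2d)[2]), each = f[2]), , drop = FALSE]
}

# sheared volume for the angled view: slice z shifted along y by z/2
shear_volume <- function(arr, fill) {
  d <- dim(arr)
  sh <- as.integer(round((seq_len(d[3]) - 1) / 2))
  ny <- d[2] + max(sh)
  out <- array(fill, dim = c(d[1], ny, d[3]))
  for (z in seq_len(d[3]))
    out[, sh[z] + seq_len(d[2]), z] <- arr[, , z]
  out
}

#' Render standardized QA views
#'
#' Maximum-intensity projections of the grayscale volume along each axis
#' with the branch-level color overlay (trunk red, level 1 green, level 2
#' blue, level >= 3 magenta, tumor purple painted beneath), plus an
#' oblique sheared projection as the angled view. Output pixels are
#' deterministic for fixed inputs.
#'
#' @param volume a [volume_grid()].
#' @param labels a [branch_labels()] volume on the same grid.
#' @param tumor optional [binary_mask()] on the same grid.
#' @param outdir directory receiving `mip_top.png`, `mip_side_x.png`,
#'   `mip_side_y.png`, `mip_angled.png`.
#' @return Invisibly, the vector of written paths.
#' @export
render_views <- function(volume, labels, tumor = NULL, outdir = ".") {
  stop_if_grid_mismatch(volume, labels, "volume and labels")
  if (!is.null(tumor)) stop_if_grid_mismatch(volume, tumor,
                                             "volume and tumor")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sp <- volume$spacing
  views <- list(top = 3L, side_x = 1L, side_y = 2L)
  paths <- character(0)
  for (nm in names(views)) {
    ax <- views[[nm]]
    g <- mip_gray(volume$data, ax)
    l <- mip_label(labels$data, ax)
    tm <- if (!is.null(tumor)) apply(tumor$data, setdiff(1:3, ax), any)
    img <- rgb_panel(g, l, tm)
    img <- aspect_fix(img, sp[setdiff(1:3, ax)])
    p <- file.path(outdir, paste0("mip_", nm, ".png"))
    png::writePNG(aperm(img, c(2, 1, 3)), p)
    paths <- c(paths, p)
  }
  # angled view: shear then project along z
  gv <- shear_volume(volume$data, 0)
  lv <- shear_volume(labels$data, -1L)
  tv <- if (!is.null(tumor)) shear_volume(tumor$data, FALSE)
  img <- rgb_panel(mip_gray(gv, 3L), mip_label(lv, 3L),
                   if (!is.null(tv)) apply(tv, 1:2, any))
  img <- aspect_fix(img, sp[1:2])
  p <- file.path(outdir, "mip_angled.png")
  png::writePNG(aperm(img, c(2, 1, 3)), p)
  invisible(c(paths, p))
}
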