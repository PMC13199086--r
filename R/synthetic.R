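#' Vessel-tree sampling parameters
#'
#' Recursive binary bifurcation from a root segment. Children are tilted
#' away from the parent direction by sampled angles and scaled in length
#' and radius; the first child continues the parent (small angle, mild
#' taper), the second is a side branch (larger angle, stronger taper), the
#' side-branching pattern typical of an aorta with emerging side vessels.
#' The default radius ratios (0.85, 0.71) satisfy Murray's law
#' (0.85^3 + 0.71^3 ~= 1); the balanced special case would be
#' 2^(-1/3) ~= 0.794 for both children. The side length ratio (0.3) keeps
#' every side chain shorter than the trunk it emerges from
#' (0.3 * (1 + 0.8 + 0.8^2 + 0.8^3) < 1), so the principal vessel path of
#' the phantom is geometrically unambiguous. Recursion stops at
#' `max_depth` or when the child radius falls below `min_radius_mm`.
#'
#' @param root_start_mm,root_direction world-space start (mm) and unit
#'   direction of the root segment.
#' @param root_length_mm,root_radius_mm root segment geometry in mm.
#' @param angle_mean_deg,angle_sd_deg per-child mean tilt from the parent
#'   direction and common SD, degrees.
#' @param length_ratio per-child expected child/parent length ratio.
#' @param length_sd_frac SD of the child length as a fraction of its mean.
#' @param radius_ratio per-child child/parent radius ratio.
#' @param max_depth maximum bifurcation depth (root = depth 0).
#' @param min_radius_mm radius floor; thinner children are not generated.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(root_start_mm = c(0, 0, 0),
                        root_direction = c(0, 0, 1),
                        root_length_mm = 10, root_radius_mm = 0.5,
                        angle_mean_deg = c(12, 50), angle_sd_deg = 4,
                        length_ratio = c(0.8, 0.3),
                        length_sd_frac = 0.08,
                        radius_ratio = c(0.85, 0.71),
                        max_depth = 4L, min_radius_mm = 0.1) {
  stopifnot(root_length_mm > 0, root_radius_mm > 0, min_radius_mm > 0,
            max_depth >= 0, length(angle_mean_deg) == 2,
            length(length_ratio) == 2, length(radius_ratio) == 2,
            all(radius_ratio > 0), all(radius_ratio <= 1),
            all(length_ratio > 0))
  structure(list(root_start_mm = as.numeric(root_start_mm),
                 root_direction = root_direction / sqrt(sum(root_direction^2)),
                 root_length_mm = root_length_mm,
                 root_radius_mm = root_radius_mm,
                 angle_mean_deg = angle_mean_deg,
                 angle_sd_deg = angle_sd_deg,
                 length_ratio = length_ratio,
                 length_sd_frac = length_sd_frac,
                 radius_ratio = radius_ratio,
                 max_depth = as.integer(max_depth),
                 min_radius_mm = min_radius_mm),
            class = "tree_params")
}

# unit vector orthogonal pair spanning the plane normal to w
orthobasis <- function(w) {
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v)
}

#' Sample a branching vessel tree
#'
#' Deterministic for a given seed: the same `(seed, params)` pair always
#' yields byte-identical segment tables.
#'
#' @param seed integer RNG seed.
#' @param params a [tree_params()].
#' @return A `data.frame` of class `vessel_tree`: columns `id`,
#'   `parent_id` (`NA` for the root), `depth`, start/end coordinates in mm
#'   (`x0, y0, z0, x1, y1, z1`) and `radius_mm`.
#' @export
sample_vessel_tree <- function(seed, params = tree_params()) {
  stopifnot(inherits(params, "tree_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rows <- list()
  nid <- 0L
  grow <- function(parent_id, depth, start, dir, len, radius) {
    nid <<- nid + 1L
    id <- nid
    end <- start + len * dir
    rows[[id]] <<- data.frame(id = id, parent_id = parent_id, depth = depth,
                              x0 = start[1], y0 = start[2], z0 = start[3],
                              x1 = end[1], y1 = end[2], z1 = end[3],
                              radius_mm = radius)
    if (depth >= params$max_depth) return(invisible(NULL))
    ob <- orthobasis(dir)
    phi0 <- stats::runif(1, 0, 2 * pi)
    for (child in 1:2) {
      r2 <- radius * params$radius_ratio[child]
      if (r2 < params$min_radius_mm) next
      ang <- abs(stats::rnorm(1, params$angle_mean_deg[child],
                              params$angle_sd_deg)) * pi / 180
      phi <- if (child == 1) phi0 else
        phi0 + pi + stats::rnorm(1, 0, 0.4)
      cdir <- cos(ang) * dir +
        sin(ang) * (cos(phi) * ob$u + sin(phi) * ob$v)
      cdir <- cdir / sqrt(sum(cdir^2))
      mu <- len * params$length_ratio[child]
      clen <- max(0.2 * mu,
                  stats::rnorm(1, mu, params$length_sd_frac * mu))
      grow(id, depth + 1L, end, cdir, clen, r2)
    }
    invisible(NULL)
  }
  grow(NA_integer_, 0L, params$root_start_mm, params$root_direction,
       params$root_length_mm, params$root_radius_mm)
  tree <- do.call(rbind, rows)
  rownames(tree) <- NULL
  class(tree) <- c("vessel_tree", class(tree))
  tree
}

# Recursive branch-order levels of tree segments: trunk (level 0) is the
# maximum-length path in the segment graph; each subtree hanging off it
# gets its principal path as level 1, and so on -- mirroring
# propagate_branch_levels() on the voxel skeleton.
tree_segment_levels <- function(tree) {
  nseg <- nrow(tree)
  # nodes: 1 = root start, node i+1 = end of segment i
  ends_of <- function(i) {
    p <- tree$parent_id[i]
    c(if (is.na(p)) 1L else p + 1L, i + 1L)
  }
  g <- igraph::make_empty_graph(n = nseg + 1L, directed = FALSE)
  el <- t(vapply(seq_len(nseg), ends_of, integer(2)))
  g <- igraph::add_edges(g, t(el))
  seglen <- sqrt((tree$x1 - tree$x0)^2 + (tree$y1 - tree$y0)^2 +
                 (tree$z1 - tree$z0)^2)
  igraph::E(g)$weight <- seglen
  igraph::E(g)$seg <- seq_len(nseg)
  levels <- rep(NA_integer_, nseg)
  # principal path from anchor node set; returns the segment ids on it
  principal <- function(sub_edges, anchors) {
    sg <- igraph::subgraph_from_edges(g, sub_edges, delete.vertices = FALSE)
    dd <- igraph::distances(sg, v = anchors)
    dd[is.infinite(dd)] <- -1
    dmin <- apply(dd, 2, min)
    reach <- which(dmin >= 0)
    far <- reach[which.max(dmin[reach])]
    s_best <- anchors[which.min(dd[, far])]
    ep <- igraph::shortest_paths(sg, from = s_best, to = far,
                                 output = "epath")$epath[[1]]
    igraph::E(sg)$seg[as.integer(ep)]
  }
  # trunk: diameter of the whole tree (two sweeps)
  dall <- igraph::distances(g, v = 1)
  a <- which.max(dall[1, ])
  da <- igraph::distances(g, v = a)
  b <- which.max(da[1, ])
  trunk_edges <- igraph::E(g)$seg[as.integer(
    igraph::shortest_paths(g, from = a, to = b, output = "epath")$epath[[1]])]
  levels[trunk_edges] <- 0L
  stack <- list(list(branch = trunk_edges, level = 1L))
  while (length(stack) > 0) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    anchor_nodes <- unique(as.vector(el[item$branch, ]))
    rem <- which(is.na(levels))
    if (length(rem) == 0) break
    att <- rem[el[rem, 1] %in% anchor_nodes | el[rem, 2] %in% anchor_nodes]
    if (length(att) == 0) next
    sgr <- igraph::subgraph_from_edges(g, rem, delete.vertices = FALSE)
    mem <- igraph::components(sgr)$membership
    part_of <- function(i) mem[el[i, 1]]
    for (pc in unique(vapply(att, part_of, numeric(1)))) {
      part <- rem[vapply(rem, part_of, numeric(1)) == pc]
      anchors <- intersect(unique(as.vector(el[part, ])), anchor_nodes)
      br <- principal(part, anchors)
      levels[br] <- item$level
      stack[[length(stack) + 1]] <- list(branch = br,
                                         level = item$level + 1L)
    }
  }
  stopifnot(!anyNA(levels))
  levels
}

#' Voxelize a vessel tree onto a grid
#'
#' The vessel mask is the union of capsules (cylinders with hemispherical
#' caps) around each segment; the centreline mask marks the voxels nearest
#' each segment axis (a 26-connected chain per segment); branch levels
#' follow the tree topology with the ground-truth trunk defined exactly as
#' the pipeline defines it — the maximum-physical-length path through the
#' centreline — and levels counting detachment depth from it. Segments
#' thinner than half the largest voxel dimension cannot be resolved by the
#' grid and are rendered as their centreline (with a warning); segments
#' leaving the grid are clipped.
#'
#' @param tree a [sample_vessel_tree()] result.
#' @param grid a [volume_grid()] supplying geometry (data ignored).
#' @return A list: `vessel_mask`, `centerline_mask` ([binary_mask()]s) and
#'   `branch_levels` (a [branch_labels()] volume, -1 off the centreline).
#' @export
voxelize_tree <- function(tree, grid) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(grid, "volume_grid"))
  d <- dim(grid$data)
  sp <- grid$spacing
  vessel <- array(FALSE, d)
  center <- array(FALSE, d)
  seg_of_center <- array(0L, d)
  thin_limit <- max(sp) / 2
  thin_segs <- tree$radius_mm < thin_limit
  if (any(thin_segs))
    warning("voxelize_tree: ", sum(thin_segs), " segment(s) thinner than ",
            "half the largest voxel dimension; rendered as centreline only")
  clipped <- FALSE
  world_min <- c(0, 0, 0)  # voxel centres at (i + 0) * spacing per affine
  for (i in seq_len(nrow(tree))) {
    p0 <- c(tree$x0[i], tree$y0[i], tree$z0[i])
    p1 <- c(tree$x1[i], tree$y1[i], tree$z1[i])
    r <- tree$radius_mm[i]
    # capsule bounding box in voxel indices
    lo <- pmax(1L, as.integer(floor((pmin(p0, p1) - r) / sp)) + 1L - 1L)
    hi <- pmin(d, as.integer(ceiling((pmax(p0, p1) + r) / sp)) + 1L + 1L)
    lo <- pmax(lo, 1L)
    if (any(lo > hi)) { clipped <- TRUE; next }
    if (any(pmin(p0, p1) - r < -sp * 2) ||
        any(pmax(p0, p1) + r > (d - 1) * sp + sp * 2)) clipped <- TRUE
    if (!thin_segs[i]) {
      xs <- (seq(lo[1], hi[1]) - 1) * sp[1]
      ys <- (seq(lo[2], hi[2]) - 1) * sp[2]
      zs <- (seq(lo[3], hi[3]) - 1) * sp[3]
      nb <- c(length(xs), length(ys), length(zs))
      px <- rep.int(xs, nb[2] * nb[3])
      py <- rep.int(rep(ys, each = nb[1]), nb[3])
      pz <- rep(zs, each = nb[1] * nb[2])
      # point-to-segment distance
      v <- p1 - p0
      vv <- sum(v^2)
      t <- ((px - p0[1]) * v[1] + (py - p0[2]) * v[2] +
            (pz - p0[3]) * v[3]) / vv
      t <- pmin(pmax(t, 0), 1)
      dx <- px - (p0[1] + t * v[1])
      dy <- py - (p0[2] + t * v[2])
      dz <- pz - (p0[3] + t * v[3])
      inside <- dx * dx + dy * dy + dz * dz <= r * r
      if (any(inside)) {
        block <- array(inside, dim = nb)
        vessel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          vessel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | block
      }
    }
    # centreline: dense samples along the axis snapped to nearest voxels
    seglen <- sqrt(vv <- sum((p1 - p0)^2))
    nstep <- max(2L, as.integer(ceiling(sqrt(sum((p1 - p0)^2)) /
                                          (0.25 * min(sp)))))
    tt <- seq(0, 1, length.out = nstep)
    cx <- as.integer(round((p0[1] + tt * (p1[1] - p0[1])) / sp[1])) + 1L
    cy <- as.integer(round((p0[2] + tt * (p1[2] - p0[2])) / sp[2])) + 1L
    cz <- as.integer(round((p0[3] + tt * (p1[3] - p0[3])) / sp[3])) + 1L
    ok <- cx >= 1L & cx <= d[1] & cy >= 1L & cy <= d[2] &
          cz >= 1L & cz <= d[3]
    if (!all(ok)) clipped <- TRUE
    lin <- cx[ok] + d[1] * (cy[ok] - 1L) + d[1] * d[2] * (cz[ok] - 1L)
    center[lin] <- TRUE
    seg_of_center[lin] <- i
  }
  if (clipped)
    warning("voxelize_tree: tree extends beyond the grid; clipped")
  vessel <- vessel | center
  seg_levels <- tree_segment_levels(tree)
  lab <- array(-1L, d)
  lab[center] <- seg_levels[seg_of_center[center]]
  list(vessel_mask = binary_mask(vessel, sp, grid$affine),
       centerline_mask = binary_mask(center, sp, grid$affine),
       branch_levels = branch_labels(lab, sp, grid$affine))
}

#' TOF intensity simulation parameters
#'
#' @param body_level,vessel_level tissue and inflow-bright vessel signal
#'   levels (arbitrary units); vessel must exceed body, as TOF inflow
#'   contrast is positive by construction.
#' @param edge_softness_vox width (in-plane voxels) of the tanh
#'   partial-volume ramp at the vessel boundary.
#' @param drift_amplitude amplitude `a` of the per-slice multiplicative
#'   drift; slice factors stay within `[1-a, 1+a]`.
#' @param noise_sigma additive noise SD.
#' @param noise_model `"gaussian"` (analytic transparency) or `"rician"`
#'   (magnitude-MR noise).
#' @return A list of class `tof_params`.
#' @export
tof_params <- function(body_level = 0.3, vessel_level = 0.9,
                       edge_softness_vox = 1, drift_amplitude = 0.2,
                       noise_sigma = 0.05,
                       noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (vessel_level <= body_level)
    stop("tof_params: vessel level must exceed body level ",
         "(TOF inflow contrast is positive)", call. = FALSE)
  stopifnot(drift_amplitude >= 0, drift_amplitude < 1, noise_sigma >= 0,
            edge_softness_vox > 0)
  structure(list(body_level = body_level, vessel_level = vessel_level,
                 edge_softness_vox = edge_softness_vox,
                 drift_amplitude = drift_amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model),
            class = "tof_params")
}

# smooth bounded random walk in [1-a, 1+a], length nz
slice_drift_profile <- function(nz, a) {
  if (a == 0 || nz < 2) return(rep(1, nz))
  steps <- stats::rnorm(nz)
  walk <- cumsum(steps)
  k <- gauss_kernels(max(1, nz / 12))
  pad <- (length(k) - 1) / 2
  walkp <- c(rep(walk[1], pad), walk, rep(walk[nz], pad))
  sm <- as.vector(stats::filter(walkp, k, sides = 2))[pad + seq_len(nz)]
  sm <- sm - mean(sm)
  m <- max(abs(sm))
  if (m == 0) return(rep(1, nz))
  1 + a * sm / m
}

#' Simulate a TOF-like magnitude volume with ground truth
#'
#' Builds a body ellipsoid at `body_level` on a dark background, paints
#' the voxelized vessel tree at `vessel_level` with a tanh partial-volume
#' ramp at its boundary, multiplies each axial slice by a smooth bounded
#' random drift factor (emulating the slice crosstalk/saturation of
#' sequential-excitation multi-slice TOF), and adds seeded noise. A
#' mask-only ellipsoidal tumor is placed beside a mid-tree segment. The
#' same `(seed, tree, params)` always yields the identical volume.
#'
#' @param tree a [sample_vessel_tree()] result.
#' @param grid a [volume_grid()] supplying the geometry.
#' @param params a [tof_params()].
#' @param seed integer RNG seed for drift and noise.
#' @param body_semiaxes_mm,body_center_mm ellipsoid geometry; defaults to
#'   an ellipsoid filling most of the grid.
#' @return A list of class `phantom_truth`: `volume`, `body_mask`,
#'   `vessel_mask`, `centerline_mask`, `branch_levels`, `tumor_mask`,
#'   `slice_drift`, `noise_sigma`, `seed`, `tree`.
#' @export
simulate_tof_volume <- function(tree, grid, params = tof_params(),
                                seed = 1L,
                                body_semiaxes_mm = NULL,
                                body_center_mm = NULL) {
  stopifnot(inherits(params, "tof_params"))
  d <- dim(grid$data)
  sp <- grid$spacing
  extent <- (d - 1) * sp
  if (is.null(body_center_mm)) body_center_mm <- extent / 2
  if (is.null(body_semiaxes_mm))
    body_semiaxes_mm <- c(0.42, 0.42, 0.47) * extent
  vox <- voxelize_tree(tree, grid)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  ex <- ((xs - body_center_mm[1]) / body_semiaxes_mm[1])^2
  ey <- ((ys - body_center_mm[2]) / body_semiaxes_mm[2])^2
  ez <- ((zs - body_center_mm[3]) / body_semiaxes_mm[3])^2
  body <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  vessel <- vox$vessel_mask$data & body
  center <- vox$centerline_mask$data & body & vessel
  lab <- vox$branch_levels$data
  lab[!center] <- -1L
  # soft vessel profile from the signed distance to the vessel surface
  soft_mm <- params$edge_softness_vox * min(sp)
  d_out <- distance_to_mask(vessel, sp)
  d_in <- distance_to_mask(!vessel, sp)
  signed <- ifelse(is.finite(d_out), d_out, 0) -
    ifelse(is.finite(d_in), d_in, 0)
  w <- 0.5 * (1 - tanh(signed / soft_mm))
  vol <- params$body_level * body +
    (params$vessel_level - params$body_level) * w * body
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  m_z <- slice_drift_profile(d[3], params$drift_amplitude)
  vol <- sweep(vol, 3, m_z, `*`)
  if (params$noise_sigma > 0) {
    if (params$noise_model == "gaussian") {
      vol <- vol + array(stats::rnorm(prod(d), 0, params$noise_sigma), d)
    } else {
      n1 <- array(stats::rnorm(prod(d), 0, params$noise_sigma), d)
      n2 <- array(stats::rnorm(prod(d), 0, params$noise_sigma), d)
      vol <- sqrt((vol + n1)^2 + n2^2)
    }
  }
  # mask-only tumor: ellipsoid beside a mid-depth segment
  tumor <- array(FALSE, d)
  mid <- which(tree$depth == max(1L, floor(max(tree$depth) / 2)))[1]
  if (!is.na(mid)) {
    tc <- c(tree$x1[mid], tree$y1[mid], tree$z1[mid]) +
      c(1.5, 1.5, 0) * tree$radius_mm[mid] + c(1, 1, 0)
    tr_ax <- pmax(1.5 * sp, 0.08 * extent)
    tx <- ((xs - tc[1]) / tr_ax[1])^2
    ty <- ((ys - tc[2]) / tr_ax[2])^2
    tz <- ((zs - tc[3]) / tr_ax[3])^2
    tumor <- (outer(outer(tx, ty, `+`), tz, `+`) <= 1) & body
  }
  structure(list(
    volume = volume_grid(vol, sp, grid$affine),
    body_mask = binary_mask(body, sp, grid$affine),
    vessel_mask = binary_mask(vessel, sp, grid$affine),
    centerline_mask = binary_mask(center, sp, grid$affine),
    branch_levels = branch_labels(lab, sp, grid$affine),
    tumor_mask = binary_mask(tumor, sp, grid$affine),
    slice_drift = m_z, noise_sigma = params$noise_sigma,
    seed = as.integer(seed), tree = tree
  ), class = "phantom_truth")
}

#' Acquisition-geometry report
#'
#' Derived numbers of the emulated 2D multi-slice FLASH-TOF geometry:
#' in-plane resolution (field of view / reconstruction matrix) and the
#' slice overlap implied by an interslice distance smaller than the slice
#' thickness.
#'
#' @param fov_mm in-plane field of view, mm.
#' @param matrix_size reconstruction matrix (per in-plane axis).
#' @param slice_thickness_mm excited slice thickness, mm.
#' @param interslice_mm distance between consecutive slice centres, mm.
#' @return A list: `in_plane_mm`, `slice_thickness_mm`, `interslice_mm`,
#'   `overlap_mm`, `overlap_percent`.
#' @export
tof_geometry_report <- function(fov_mm = 30, matrix_size = 256,
                                slice_thickness_mm = 0.5,
                                interslice_mm = 0.3) {
  stopifnot(fov_mm > 0, matrix_size > 0, slice_thickness_mm > 0,
            interslice_mm > 0)
  overlap <- slice_thickness_mm - interslice_mm
  list(in_plane_mm = fov_mm / matrix_size,
       slice_thickness_mm = slice_thickness_mm,
       interslice_mm = interslice_mm,
       overlap_mm = overlap,
       overlap_percent = 100 * overlap / slice_thickness_mm)
}

#' Phantom presets
#'
#' `small`: 64^3 isotropic 0.25 mm grid with a depth-2 tree (fast,
#' used throughout the test-suite). `default`: 128 x 128 x 96 grid at the
#' emulated acquisition spacing (0.117, 0.117, 0.5) mm with a depth-4
#' tree. `stress`: the default grid with a depth-6 tree and doubled noise.
#'
#' @param preset one of `"small"`, `"default"`, `"stress"`.
#' @return A list with `dim`, `spacing`, `tree` ([tree_params()]) and
#'   `tof` ([tof_params()]).
#' @export
phantom_preset <- function(preset = c("small", "default", "stress")) {
  preset <- match.arg(preset)
  if (preset == "small") {
    dims <- c(64L, 64L, 64L)
    sp <- c(0.25, 0.25, 0.25)
    tp <- tree_params(root_start_mm = c(7.875, 7.875, 1.6),
                      root_length_mm = 5.5, root_radius_mm = 0.55,
                      max_depth = 2L, min_radius_mm = 0.15)
    ip <- tof_params()
  } else if (preset == "default") {
    dims <- c(128L, 128L, 96L)
    sp <- c(0.117, 0.117, 0.5)
    tp <- tree_params(root_start_mm = c(7.4295, 7.4295, 4.5),
                      root_length_mm = 13, root_radius_mm = 0.5,
                      max_depth = 4L, min_radius_mm = 0.12)
    ip <- tof_params()
  } else {
    dims <- c(128L, 128L, 96L)
    sp <- c(0.117, 0.117, 0.5)
    tp <- tree_params(root_start_mm = c(7.4295, 7.4295, 4.5),
                      root_length_mm = 13, root_radius_mm = 0.5,
                      max_depth = 6L, min_radius_mm = 0.08)
    ip <- tof_params(noise_sigma = 0.1)
  }
  list(dim = dims, spacing = sp, tree = tp, tof = ip)
}

#' Build a complete phantom bundle
#'
#' Convenience composition of [sample_vessel_tree()], [voxelize_tree()]
#' and [simulate_tof_volume()] for a named preset; optionally writes all
#' truth volumes as NIfTI plus a JSON manifest.
#'
#' @param seed integer RNG seed (tree and intensity noise).
#' @param preset see [phantom_preset()].
#' @param outdir optional output directory; when given, all truth
#'   artifacts and a `phantom_manifest.json` are written there.
#' @return A `phantom_truth` list (see [simulate_tof_volume()]).
#' @export
make_phantom_bundle <- function(seed = 1L,
                                preset = c("small", "default", "stress"),
                                outdir = NULL) {
  preset <- match.arg(preset)
  ps <- phantom_preset(preset)
  grid <- volume_grid(array(0, ps$dim), spacing = ps$spacing)
  tree <- sample_vessel_tree(seed, ps$tree)
  truth <- simulate_tof_volume(tree, grid, ps$tof, seed = seed + 1L)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_volume(truth$volume, file.path(outdir, "volume.nii.gz"))
    write_volume(truth$body_mask, file.path(outdir, "body_mask.nii.gz"))
    write_volume(truth$vessel_mask, file.path(outdir, "vessel_mask.nii.gz"))
    write_volume(truth$centerline_mask,
                 file.path(outdir, "centerline_mask.nii.gz"))
    write_volume(truth$branch_levels,
                 file.path(outdir, "branch_levels.nii.gz"))
    write_volume(truth$tumor_mask, file.path(outdir, "tumor_mask.nii.gz"))
    manifest <- list(seed = seed, preset = preset, dim = ps$dim,
                     spacing_mm = ps$spacing,
                     geometry = tof_geometry_report(),
                     noise_sigma = truth$noise_sigma,
                     slice_drift = truth$slice_drift,
                     n_segments = nrow(tree))
    jsonlite::write_json(manifest, file.path(outdir,
                                             "phantom_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  truth
}
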