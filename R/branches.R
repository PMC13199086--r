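#' Convert a skeleton mask into a voxel-resolution graph
#'
#' One node per skeleton voxel; one undirected edge for every pair of
#' 26-adjacent skeleton voxels, weighted by the physical distance between
#' voxel centres (so axis steps weigh `sx`, `sy` or `sz` and diagonal
#' steps their 2- or 3-axis combinations). Connected components are
#' labeled on the same 26-connectivity.
#'
#' @param skeleton a [binary_mask()] holding the skeleton.
#' @param spacing per-axis voxel size in mm; defaults to the mask's.
#' @return A list of class `skeleton_graph`: `coords` (n x 3 integer,
#'   1-based voxel indices), `graph` (an igraph with `weight` edge
#'   attribute in mm), `component` (integer membership per node), plus the
#'   grid geometry (`dim`, `spacing`, `affine`).
#' @export
skeleton_to_graph <- function(skeleton, spacing = skeleton$spacing) {
  stopifnot(inherits(skeleton, "binary_mask"))
  d <- dim(skeleton$data)
  idx <- which(skeleton$data)
  n <- length(idx)
  coords <- cbind(
    x = ((idx - 1L) %% d[1]) + 1L,
    y = (((idx - 1L) %/% d[1]) %% d[2]) + 1L,
    z = ((idx - 1L) %/% (d[1] * d[2])) + 1L
  )
  node_of <- integer(prod(d))
  node_of[idx] <- seq_len(n)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  # half the offsets suffice for undirected edges
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 |
               (offs$dy == 0 & offs$dx > 0))), ]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  if (n > 0) {
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      nx <- coords[, 1] + o$dx; ny <- coords[, 2] + o$dy
      nz <- coords[, 3] + o$dz
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
            nz >= 1L & nz <= d[3]
      lin <- nx[ok] + d[1] * (ny[ok] - 1L) + d[1] * d[2] * (nz[ok] - 1L)
      nb <- node_of[lin]
      hit <- nb > 0L
      if (!any(hit)) next
      from <- c(from, which(ok)[hit])
      to <- c(to, nb[hit])
      len <- c(len, rep(sqrt(sum((c(o$dx, o$dy, o$dz) * spacing)^2)),
                        sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$weight <- len
  }
  comp <- if (n > 0) igraph::components(g)$membership else integer(0)
  structure(list(coords = coords, graph = g, component = as.integer(comp),
                 dim = d, spacing = spacing, affine = skeleton$affine),
            class = "skeleton_graph")
}

# Deterministic lexicographic node order on (z, y, x).
node_lex_rank <- function(coords) {
  order(order(coords[, 3], coords[, 2], coords[, 1]))
}

# Kruskal MST restricted to one component; edges sorted by length then by
# the lexicographic (z,y,x) rank of their endpoints. Returns an edge matrix.
component_mst <- function(sg, nodes) {
  sub <- igraph::induced_subgraph(sg$graph, nodes)
  el <- igraph::as_edgelist(sub, names = FALSE)
  if (nrow(el) == 0) return(el)
  w <- igraph::E(sub)$weight
  lex <- node_lex_rank(sg$coords[nodes, , drop = FALSE])
  a <- pmin(lex[el[, 1]], lex[el[, 2]])
  b <- pmax(lex[el[, 1]], lex[el[, 2]])
  ord <- order(w, a, b)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) {
    parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(nrow(el))
  for (e in ord) {
    ra <- find(el[e, 1]); rb <- find(el[e, 2])
    if (ra != rb) { parent[ra] <- rb; keep[e] <- TRUE }
  }
  el[keep, , drop = FALSE]
}

#' Identify the central trunk of a skeleton component
#'
#' The trunk is the maximum-physical-length simple path in the component:
#' the exact diameter of the component's minimum spanning tree, found by
#' two farthest-node sweeps. All tie-breaks are lexicographic on (z, y, x)
#' voxel coordinates, so identical inputs always give the identical path.
#'
#' @param sg a [skeleton_to_graph()] result.
#' @param component component id (see `sg$component`).
#' @return A list: `node_ids` (ordered node indices into `sg$coords`),
#'   `coords` (ordered voxel coordinates), `length_mm` (physical path
#'   length).
#' @export
identify_trunk <- function(sg, component) {
  nodes <- which(sg$component == component)
  if (length(nodes) == 0)
    stop("identify_trunk: empty component ", component, call. = FALSE)
  if (length(nodes) == 1)
    return(list(node_ids = nodes,
                coords = sg$coords[nodes, , drop = FALSE], length_mm = 0))
  el <- component_mst(sg, nodes)
  tg <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  tg <- igraph::add_edges(tg, t(el))
  co <- sg$coords[nodes, , drop = FALSE]
  igraph::E(tg)$weight <- sqrt(colSums(
    ((t(co[el[, 1], , drop = FALSE]) - t(co[el[, 2], , drop = FALSE])) *
       sg$spacing)^2))
  lex <- order(co[, 3], co[, 2], co[, 1])
  farthest <- function(from) {
    dd <- as.vector(igraph::distances(tg, v = from))
    cand <- which(dd == max(dd))
    cand[order(co[cand, 3], co[cand, 2], co[cand, 1])][1]
  }
  a <- farthest(lex[1])
  b <- farthest(a)
  # orient the path from the lexicographically smaller endpoint
  ends <- c(a, b)
  ends <- ends[order(co[ends, 3], co[ends, 2], co[ends, 1])]
  p <- igraph::shortest_paths(tg, from = ends[1], to = ends[2],
                              output = "vpath")$vpath[[1]]
  p <- as.integer(p)
  dlen <- igraph::distances(tg, v = ends[1], to = ends[2])[1, 1]
  list(node_ids = nodes[p], coords = sg$coords[nodes[p], , drop = FALSE],
       length_mm = dlen)
}

#' Propagate hierarchical branch levels outward from the trunks
#'
#' Per component: trunk voxels receive level 0 and are removed. Each
#' remaining 26-connected part hangs off the trunk; within it, the
#' principal branch path — from its attachment to its farthest voxel
#' (physical distance) — receives level 1 and is removed; parts hanging
#' off a level-1 branch are decomposed the same way at level 2, and so on
#' until the component is exhausted. Every voxel is labeled exactly once
#' (exclusion constraint), so the level sets partition the skeleton, and
#' a level-k branch always emerges from a level-(k-1) branch. The largest
#' component by voxel count is flagged as carrying the main trunk.
#'
#' @param sg a [skeleton_to_graph()] result.
#' @param trunks list of [identify_trunk()] results, one per component
#'   (ordered by component id).
#' @return A list: `labels` (a [branch_labels()] volume, -1 outside the
#'   skeleton), `main_component` (id of the largest component).
#' @export
propagate_branch_levels <- function(sg, trunks) {
  d <- sg$dim
  n <- nrow(sg$coords)
  node_lin <- sg$coords[, 1] + d[1] * (sg$coords[, 2] - 1L) +
    d[1] * d[2] * (sg$coords[, 3] - 1L)
  node_of <- integer(prod(d))
  node_of[node_lin] <- seq_len(n)
  lab_node <- rep(-1L, n)
  ncomp <- if (n > 0) max(sg$component) else 0L
  if (ncomp > 0 && length(trunks) < ncomp)
    stop("propagate_branch_levels: every component needs a trunk",
         call. = FALSE)
  co <- sg$coords
  lex_order <- function(ids) ids[order(co[ids, 3], co[ids, 2], co[ids, 1])]
  # 26-neighbour node ids of a set of nodes
  neighbours_of <- function(ids) {
    unique(unlist(igraph::adjacent_vertices(sg$graph, ids)))
  }
  for (comp in seq_len(ncomp)) {
    tr <- trunks[[comp]]
    if (is.null(tr))
      stop("propagate_branch_levels: missing trunk for component ", comp,
           call. = FALSE)
    stopifnot(all(lab_node[tr$node_ids] == -1L))  # exclusion constraint
    lab_node[tr$node_ids] <- 0L
    # stack of (part nodes, anchor nodes, level)
    stack <- list(list(anchor = tr$node_ids, level = 1L))
    while (length(stack) > 0) {
      item <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      anchor <- item$anchor
      rem <- which(sg$component == comp & lab_node == -1L)
      if (length(rem) == 0) break
      # parts of the unlabeled remainder attached to this anchor
      att <- intersect(neighbours_of(anchor), rem)
      if (length(att) == 0) next
      sub <- igraph::induced_subgraph(sg$graph, rem)
      mem <- igraph::components(sub)$membership
      att_local <- match(att, rem)
      for (pc in sort(unique(mem[att_local]))) {
        part <- rem[mem == pc]
        sources <- lex_order(intersect(att, part))
        sub_p <- igraph::induced_subgraph(sg$graph, part)
        src_local <- match(sources, part)
        dd <- igraph::distances(sub_p, v = src_local)
        dmin <- apply(dd, 2, min)
        far <- which(dmin == max(dmin))
        far <- far[order(co[part[far], 3], co[part[far], 2],
                         co[part[far], 1])][1]
        s_best <- src_local[which.min(dd[, far])]
        p <- igraph::shortest_paths(sub_p, from = s_best, to = far,
                                    output = "vpath")$vpath[[1]]
        branch <- part[as.integer(p)]
        stopifnot(all(lab_node[branch] == -1L))  # exclusion constraint
        lab_node[branch] <- item$level
        stack[[length(stack) + 1]] <- list(anchor = branch,
                                           level = item$level + 1L)
      }
    }
    if (any(sg$component == comp & lab_node == -1L))
      stop("propagate_branch_levels: propagation stalled in component ",
           comp, call. = FALSE)
  }
  lab <- array(-1L, d)
  lab[node_lin] <- lab_node
  main <- if (ncomp > 0) which.max(tabulate(sg$component)) else NA_integer_
  labels <- branch_labels(lab, spacing = sg$spacing, affine = sg$affine)
  list(labels = labels, main_component = as.integer(main))
}

#' Branch-level color scheme
#'
#' The rendering taxonomy: main trunk red, first-order branches green,
#' second-order blue, third- and higher-order magenta, tumor overlay
#' purple (painted beneath the vessel labels).
#'
#' @return A list of RGB triplets in \[0, 1\].
#' @export
branch_color_scheme <- function() {
  list(trunk = c(1, 0, 0), level1 = c(0, 1, 0), level2 = c(0, 0, 1),
       higher = c(1, 0, 1), tumor = c(0.5, 0, 0.5))
}

#' Colorize a branch-label volume
#'
#' Builds an RGB overlay volume from branch levels: level 0 red, level 1
#' green, level 2 blue, levels >= 3 magenta; an optional tumor mask is
#' painted purple beneath the vessel labels (vessel color wins where they
#' overlap); everything else is black.
#'
#' @param labels a [branch_labels()] volume.
#' @param tumor optional [binary_mask()] on the same grid.
#' @param scheme a [branch_color_scheme()].
#' @return A 4D numeric array `dim x 3` with values in \[0, 1\].
#' @export
colorize_labels <- function(labels, tumor = NULL,
                            scheme = branch_color_scheme()) {
  stopifnot(inherits(labels, "branch_labels"))
  if (!is.null(tumor)) stop_if_grid_mismatch(labels, tumor,
                                             "labels and tumor mask")
  d <- dim(labels$data)
  rgb <- array(0, dim = c(d, 3))
  paint <- function(rgb, sel, col) {
    for (ch in 1:3) {
      plane <- rgb[, , , ch]
      plane[sel] <- col[ch]
      rgb[, , , ch] <- plane
    }
    rgb
  }
  if (!is.null(tumor)) rgb <- paint(rgb, tumor$data, scheme$tumor)
  rgb <- paint(rgb, labels$data == 0L, scheme$trunk)
  rgb <- paint(rgb, labels$data == 1L, scheme$level1)
  rgb <- paint(rgb, labels$data == 2L, scheme$level2)
  rgb <- paint(rgb, labels$data >= 3L, scheme$higher)
  rgb
}
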