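# Morphology generation: somata in the lower cylinder, dendrites grown as
# minimum-spanning trees (with a balancing factor trading wiring cost against
# conduction path length) toward virtual target axons, then tapered so that
# somatic input resistance calibrates to the quoted cell-type values.

new_morph_tree <- function(nodes, cell_type = "pyr", meta = list()) {
  structure(list(nodes = nodes, cell_type = cell_type, meta = meta),
            class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("<morph_tree> %s cell, %d nodes, total cable %.0f um\n",
              x$cell_type, nrow(x$nodes), morph_total_length(x)))
  invisible(x)
}

# internal: per-node segment length to parent (0 for the root)
morph_segment_lengths <- function(tree) {
  nd <- tree$nodes
  len <- numeric(nrow(nd))
  has_par <- nd$parent > 0
  p <- match(nd$parent[has_par], nd$id)
  len[has_par] <- sqrt((nd$x[has_par] - nd$x[p])^2 +
                       (nd$y[has_par] - nd$y[p])^2 +
                       (nd$z[has_par] - nd$z[p])^2)
  len
}

#' Total cable length of a morphology
#' @param tree A `morph_tree`.
#' @return Total dendritic length (um), summed over all parent-child segments.
#' @export
morph_total_length <- function(tree) sum(morph_segment_lengths(tree))

# internal: path length from soma for every node (nodes are stored in
# topological order: parent always precedes child)
morph_path_lengths <- function(tree) {
  nd <- tree$nodes
  seg <- morph_segment_lengths(tree)
  plen <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] > 0) plen[i] <- plen[match(nd$parent[i], nd$id)] + seg[i]
  }
  plen
}

#' Default taper parameters
#'
#' Node diameters follow `d = scale * (d_min + k * sqrt(l_tip))` where
#' `l_tip` is the longest downstream path to a terminal (um), so branches
#' thicken toward the soma (centripetal taper). The `scale` values are
#' calibrated once per cell type so that the mean somatic input resistance of
#' grown populations matches the target values (about 200 MOhm for pyramidal
#' cells and 175 MOhm for stellate cells under the calibration passive set);
#' see [calibrate_taper()].
#'
#' @param cell_type `"pyr"` or `"int"`.
#' @return A list with `d_min`, `k`, `scale` and `soma_diam` (um).
#' @export
taper_defaults <- function(cell_type = c("pyr", "int")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "pyr") {
    list(d_min = 0.5, k = 0.06, scale = 0.549, soma_diam = 20)
  } else {
    list(d_min = 0.5, k = 0.06, scale = 0.609, soma_diam = 15)
  }
}

# internal: assign radii from the taper rule given the tree topology
apply_taper <- function(nodes, taper) {
  n <- nrow(nodes)
  seg <- numeric(n)
  has_par <- nodes$parent > 0
  p <- match(nodes$parent[has_par], nodes$id)
  seg[has_par] <- sqrt((nodes$x[has_par] - nodes$x[p])^2 +
                       (nodes$y[has_par] - nodes$y[p])^2 +
                       (nodes$z[has_par] - nodes$z[p])^2)
  # longest path to a downstream tip, computed children-first
  ltip <- numeric(n)
  for (i in rev(seq_len(n))) {
    if (nodes$parent[i] > 0) {
      pi <- match(nodes$parent[i], nodes$id)
      ltip[pi] <- max(ltip[pi], ltip[i] + seg[i])
    }
  }
  d <- taper$scale * (taper$d_min + taper$k * sqrt(ltip))
  r <- d / 2
  r[nodes$type == 1L] <- taper$soma_diam / 2
  nodes$radius <- r
  nodes
}

#' Grow a dendritic tree toward target points
#'
#' Greedy minimum-spanning-tree construction with a balancing factor: targets
#' are attached one at a time, choosing the (tree node, target) pair that
#' minimises `wiring distance + bf * resulting path length to the soma`,
#' subject to the wiring distance not exceeding `reach`. A two-element target
#' list `list(upper =, lower =)` grows the upper group first and then the
#' lower group (the pyramidal rule producing apical-then-basal trees).
#' Diameters are assigned afterwards by the centripetal taper rule.
#'
#' @param soma_pos Numeric length-3 soma position (um).
#' @param targets A numeric matrix (n x 3) of target points, or a named list
#'   `list(upper =, lower =)` of two such matrices grown in that order.
#' @param reach Maximal wiring distance for a single attachment (um).
#' @param balancing_factor Weight `bf` of the conduction-path term.
#' @param taper_params Taper parameters, see [taper_defaults()].
#' @param cell_type `"pyr"` or `"int"` (node type tags and default taper).
#' @return A `morph_tree`. Targets that can never be reached are dropped with
#'   a warning; with no reachable target at all the tree degenerates to the
#'   soma node.
#' @export
grow_dendrite <- function(soma_pos, targets, reach = 150, balancing_factor = 0.7,
                          taper_params = NULL, cell_type = c("pyr", "int")) {
  cell_type <- match.arg(cell_type)
  if (is.null(taper_params)) taper_params <- taper_defaults(cell_type)
  phases <- if (is.list(targets) && !is.data.frame(targets)) {
    list(upper = targets$upper, lower = targets$lower)
  } else {
    list(all = targets)
  }
  # type tag per phase: apical for the upper group of a pyramidal cell
  type_of <- function(phase) if (phase == "upper") 4L else 3L

  pos <- matrix(soma_pos, 1L, 3L)
  parent <- 0L
  plen <- 0
  type <- 1L
  bf <- balancing_factor
  n_unreach <- 0L

  for (phase in names(phases)) {
    tg <- phases[[phase]]
    if (is.null(tg) || nrow(tg) == 0L) next
    m <- nrow(tg)
    remaining <- rep(TRUE, m)
    # best feasible candidate per target (cost and tree-node index)
    best_cost <- rep(Inf, m)
    best_node <- rep(NA_integer_, m)
    for (i in seq_len(nrow(pos))) {
      d <- sqrt(colSums((t(tg) - pos[i, ])^2))
      cand <- d + bf * (plen[i] + d)
      ok <- d <= reach & cand < best_cost
      best_cost[ok] <- cand[ok]
      best_node[ok] <- i
    }
    repeat {
      masked <- ifelse(remaining, best_cost, Inf)
      j <- which.min(masked)
      if (!length(j) || !is.finite(masked[j])) break
      i <- best_node[j]
      d_ij <- sqrt(sum((tg[j, ] - pos[i, ])^2))
      pos <- rbind(pos, tg[j, , drop = FALSE])
      parent <- c(parent, i)
      plen <- c(plen, plen[i] + d_ij)
      type <- c(type, type_of(phase))
      remaining[j] <- FALSE
      new_i <- nrow(pos)
      idx <- which(remaining)
      if (length(idx)) {
        d <- sqrt(colSums((t(tg[idx, , drop = FALSE]) - pos[new_i, ])^2))
        cand <- d + bf * (plen[new_i] + d)
        ok <- d <= reach & cand < best_cost[idx]
        best_cost[idx[ok]] <- cand[ok]
        best_node[idx[ok]] <- new_i
      }
      if (!any(remaining)) break
    }
    n_unreach <- n_unreach + sum(remaining)
  }
  if (n_unreach > 0L) {
    warn(sprintf("%d target(s) beyond reach were not attached", n_unreach))
  }
  nodes <- tibble(
    id = seq_len(nrow(pos)),
    parent = as.integer(c(-1L, parent[-1L])),
    type = as.integer(type),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = 1
  )
  nodes$parent[1] <- -1L
  nodes <- apply_taper(nodes, taper_params)
  new_morph_tree(nodes, cell_type,
                 meta = list(reach = reach, balancing_factor = bf,
                             unreached = n_unreach))
}

#' Virtual target-axon field
#'
#' Straight axons are laid down as chords of the cylinder cross-section at
#' uniformly random depths within each layer and uniformly random planar
#' orientations. A cell connects to every axon whose chord passes within the
#' reach distance of its soma in the horizontal plane (see
#' [select_targets()]); the synaptic target point on each selected axon is
#' the chord point of closest planar approach. Axons are construction
#' scaffolding only: they are discarded after growth and contribute no
#' membrane.
#'
#' @param geometry A [column_geometry()].
#' @param n_per_layer Number of axons per layer.
#' @param layers Character vector, subset of `c("upper", "lower")`.
#' @return A list with one tibble per requested layer describing the chords
#'   (anchor `ax`, `ay`, unit direction `ux`, `uy`, parameter range `t1`,
#'   `t2`, depth `z`).
#' @export
axon_field <- function(geometry, n_per_layer = 160, layers = c("upper", "lower")) {
  stopifnot(inherits(geometry, "column_geometry"))
  r_cyl <- geometry$radius
  one_layer <- function(zr) {
    z <- runif(n_per_layer, zr[1], zr[2])
    # chord: anchor point uniform in the disk, direction uniform in angle
    rho <- r_cyl * sqrt(runif(n_per_layer))
    phi <- runif(n_per_layer, 0, 2 * pi)
    ax <- rho * cos(phi); ay <- rho * sin(phi)
    th <- runif(n_per_layer, 0, pi)
    ux <- cos(th); uy <- sin(th)
    # chord endpoints: |a + t u| = R  ->  t^2 + 2 t (a.u) + |a|^2 - R^2 = 0
    adotu <- ax * ux + ay * uy
    disc <- sqrt(pmax(adotu^2 - (rho^2 - r_cyl^2), 0))
    tibble(ax = ax, ay = ay, ux = ux, uy = uy,
           t1 = -adotu - disc, t2 = -adotu + disc, z = z)
  }
  out <- list()
  if ("upper" %in% layers) out$upper <- one_layer(geometry$upper)
  if ("lower" %in% layers) out$lower <- one_layer(geometry$lower)
  out
}

#' Select reachable axons and their target points for one soma
#'
#' An axon is selected when its chord passes within `reach` of the soma in
#' the horizontal plane; the target point is the chord point of closest
#' planar approach (at the axon's depth).
#'
#' @param chords One layer tibble from [axon_field()].
#' @param soma_pos Length-3 soma position (um).
#' @param reach Maximal planar soma-axon distance (um).
#' @return A numeric matrix (n x 3) of target points.
#' @export
select_targets <- function(chords, soma_pos, reach = 150) {
  rx <- soma_pos[1] - chords$ax
  ry <- soma_pos[2] - chords$ay
  tt <- pmin(pmax(rx * chords$ux + ry * chords$uy, chords$t1), chords$t2)
  px <- chords$ax + tt * chords$ux
  py <- chords$ay + tt * chords$uy
  d <- sqrt((px - soma_pos[1])^2 + (py - soma_pos[2])^2)
  sel <- d <= reach
  cbind(x = px[sel], y = py[sel], z = chords$z[sel])
}

#' Generate a population of morphologies
#'
#' Somata are distributed uniformly in the lower cylinder volume for both
#' cell types. Each cell receives its own fresh virtual axon field and
#' connects to the axons passing within `reach` of its soma in the
#' horizontal plane. Pyramidal cells connect to upper-layer axons first and
#' then to lower-layer axons (producing apical and basal trees); stellate
#' cells connect to lower-layer axons only.
#'
#' @param geometry A [column_geometry()].
#' @param n_pyr,n_int Number of pyramidal and stellate cells.
#' @param n_axons Axons per layer in each cell's target field.
#' @param reach Maximal planar soma-axon distance for axon selection (um).
#' @param balancing_factor MST balancing factor.
#' @param seed Integer seed.
#' @return A list of `morph_tree` objects (pyramidal cells first), each with
#'   absolute coordinates and `meta$soma` recording the soma position.
#' @export
generate_population <- function(geometry = column_geometry(), n_pyr = 0, n_int = 0,
                                n_axons = 160, reach = 150, balancing_factor = 0.7,
                                seed = 1L) {
  if (n_pyr < 0 || n_int < 0) abort("cell counts must be non-negative")
  with_seed(seed, {
    n_tot <- n_pyr + n_int
    if (n_tot == 0L) return(list())
    rho <- geometry$radius * sqrt(runif(n_tot))
    phi <- runif(n_tot, 0, 2 * pi)
    sx <- rho * cos(phi); sy <- rho * sin(phi)
    sz <- runif(n_tot, geometry$lower[1], geometry$lower[2])
    lapply(seq_len(n_tot), function(i) {
      is_pyr <- i <= n_pyr
      soma <- c(sx[i], sy[i], sz[i])
      field <- axon_field(geometry, n_axons,
                          layers = if (is_pyr) c("upper", "lower") else "lower")
      targets <- lapply(field, select_targets, soma_pos = soma, reach = reach)
      tree <- grow_dendrite(
        soma,
        targets = if (is_pyr) targets else targets$lower,
        reach = Inf,  # axon selection already enforced the reach rule
        balancing_factor = balancing_factor,
        cell_type = if (is_pyr) "pyr" else "int"
      )
      tree$meta$soma <- soma
      tree$meta$cell <- i
      tree
    })
  })
}

#' Ball-and-stick morphology
#'
#' A fast fixture capturing the two-bush dipolar geometry: a cylindrical soma
#' with one unbranched basal cable pointing down and one apical cable
#' pointing up. The default proportions are chosen so that, for a soma at
#' mid-depth of the lower cylinder, the membrane splits between the two
#' cylinders roughly like the algorithmically grown pyramidal cells
#' (about 45% of the area above the cylinder junction).
#'
#' @param basal_len,apical_len Cable lengths (um); either may be 0.
#' @param diam Basal dendrite diameter (um).
#' @param apical_diam Apical dendrite diameter (um); defaults to `diam`.
#' @param soma_diam Soma diameter (um).
#' @param soma_pos Soma position (um).
#' @param cell_type Cell-type tag.
#' @return A `morph_tree`.
#' @export
ball_and_stick <- function(basal_len = 150, apical_len = 300, diam = 2,
                           apical_diam = diam,
                           soma_diam = 20, soma_pos = c(0, 0, 0),
                           cell_type = "pyr") {
  if (basal_len < 0 || apical_len < 0) abort("cable lengths must be non-negative")
  nodes <- tibble(
    id = 1L, parent = -1L, type = 1L,
    x = soma_pos[1], y = soma_pos[2], z = soma_pos[3], radius = soma_diam / 2
  )
  nid <- 1L
  if (basal_len > 0) {
    nid <- nid + 1L
    nodes <- bind_rows(nodes, tibble(
      id = nid, parent = 1L, type = 3L,
      x = soma_pos[1], y = soma_pos[2], z = soma_pos[3] - basal_len,
      radius = diam / 2
    ))
  }
  if (apical_len > 0) {
    nid <- nid + 1L
    nodes <- bind_rows(nodes, tibble(
      id = nid, parent = 1L, type = 4L,
      x = soma_pos[1], y = soma_pos[2], z = soma_pos[3] + apical_len,
      radius = apical_diam / 2
    ))
  }
  new_morph_tree(nodes, cell_type, meta = list(soma = soma_pos))
}

#' Read and write SWC morphology files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed. Files whose ids are unsorted or non-contiguous are accepted and
#' topologically reindexed so that every parent precedes its children.
#'
#' @param path File path.
#' @param cell_type Cell-type tag attached to the returned tree.
#' @return `read_swc()` returns a `morph_tree`; `write_swc()` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path, cell_type = "pyr") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) abort("SWC parse error: no data lines")
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad)) {
    abort(sprintf("SWC parse error at line %d: expected 7 columns", rows[bad[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- rows[which(rowSums(is.na(m)) > 0)[1]]
    abort(sprintf("SWC parse error at line %d: non-numeric field", bad))
  }
  nodes <- tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  root <- which(nodes$parent == -1L)
  if (length(root) != 1L) abort("SWC parse error: need exactly one root (parent -1)")
  if (any(nodes$radius <= 0)) abort("SWC parse error: non-positive radius")
  # a file already in canonical order (ids 1..n, parents before children)
  # round-trips unchanged
  if (root == 1L && identical(nodes$id, seq_len(nrow(nodes))) &&
      all(nodes$parent < nodes$id)) {
    return(new_morph_tree(
      select(nodes, "id", "parent", "type", "x", "y", "z", "radius"), cell_type))
  }
  # topological reindex: breadth-first from the root
  order_idx <- integer(nrow(nodes))
  order_idx[1] <- root
  kids <- split(seq_len(nrow(nodes)), nodes$parent)
  filled <- 1L; head_i <- 1L
  while (head_i <= filled) {
    cur <- order_idx[head_i]
    ch <- kids[[as.character(nodes$id[cur])]]
    if (!is.null(ch)) {
      order_idx[filled + seq_along(ch)] <- ch
      filled <- filled + length(ch)
    }
    head_i <- head_i + 1L
  }
  if (filled != nrow(nodes)) abort("SWC parse error: disconnected nodes present")
  nodes <- nodes[order_idx, ]
  remap <- match(nodes$parent, nodes$id)
  nodes$parent <- ifelse(is.na(remap), -1L, remap)
  nodes$id <- seq_len(nrow(nodes))
  new_morph_tree(select(nodes, "id", "parent", "type", "x", "y", "z", "radius"),
                 cell_type)
}

#' @rdname read_swc
#' @param tree A `morph_tree`.
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  out <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                 nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# SWC export", out), path)
  invisible(path)
}

#' Membrane surface depth profile of a population
#'
#' Lateral membrane area per depth bin, the profile used to judge whether a
#' grown population reproduces the bimodal two-bush arrangement.
#'
#' @param trees List of `morph_tree`.
#' @param bin Depth bin width (um).
#' @return A tibble with `z` (bin midpoint) and `area` (um^2).
#' @export
surface_depth_profile <- function(trees, bin = 25) {
  rows <- purrr::map_dfr(trees, function(tree) {
    nd <- tree$nodes
    seg <- morph_segment_lengths(tree)
    has_par <- nd$parent > 0
    p <- match(nd$parent[has_par], nd$id)
    zmid <- (nd$z[has_par] + nd$z[p]) / 2
    diam <- nd$radius[has_par] + nd$radius[p]  # mean diameter
    tibble(z = zmid, area = pi * diam * seg[has_par])
  })
  rows %>%
    mutate(z = (floor(.data$z / bin) + 0.5) * bin) %>%
    group_by(z) %>%
    summarise(area = sum(.data$area), .groups = "drop")
}

# internal: mean path length from soma to apical (upper-phase) tips
mean_apical_path <- function(tree) {
  nd <- tree$nodes
  plen <- morph_path_lengths(tree)
  is_tip <- !(nd$id %in% nd$parent)
  sel <- is_tip & nd$type == 4L
  if (!any(sel)) return(NA_real_)
  mean(plen[sel])
}
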