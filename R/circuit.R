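# Circuit-theory connectivity on the resistance lattice: Kirchhoff current
# solves (sparse Laplacian), cumulative current maps, least-cost corridors,
# pinch points, and current-flow centrality of the patch network.

#' Build a conductance lattice from a resistance surface
#'
#' Valid (non-nodata) cells become nodes; 4- or 8-neighbour pairs become
#' resistor edges with conductance `2 / (cost_a + cost_b)`, diagonal edges
#' scaled by `1/sqrt(2)`. Each edge also carries a cost-weighted length
#' (mean cost x step length in metres) used for least-cost paths.
#'
#' @param surface positive-cost `raster_grid`.
#' @param connectivity 4 or 8.
#' @return a `conductance_lattice`: `cells` (linear indices), `node_of`
#'   (matrix cell -> node id, 0 invalid), `edges` (data.frame `a`, `b`,
#'   `cond`, `w`), `n`, `rg` (geometry reference).
#' @export
build_lattice <- function(surface, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- surface$values
  if (all(is.na(v))) stop("build_lattice: surface is entirely nodata")
  if (any(v <= 0, na.rm = TRUE)) stop("build_lattice: costs must be positive")
  nr <- nrow(v); nc <- ncol(v)
  cells <- which(!is.na(v))
  node_of <- matrix(0L, nr, nc)
  node_of[cells] <- seq_along(cells)
  offs <- list(c(1L, 0L, 1), c(0L, 1L, 1))                 # S, E
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) # SE, NE
  }
  ea <- eb <- integer(0); cond <- w <- numeric(0)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    idx2 <- (c2[ok] - 1L) * nr + r2[ok]
    valid <- node_of[idx2] > 0L
    a <- node_of[cells[ok]][valid]
    b <- node_of[idx2][valid]
    ca <- v[cells[ok]][valid]; cb <- v[idx2][valid]
    ea <- c(ea, a); eb <- c(eb, b)
    cond <- c(cond, 2 / (ca + cb) / o[3])
    w <- c(w, (ca + cb) / 2 * o[3] * surface$cellsize)
  }
  structure(list(cells = cells, node_of = node_of,
                 edges = data.frame(a = ea, b = eb, cond = cond, w = w),
                 n = length(cells), rg = surface),
            class = "conductance_lattice")
}

# Grouped (contracted) Laplacian solve. grp maps node -> group; groups listed
# in `injections` (named numeric, group index as name) receive current;
# `ground` is the grounded group. Returns per-group voltages.
lattice_solve_groups <- function(lattice, grp, ground, injections) {
  G <- max(grp)
  a <- grp[lattice$edges$a]; b <- grp[lattice$edges$b]
  keep <- a != b
  a <- a[keep]; b <- b[keep]; cv <- lattice$edges$cond[keep]
  L <- Matrix::sparseMatrix(i = c(a, b, a, b), j = c(b, a, a, b),
                            x = c(-cv, -cv, cv, cv), dims = c(G, G))
  bvec <- numeric(G)
  bvec[as.integer(names(injections))] <- injections
  free <- setdiff(seq_len(G), ground)
  vfree <- Matrix::solve(L[free, free, drop = FALSE], bvec[free])
  volt <- numeric(G)
  volt[free] <- as.numeric(vfree)
  volt
}

# verify source and ground are in one component; error naming components
check_connected <- function(lattice, src, gnd) {
  g <- igraph::graph_from_edgelist(
    as.matrix(lattice$edges[, c("a", "b")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, lattice$n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  cs <- unique(comp[src]); cg <- unique(comp[gnd])
  if (!any(cs %in% cg)) {
    stop(sprintf(
      "source and ground are disconnected (components %s vs %s)",
      paste(cs, collapse = "/"), paste(cg, collapse = "/")))
  }
  invisible(TRUE)
}

#' Solve the Kirchhoff current flow between source and ground cells
#'
#' Source cells are collapsed into one zero-resistance super-node (likewise
#' ground cells), `injected` units of current are injected at the source and
#' withdrawn at the ground, and the lattice Laplacian system is solved by a
#' sparse direct factorisation.
#'
#' @param lattice a `conductance_lattice`.
#' @param source_nodes,ground_nodes disjoint node-id vectors.
#' @param injected injected current (default 1).
#' @return list `voltages` (per node), `branch_currents` (per edge, signed
#'   a->b), `node_current` (per node: half the summed absolute incident
#'   branch currents; `injected` at source/ground nodes), and
#'   `effective_resistance`.
#' @export
solve_current <- function(lattice, source_nodes, ground_nodes, injected = 1) {
  stopifnot(length(source_nodes) > 0, length(ground_nodes) > 0,
            !any(source_nodes %in% ground_nodes))
  check_connected(lattice, source_nodes, ground_nodes)
  grp <- seq_len(lattice$n)
  sid <- min(source_nodes); gid <- min(ground_nodes)
  grp[source_nodes] <- sid
  grp[ground_nodes] <- gid
  grp <- match(grp, sort(unique(grp)))
  src_g <- grp[sid]; gnd_g <- grp[gid]
  inj <- injected; names(inj) <- src_g
  volt_g <- lattice_solve_groups(lattice, grp, gnd_g, inj)
  volt <- volt_g[grp]
  ic <- lattice$edges$cond * (volt[lattice$edges$a] - volt[lattice$edges$b])
  half <- rowsum(c(abs(ic), abs(ic)),
                 c(lattice$edges$a, lattice$edges$b)) / 2
  node_current <- numeric(lattice$n)
  node_current[as.integer(rownames(half))] <- half[, 1]
  node_current[c(source_nodes, ground_nodes)] <- injected
  list(voltages = volt, branch_currents = ic, node_current = node_current,
       effective_resistance = volt[sid] / injected)
}

#' Cumulative current density map between source patches
#'
#' Patches enter the circuit as zero-resistance super-nodes. In `pairwise`
#' mode one unit of current is passed between every unordered patch pair and
#' the per-cell current densities are summed. In `all_to_one` mode each patch
#' in turn is grounded while one unit is injected at every other patch.
#'
#' @param lattice a `conductance_lattice`.
#' @param patch_nodes list (length >= 2) of node-id vectors, one per patch.
#' @param mode `"pairwise"` or `"all_to_one"`.
#' @return list `current` (`raster_grid` of cumulative current density) and
#'   `total_injected` (units of current injected over all solves).
#' @export
cumulative_current <- function(lattice, patch_nodes,
                               mode = c("pairwise", "all_to_one")) {
  mode <- match.arg(mode)
  P <- length(patch_nodes)
  if (P < 2) stop("cumulative_current: need at least 2 patches")
  # contract every patch
  grp0 <- seq_len(lattice$n)
  for (p in seq_len(P)) grp0[patch_nodes[[p]]] <- min(patch_nodes[[p]])
  grp <- match(grp0, sort(unique(grp0)))
  pgrp <- vapply(patch_nodes, function(nd) grp[nd[1]], integer(1))
  acc <- numeric(lattice$n)
  total <- 0
  run <- function(ground_g, inj) {
    volt_g <- lattice_solve_groups(lattice, grp, ground_g, inj)
    volt <- volt_g[grp]
    ic <- lattice$edges$cond * (volt[lattice$edges$a] - volt[lattice$edges$b])
    half <- rowsum(c(abs(ic), abs(ic)),
                   c(lattice$edges$a, lattice$edges$b)) / 2
    add <- numeric(lattice$n)
    add[as.integer(rownames(half))] <- half[, 1]
    add
  }
  if (mode == "pairwise") {
    for (i in seq_len(P - 1)) {
      for (j in (i + 1):P) {
        inj <- 1; names(inj) <- pgrp[i]
        acc <- acc + run(pgrp[j], inj)
        total <- total + 1
      }
    }
  } else {
    for (j in seq_len(P)) {
      inj <- rep(1, P - 1)
      names(inj) <- pgrp[-j]
      acc <- acc + run(pgrp[j], inj)
      total <- total + (P - 1)
    }
  }
  cur <- matrix(NA_real_, rg_nrow(lattice$rg), rg_ncol(lattice$rg))
  cur[lattice$cells] <- acc
  list(current = rg_with_values(lattice$rg, cur), total_injected = total)
}

#' Least-cost corridors between source patches
#'
#' Cost-weighted distances are computed on the lattice (patches as
#' zero-cost super-vertices) with Dijkstra's algorithm; each patch is linked
#' to its `k_nearest` nearest neighbours by cost-weighted distance, pairs
#' deduplicated, and the least-cost path polyline extracted per pair.
#' Unreachable pairs are skipped with a message.
#'
#' @param surface resistance `raster_grid`.
#' @param patch_cells list of linear cell-index vectors, one per patch.
#' @param k_nearest neighbours per patch (default 4).
#' @param connectivity lattice connectivity.
#' @return list `corridors` (data.frame `id`, `patch_a`, `patch_b`, `cwd`,
#'   `lcp_length_km`, `wkt`), `paths` (list of path cell vectors),
#'   `dist_fields` (patch x cell cost-weighted distance matrix), `lattice`.
#' @export
least_cost_corridors <- function(surface, patch_cells, k_nearest = 4,
                                 connectivity = 8) {
  P <- length(patch_cells)
  if (P < 2) stop("least_cost_corridors: need at least 2 patches")
  lattice <- build_lattice(surface, connectivity)
  nodes <- lapply(patch_cells, function(cc) lattice$node_of[cc])
  if (any(vapply(nodes, function(x) any(x == 0L), logical(1)))) {
    stop("least_cost_corridors: patch cells include nodata cells")
  }
  n <- lattice$n
  el <- rbind(as.matrix(lattice$edges[, c("a", "b")]),
              do.call(rbind, lapply(seq_len(P), function(p) {
                cbind(n + p, nodes[[p]])
              })))
  wts <- c(lattice$edges$w, rep(0, sum(lengths(nodes))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n + P - igraph::vcount(g)))
  supers <- n + seq_len(P)
  dmat <- igraph::distances(g, v = supers, to = supers, weights = wts)
  dist_fields <- igraph::distances(g, v = supers,
                                   to = seq_len(n), weights = wts)
  pairs <- list()
  for (p in seq_len(P)) {
    d <- dmat[p, ]; d[p] <- Inf
    nb <- order(d)[seq_len(min(k_nearest, P - 1))]
    nb <- nb[is.finite(d[nb])]
    for (q in nb) pairs[[length(pairs) + 1L]] <- sort(c(p, q))
  }
  pairs <- unique(pairs)
  in_patch <- integer(n)
  for (p in seq_len(P)) in_patch[nodes[[p]]] <- p
  rows <- list(); paths <- list()
  id <- 0L
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    if (!is.finite(dmat[i, j])) {
      message(sprintf("corridor %d-%d skipped: patches unreachable", i, j))
      next
    }
    vp <- igraph::shortest_paths(g, from = supers[i], to = supers[j],
                                 weights = wts, output = "vpath")$vpath[[1]]
    vp <- as.integer(vp)
    vp <- vp[vp <= n]
    interior <- vp[!(in_patch[vp] %in% c(i, j))]
    if (length(interior) && all(in_patch[interior] > 0)) next # inside other patches
    xy <- rg_xy(lattice$rg, lattice$cells[vp])
    len_km <- if (nrow(xy) > 1) {
      sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)) / 1000
    } else 0
    id <- id + 1L
    rows[[id]] <- data.frame(id = id, patch_a = i, patch_b = j,
                             cwd = dmat[i, j], lcp_length_km = len_km,
                             wkt = path_to_wkt(xy))
    paths[[id]] <- lattice$cells[vp]
  }
  list(corridors = if (id) do.call(rbind, rows) else
         data.frame(id = integer(0), patch_a = integer(0),
                    patch_b = integer(0), cwd = numeric(0),
                    lcp_length_km = numeric(0), wkt = character(0)),
       paths = paths, dist_fields = dist_fields, lattice = lattice)
}

#' Identify pinch points from an all-to-one current map
#'
#' Restricts the current map to the corridor analysis zone (cells whose
#' summed cost-weighted distance to a linked patch pair exceeds that pair's
#' least-cost distance by at most `cwd_cutoff`), classifies current into
#' `k` natural-breaks levels, and polygonises top-level components larger
#' than `min_area_ha` hectares.
#'
#' @param current_map `raster_grid` (all-to-one cumulative current).
#' @param corr output of [least_cost_corridors()].
#' @param cwd_cutoff corridor width threshold in cost-weighted distance
#'   units.
#' @param k number of current classes.
#' @param min_area_ha minimum pinch-point area (strictly exceeded).
#' @return list `pinch_points` (data.frame `id`, `area_ha`, `wkt`), `cells`
#'   (list of cell vectors), `zone` (logical matrix of the analysis zone).
#' @export
pinch_points <- function(current_map, corr, cwd_cutoff = 10000, k = 5,
                         min_area_ha = 5) {
  lattice <- corr$lattice
  n <- lattice$n
  zone_nodes <- logical(n)
  for (r in seq_len(nrow(corr$corridors))) {
    i <- corr$corridors$patch_a[r]; j <- corr$corridors$patch_b[r]
    tot <- corr$dist_fields[i, ] + corr$dist_fields[j, ]
    zone_nodes <- zone_nodes | (tot <= corr$corridors$cwd[r] + cwd_cutoff)
  }
  zone <- matrix(FALSE, rg_nrow(current_map), rg_ncol(current_map))
  zone[lattice$cells[zone_nodes]] <- TRUE
  vals <- current_map$values[zone]
  vals <- vals[is.finite(vals)]
  empty <- list(pinch_points = data.frame(id = integer(0),
                                          area_ha = numeric(0),
                                          wkt = character(0)),
                cells = list(), zone = zone)
  if (!length(vals)) return(empty)
  nd <- length(unique(vals))
  if (nd < 2) {
    warning("pinch_points: uniform current in corridor zone; no pinch points")
    return(empty)
  }
  if (nd < k) {
    warning(sprintf(
      "pinch_points: only %d distinct current values; quantile classes used", nd))
    breaks <- unique(quantile(vals, seq_len(nd - 1) / nd))
  } else {
    breaks <- jenks(vals, k)$breaks
  }
  top <- max(jenks_assign(vals, breaks))
  mask <- zone & !is.na(current_map$values) &
    jenks_assign(current_map$values, breaks) == top
  mask[is.na(mask)] <- FALSE
  lab <- label_components(mask, 8)
  cell_ha <- current_map$cellsize^2 / 1e4
  comps <- if (any(lab > 0)) split(which(lab > 0), lab[lab > 0]) else list()
  comps <- comps[vapply(comps, length, integer(1)) * cell_ha > min_area_ha]
  rows <- list()
  for (i in seq_along(comps)) {
    rows[[i]] <- data.frame(
      id = i, area_ha = length(comps[[i]]) * cell_ha,
      wkt = rings_to_wkt(trace_boundary(current_map, comps[[i]])))
  }
  list(pinch_points = if (length(rows)) do.call(rbind, rows) else
         empty$pinch_points,
       cells = unname(comps), zone = zone)
}

#' Current-flow centrality of the patch network
#'
#' The corridor network is treated as a resistor network (edge resistance =
#' corridor cost-weighted distance). For every unordered pair of nodes in a
#' connected component, one unit of current is passed between them by solving
#' the reduced Laplacian system; node centrality is the mean throughput (half
#' the summed absolute incident edge currents, 1 for the injection pair) and
#' edge centrality the mean absolute current, over pairs of the node's
#' component.
#'
#' @param n_nodes number of network nodes.
#' @param edges data.frame `a`, `b`, `resistance`.
#' @return list `node` (numeric length `n_nodes`) and `edge` (numeric per
#'   edge row).
#' @export
current_flow_centrality <- function(n_nodes, edges) {
  node_c <- numeric(n_nodes)
  edge_c <- numeric(nrow(edges))
  if (n_nodes < 2 || !nrow(edges)) return(list(node = node_c, edge = edge_c))
  stopifnot(all(edges$resistance > 0))
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("a", "b")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  for (cmp in unique(memb)) {
    vs <- which(memb == cmp)
    if (length(vs) < 2) next
    eidx <- which(memb[edges$a] == cmp)
    idx <- match(seq_len(n_nodes), vs)        # global -> local
    a <- idx[edges$a[eidx]]; b <- idx[edges$b[eidx]]
    cv <- 1 / edges$resistance[eidx]
    m <- length(vs)
    L <- matrix(0, m, m)
    for (e in seq_along(a)) {
      L[a[e], b[e]] <- L[a[e], b[e]] - cv[e]
      L[b[e], a[e]] <- L[b[e], a[e]] - cv[e]
      L[a[e], a[e]] <- L[a[e], a[e]] + cv[e]
      L[b[e], b[e]] <- L[b[e], b[e]] + cv[e]
    }
    prs <- utils::combn(m, 2)
    npair <- ncol(prs)
    nacc <- numeric(m); eacc <- numeric(length(a))
    for (pp in seq_len(npair)) {
      s <- prs[1, pp]; t <- prs[2, pp]
      v <- numeric(m)
      rhs <- numeric(m); rhs[s] <- 1
      v[-t] <- solve(L[-t, -t, drop = FALSE], rhs[-t])
      ie <- cv * (v[a] - v[b])
      eacc <- eacc + abs(ie)
      thr <- rowsum(c(abs(ie), abs(ie)), c(a, b)) / 2
      tv <- numeric(m)
      tv[as.integer(rownames(thr))] <- thr[, 1]
      tv[c(s, t)] <- 1
      nacc <- nacc + tv
    }
    node_c[vs] <- nacc / npair
    edge_c[eidx] <- eacc / npair
  }
  list(node = node_c, edge = edge_c)
}

#' Classify centrality values into importance levels
#'
#' Three-class natural breaks; the top class is `"high"`. With fewer than 3
#' distinct values the class count is reduced with a warning (all-equal
#' values are all `"low"`).
#'
#' @param values numeric centrality values.
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
classify_centrality <- function(values) {
  ok <- is.finite(values)
  nd <- length(unique(values[ok]))
  if (nd == 0) return(rep(NA_character_, length(values)))
  if (nd == 1) {
    warning("classify_centrality: all values equal; single class 'low'")
    out <- rep(NA_character_, length(values))
    out[ok] <- "low"
    return(out)
  }
  kk <- min(3, nd)
  jb <- suppressWarnings(jenks(values[ok], kk))
  cls <- jenks_assign(values, jb$breaks)
  labels <- switch(kk, "low", c("low", "high"), c("low", "medium", "high"))
  out <- labels[cls]
  out
}
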