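# Graph connectivity indices of a seasonal/guild corridor network.

#' Simple ecological network graph
#'
#' Holds node count and deduplicated, self-loop-free edges. The connectivity
#' index formulas assume a simple graph, so duplicate corridors between a
#' patch pair are collapsed.
#'
#' @param n_nodes number of source patches (nodes).
#' @param edges two-column matrix or data.frame of node-id pairs (may be
#'   empty).
#' @return object of class `eco_network_graph` with `V`, `E`, `edges`.
#' @export
eco_network_graph <- function(n_nodes, edges = NULL) {
  if (is.null(edges) || !NROW(edges)) {
    ed <- matrix(integer(0), 0, 2)
  } else {
    ed <- as.matrix(edges[, 1:2, drop = FALSE])
    storage.mode(ed) <- "integer"
    if (any(ed < 1 | ed > n_nodes)) {
      stop("eco_network_graph: edge references a node outside 1..V")
    }
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]     # drop self-loops
    ed <- t(apply(ed, 1, sort))
    ed <- unique(ed)
  }
  structure(list(V = as.integer(n_nodes), E = nrow(ed), edges = ed),
            class = "eco_network_graph")
}

#' Alpha, beta and gamma connectivity indices
#'
#' alpha = (E - V + 1) / (2V - 5) measures loop redundancy (0 for trees, 1
#' for a maximally meshed planar network); beta = E / V is links per node;
#' gamma = E / (3 (V - 2)) is the realised fraction of the maximal planar
#' link count. Alpha and gamma are undefined (`NA`, with a warning) when
#' V < 3; beta when V < 1. A `disconnected` flag marks E < V - 1, where a
#' connected network is impossible and alpha can be negative.
#'
#' @param graph an [eco_network_graph()], or node count `V` when `E` given.
#' @param E edge count (when `graph` is a plain node count).
#' @return list of class `network_indices`: `V`, `E`, `alpha`, `beta`,
#'   `gamma`, their 3-decimal rounded counterparts (`alpha3`, `beta3`,
#'   `gamma3`), and `disconnected`.
#' @export
compute_indices <- function(graph, E = NULL) {
  if (inherits(graph, "eco_network_graph")) {
    V <- graph$V; E <- graph$E
  } else {
    V <- as.integer(graph)
    stopifnot(!is.null(E))
    E <- as.integer(E)
  }
  if (V < 1) {
    warning("compute_indices: V = 0; all indices undefined")
    beta <- NA_real_
  } else {
    beta <- E / V
  }
  if (V < 3) {
    if (V >= 1) warning("compute_indices: V < 3; alpha and gamma undefined")
    alpha <- gamma <- NA_real_
  } else {
    alpha <- (E - V + 1) / (2 * V - 5)
    gamma <- E / (3 * (V - 2))
  }
  structure(list(V = V, E = E, alpha = alpha, beta = beta, gamma = gamma,
                 alpha3 = round(alpha, 3), beta3 = round(beta, 3),
                 gamma3 = round(gamma, 3),
                 disconnected = E < V - 1),
            class = "network_indices")
}

#' @export
print.network_indices <- function(x, ...) {
  cat(sprintf("<network_indices> V = %d, E = %d%s\n", x$V, x$E,
              if (x$disconnected) " (disconnected)" else ""))
  cat(sprintf("  alpha = %.3f  beta = %.3f  gamma = %.3f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Summarise a patch-corridor network
#'
#' Builds the simple graph (V = patches, E = deduplicated corridors) and a
#' summary of source areas and corridor lengths.
#'
#' @param patches patch data.frame with `id` and `area_km2`.
#' @param corridors corridor data.frame with `patch_a`, `patch_b`,
#'   `lcp_length_km`.
#' @return list `graph` ([eco_network_graph()]), `indices`
#'   ([compute_indices()] result), `summary` (data.frame with patch/corridor
#'   totals and means).
#' @export
summarize_network <- function(patches, corridors) {
  V <- nrow(patches)
  if (NROW(corridors) &&
      !all(c(corridors$patch_a, corridors$patch_b) %in% patches$id)) {
    stop("summarize_network: corridor references a missing patch id")
  }
  g <- eco_network_graph(V, if (NROW(corridors))
    cbind(match(corridors$patch_a, patches$id),
          match(corridors$patch_b, patches$id)) else NULL)
  # corridor lengths on the deduplicated pairs (first occurrence wins)
  lens <- if (NROW(corridors)) {
    key <- paste(pmin(corridors$patch_a, corridors$patch_b),
                 pmax(corridors$patch_a, corridors$patch_b))
    corridors$lcp_length_km[!duplicated(key)]
  } else numeric(0)
  idx <- suppressWarnings(compute_indices(g))
  list(graph = g, indices = idx,
       summary = data.frame(
         n_patches = V,
         total_area_km2 = sum(patches$area_km2),
         mean_patch_area_km2 = if (V) mean(patches$area_km2) else NA_real_,
         n_corridors = g$E,
         total_length_km = sum(lens),
         mean_length_km = if (length(lens)) sum(lens) / length(lens)
                          else NA_real_))
}
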