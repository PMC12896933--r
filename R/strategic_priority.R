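# Strategic areas (corridor intersection nodes, multi-guild source overlaps)
# and the seasonal conservation-priority map built from weighted kernel
# densities of the five network elements.

# proper intersection point of segments p1-p2 and p3-p4, or NULL
seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(NULL)  # parallel or collinear
  dp <- p3 - p1
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
  u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p1 + t * d1
}

polyline_intersections <- function(xy1, xy2) {
  pts <- list()
  for (i in seq_len(nrow(xy1) - 1)) {
    for (j in seq_len(nrow(xy2) - 1)) {
      p <- seg_intersect(xy1[i, ], xy1[i + 1, ], xy2[j, ], xy2[j + 1, ])
      if (!is.null(p)) pts[[length(pts) + 1L]] <- p
    }
  }
  if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 2)
}

#' Ecological nodes: corridor intersections between guilds
#'
#' Finds geometric intersections of corridor polylines belonging to distinct
#' guilds within one season; intersection points closer than one cell are
#' merged to a single node.
#'
#' @param corridors_by_guild named list: guild -> list of corridor polylines
#'   (2-column coordinate matrices).
#' @param cellsize merge radius in metres (one cell).
#' @return list `nodes` (data.frame `id`, `x`, `y`, `guild_a`, `guild_b`)
#'   and `pair_counts` (data.frame `guild_a`, `guild_b`, `n`).
#' @export
corridor_nodes <- function(corridors_by_guild, cellsize) {
  guilds <- names(corridors_by_guild)
  raw <- list()
  if (length(guilds) >= 2) {
    for (i in seq_len(length(guilds) - 1)) {
      for (j in (i + 1):length(guilds)) {
        for (l1 in corridors_by_guild[[i]]) {
          for (l2 in corridors_by_guild[[j]]) {
            pts <- polyline_intersections(l1, l2)
            if (nrow(pts)) {
              raw[[length(raw) + 1L]] <- data.frame(
                x = pts[, 1], y = pts[, 2],
                guild_a = guilds[i], guild_b = guilds[j])
            }
          }
        }
      }
    }
  }
  if (!length(raw)) {
    return(list(nodes = data.frame(id = integer(0), x = numeric(0),
                                   y = numeric(0), guild_a = character(0),
                                   guild_b = character(0)),
                pair_counts = data.frame(guild_a = character(0),
                                         guild_b = character(0),
                                         n = integer(0))))
  }
  pts <- do.call(rbind, raw)
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (!length(keep) ||
        all((pts$x[keep] - pts$x[i])^2 + (pts$y[keep] - pts$y[i])^2 >=
              cellsize^2)) {
      keep <- c(keep, i)
    }
  }
  nodes <- pts[keep, , drop = FALSE]
  nodes <- cbind(id = seq_len(nrow(nodes)), nodes)
  rownames(nodes) <- NULL
  pc <- aggregate(list(n = nodes$id),
                  nodes[, c("guild_a", "guild_b")], length)
  list(nodes = nodes, pair_counts = pc)
}

#' Ecological overlap areas of guild source layers
#'
#' Computes per-cell guild richness from the guild union layers and
#' polygonises contiguous regions where two or more guilds overlap.
#'
#' @param guild_layers named list of guild binary `raster_grid`s.
#' @return list `richness` (`raster_grid`), `overlaps` (data.frame `id`,
#'   `richness` (max within region), `area_km2`, `wkt`), `cells` (list).
#' @export
source_overlaps <- function(guild_layers) {
  stopifnot(length(guild_layers) >= 1)
  ref <- guild_layers[[1]]
  rich <- matrix(0, rg_nrow(ref), rg_ncol(ref))
  for (gl in guild_layers) {
    stop_if_grid_mismatch(ref, gl, "guild source layers")
    v <- gl$values
    v[is.na(v)] <- 0
    rich <- rich + v
  }
  rich[is.na(ref$values)] <- NA
  lab <- label_components(!is.na(rich) & rich >= 2, 8)
  comps <- if (any(lab > 0)) split(which(lab > 0), lab[lab > 0]) else list()
  cell_km2 <- (ref$cellsize / 1000)^2
  rows <- list()
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    rows[[i]] <- data.frame(
      id = i, richness = max(rich[cc]), area_km2 = length(cc) * cell_km2,
      wkt = rings_to_wkt(trace_boundary(ref, cc)))
  }
  list(richness = rg_with_values(ref, rich),
       overlaps = if (length(rows)) do.call(rbind, rows) else
         data.frame(id = integer(0), richness = integer(0),
                    area_km2 = numeric(0), wkt = character(0)),
       cells = unname(comps))
}

#' Weighted kernel density of a network element layer
#'
#' Geometries are supplied rasterized (cell-index vectors) or as points;
#' every cell of a geometry carries the geometry's weight. The density is
#' linear in the weights. An empty element set gives a zero raster flagged
#' `empty`.
#'
#' @param rg reference `raster_grid`.
#' @param cells list of cell-index vectors (one per geometry), or `NULL`.
#' @param weights per-geometry weights.
#' @param bandwidth KDE bandwidth in metres.
#' @return `raster_grid` (attribute `empty` = TRUE when no geometries).
#' @export
element_density <- function(rg, cells, weights = NULL, bandwidth = 500) {
  if (is.null(cells) || !length(cells)) {
    out <- rg_with_values(rg, matrix(0, rg_nrow(rg), rg_ncol(rg)))
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (is.null(weights)) weights <- rep(1, length(cells))
  stopifnot(length(weights) == length(cells))
  allcells <- unlist(cells)
  w <- rep(weights, lengths(cells))
  xy <- rg_xy(rg, allcells)
  kde_raster(rg, xy[, 1], xy[, 2], weights = w, bandwidth = bandwidth)
}

#' Standardise a density layer to the 0-4 ordinal scale
#'
#' Five-class natural breaks, reclassified low = 0 to high = 4. An all-zero
#' (or constant) layer maps to all 0; with fewer than five distinct values a
#' quantile fallback is used with a warning.
#'
#' @param rg density `raster_grid`.
#' @return `raster_grid` with integer values 0-4 (NA preserved).
#' @export
standardize_layer <- function(rg) {
  v <- rg$values
  ok <- is.finite(v)
  nd <- length(unique(v[ok]))
  if (nd <= 1) return(rg_with_values(rg, ifelse(is.na(v), NA, 0)))
  if (nd < 5) {
    warning(sprintf(
      "standardize_layer: only %d distinct values; quantile classes used", nd))
    breaks <- unique(quantile(v[ok], seq_len(nd - 1) / nd))
  } else {
    breaks <- jenks(v[ok], 5)$breaks
  }
  cls <- jenks_assign(v, breaks) - 1L
  # spread reduced class counts onto the 0-4 scale keeping the top at 4
  if (nd < 5) cls <- cls * (4 / max(cls, na.rm = TRUE))
  rg_with_values(rg, matrix(as.numeric(cls), nrow(v), ncol(v)))
}

#' Composite conservation-priority map
#'
#' Sums the five standardised element layers with equal weights (0-20
#' scale), classifies the composite into three natural-breaks levels, and
#' reports the area share of the top ("high priority") class. Missing
#' element layers enter as all-zero with a flag.
#'
#' @param layers named list of up to five standardised `raster_grid`s
#'   (`sources`, `corridors`, `pinch_points`, `nodes`, `overlaps`); `NULL`
#'   entries allowed.
#' @return list `composite` (`raster_grid`), `classes` (`raster_grid` of
#'   1-3), `high_priority_fraction`, `missing_elements` (character).
#' @export
composite_priority <- function(layers) {
  expected <- c("sources", "corridors", "pinch_points", "nodes", "overlaps")
  missing_el <- expected[!expected %in% names(layers) |
                           vapply(expected, function(e)
                             is.null(layers[[e]]), logical(1))]
  present <- Filter(Negate(is.null), layers)
  stopifnot(length(present) >= 1)
  ref <- present[[1]]
  comp <- matrix(0, rg_nrow(ref), rg_ncol(ref))
  for (l in present) {
    stop_if_grid_mismatch(ref, l, "standardized element layers")
    v <- l$values
    v[is.na(v)] <- 0
    comp <- comp + v
  }
  comp[is.na(ref$values) & Reduce(`&`, lapply(present, function(l)
    is.na(l$values)))] <- NA
  ok <- is.finite(comp)
  nd <- length(unique(comp[ok]))
  if (nd < 2) {
    warning("composite_priority: constant composite; single class, no high-priority area")
    cls <- ifelse(is.na(comp), NA, 1)
    frac <- 0
  } else {
    kk <- min(3, nd)
    jb <- suppressWarnings(jenks(comp[ok], kk))
    cls <- jenks_assign(comp, jb$breaks)
    if (kk < 3) cls <- cls + (3 - kk)   # top class stays "high" (3)
    frac <- sum(cls == 3, na.rm = TRUE) / sum(ok)
  }
  list(composite = rg_with_values(ref, comp),
       classes = rg_with_values(ref, matrix(as.numeric(cls),
                                            nrow(comp), ncol(comp))),
       high_priority_fraction = frac,
       missing_elements = missing_el)
}
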