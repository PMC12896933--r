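# Ecological source patches: connected suitable areas above a guild-specific
# minimum size, and guild-level seasonal source layers.

#' Guild minimum patch areas (km2)
#'
#' Songbirds persist in patches above 0.5 km2; waders, swimming birds and
#' raptors require 2 km2.
#' @export
GUILD_MIN_AREA_KM2 <- c(wading = 2, songbird = 0.5, raptor = 2, swimming = 2)

#' Extract source patches from a binary habitat raster
#'
#' Labels connected suitable components (default 8-connectivity), drops those
#' at or below the minimum area, and traces boundary polygons on cell edges.
#'
#' @param binary binary `raster_grid` (1 = suitable).
#' @param min_area_km2 minimum patch area in km2 (patches must exceed it).
#' @param suitability optional suitability `raster_grid` for per-patch mean
#'   suitability.
#' @param connectivity 4 or 8.
#' @return list with `patches` (data.frame `id`, `area_km2`, `n_cells`,
#'   `mean_suitability`, `wkt`), `cells` (list of cell-index vectors per
#'   patch), and `label` (full label matrix before area filtering).
#' @export
extract_patches <- function(binary, min_area_km2, suitability = NULL,
                            connectivity = 8) {
  mask <- !is.na(binary$values) & binary$values >= 1
  lab <- label_components(mask, connectivity)
  cell_km2 <- (binary$cellsize / 1000)^2
  if (!any(mask)) {
    return(list(patches = data.frame(id = integer(0), area_km2 = numeric(0),
                                     n_cells = integer(0),
                                     mean_suitability = numeric(0),
                                     wkt = character(0)),
                cells = list(), label = lab))
  }
  comps <- split(which(lab > 0), lab[lab > 0])
  keep <- vapply(comps, length, integer(1)) * cell_km2 > min_area_km2
  comps <- comps[keep]
  rows <- list(); cells <- list()
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    ms <- if (!is.null(suitability)) mean(suitability$values[cc], na.rm = TRUE)
          else NA_real_
    rows[[i]] <- data.frame(
      id = i, area_km2 = length(cc) * cell_km2, n_cells = length(cc),
      mean_suitability = ms,
      wkt = rings_to_wkt(trace_boundary(binary, cc)))
    cells[[i]] <- cc
  }
  list(patches = if (length(rows)) do.call(rbind, rows) else
         data.frame(id = integer(0), area_km2 = numeric(0),
                    n_cells = integer(0), mean_suitability = numeric(0),
                    wkt = character(0)),
       cells = cells, label = lab)
}

#' Overlay species binary habitat maps into a guild source layer
#'
#' Cell-wise union: a cell is guild-suitable if it is suitable for any member
#' species present that season. Also returns the per-cell species richness as
#' an auxiliary layer.
#'
#' @param species_binaries list of binary `raster_grid`s (one per species;
#'   may be empty for species excluded that season).
#' @return list `union` (binary `raster_grid`) and `richness`
#'   (`raster_grid` of species counts).
#' @export
guild_overlay <- function(species_binaries) {
  species_binaries <- Filter(Negate(is.null), species_binaries)
  if (!length(species_binaries)) stop("guild_overlay: no species rasters")
  ref <- species_binaries[[1]]
  rich <- matrix(0, rg_nrow(ref), rg_ncol(ref))
  for (b in species_binaries) {
    stop_if_grid_mismatch(ref, b, "species habitat rasters")
    v <- b$values
    v[is.na(v)] <- 0
    rich <- rich + v
  }
  rich[is.na(ref$values)] <- NA
  list(union = rg_with_values(ref, ifelse(is.na(rich), NA,
                                          as.numeric(rich > 0))),
       richness = rg_with_values(ref, rich))
}

#' Build a guild-season source layer
#'
#' Unions the member species' binary maps, extracts patches above the guild
#' minimum area, and summarises total and mean patch area.
#'
#' @param species_binaries list of species binary `raster_grid`s.
#' @param guild guild name (sets the minimum patch area).
#' @param suitability optional guild-mean suitability raster for patch
#'   attributes.
#' @param connectivity component connectivity.
#' @return list `patches`, `cells`, `union`, `richness`, `summary`
#'   (data.frame `guild`, `n_patches`, `total_area_km2`,
#'   `mean_patch_area_km2`).
#' @export
guild_source_layer <- function(species_binaries, guild, suitability = NULL,
                               connectivity = 8) {
  ov <- guild_overlay(species_binaries)
  min_a <- GUILD_MIN_AREA_KM2[[guild]]
  px <- extract_patches(ov$union, min_a, suitability, connectivity)
  n <- nrow(px$patches)
  total <- sum(px$patches$area_km2)
  list(patches = px$patches, cells = px$cells, union = ov$union,
       richness = ov$richness,
       summary = data.frame(
         guild = guild, n_patches = n, total_area_km2 = total,
         mean_patch_area_km2 = if (n) total / n else NA_real_))
}
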