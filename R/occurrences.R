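# Ingestion and preparation of occurrence records: season assignment,
# per-species-season minimum-record filtering, spatial thinning, and
# bias-corrected background sampling.

#' Assign a calendar season to a date
#'
#' Spring is March-May, summer June-August, autumn September-November and
#' winter December-February (December of one year belongs to the same winter
#' as the following January and February).
#'
#' @param date `Date`, or character parseable as `YYYY-MM-DD`.
#' @return character vector of seasons; `NA` (with a warning) for unparseable
#'   dates.
#' @export
assign_season <- function(date) {
  d <- suppressWarnings(as.Date(date))
  bad <- is.na(d) & !is.na(date)
  if (any(bad)) {
    warning(sprintf("assign_season: %d unparseable date(s) dropped (e.g. '%s')",
                    sum(bad), as.character(date[bad][1])))
  }
  mo <- as.integer(format(d, "%m"))
  out <- rep(NA_character_, length(mo))
  out[mo %in% 3:5] <- "spring"
  out[mo %in% 6:8] <- "summer"
  out[mo %in% 9:11] <- "autumn"
  out[mo %in% c(12L, 1L, 2L)] <- "winter"
  out
}

#' Read an occurrence CSV
#'
#' Expects columns `species`, `guild`, `x`/`lon`, `y`/`lat`, `date`. Rows
#' with missing coordinates or unparseable dates are rejected with their line
#' numbers reported in a warning.
#'
#' @param path CSV path.
#' @return data.frame with columns `species`, `guild`, `x`, `y`, `date`,
#'   `season`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "lon"] <- "x"
  names(df)[names(df) == "lat"] <- "y"
  need <- c("species", "guild", "x", "y", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  season <- suppressWarnings(assign_season(df$date))
  bad <- is.na(season) | !is.finite(df$x) | !is.finite(df$y)
  if (any(bad)) {
    warning(sprintf("read_occurrences: rejected %d malformed row(s): line(s) %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  }
  df <- df[!bad, , drop = FALSE]
  df$season <- season[!bad]
  df
}

#' Minimum-record filter for a species-season dataset
#'
#' Species-season datasets below the minimum record count are excluded from
#' modelling.
#'
#' @param n_records number of records in the dataset.
#' @param min_n threshold (default 10).
#' @return logical: `TRUE` to keep.
#' @export
filter_min_records <- function(n_records, min_n = 10) {
  n_records >= min_n
}

#' Greedy spatial thinning
#'
#' Removes points so that no two retained points lie within `radius` of each
#' other. Points are visited in a seeded random order and kept if no
#' already-retained point is closer than the radius, making the retained set
#' maximal for that order. Exact duplicates are collapsed first.
#'
#' @param x,y point coordinates (metres).
#' @param radius exclusion radius in metres.
#' @param seed RNG seed fixing the processing order.
#' @return integer indices (into the input) of retained points.
#' @export
spatial_thin <- function(x, y, radius = 500, seed = 1) {
  stopifnot(radius > 0, length(x) == length(y))
  n <- length(x)
  if (n == 0) return(integer(0))
  dup <- duplicated(cbind(x, y))
  cand <- which(!dup)
  ord <- with_seed(seed, sample(cand))
  kept <- integer(0)
  r2 <- radius^2
  for (i in ord) {
    if (!length(kept) ||
        all((x[kept] - x[i])^2 + (y[kept] - y[i])^2 >= r2)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Bias-aware background sampling
#'
#' Draws background cells with probability proportional to the kernel density
#' of the pooled occurrence records of all species (the "bias file"), so
#' background reflects the same uneven recording effort as the presences.
#' Nodata cells are excluded. When more points are requested than there are
#' valid cells, sampling falls back to with-replacement with a warning.
#'
#' @param rg reference `raster_grid` (defines valid cells via `NA`).
#' @param occ_x,occ_y coordinates of all pooled occurrence records.
#' @param n number of background points (default 10000).
#' @param bandwidth KDE bandwidth in metres (default 10 cells).
#' @param seed RNG seed.
#' @return data.frame `x`, `y`, `cell` of background points (cell centres).
#' @export
sample_background <- function(rg, occ_x, occ_y, n = 10000,
                              bandwidth = 10 * rg$cellsize, seed = 1) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                cell = integer(0)))
  stopifnot(length(occ_x) >= 1)
  dens <- kde_raster(rg, occ_x, occ_y, bandwidth = bandwidth)
  valid <- which(!is.na(rg$values))
  w <- dens$values[valid]
  w <- w + max(w) * 1e-9  # keep far cells reachable, avoid zero-weight errors
  with_seed(seed, {
    if (n <= length(valid)) {
      pick <- sample(valid, n, replace = FALSE, prob = w)
    } else {
      warning(sprintf(
        "sample_background: %d points requested but only %d valid cells; sampling with replacement",
        n, length(valid)))
      pick <- sample(valid, n, replace = TRUE, prob = w)
    }
    xy <- rg_xy(rg, pick)
    data.frame(x = xy[, 1], y = xy[, 2], cell = pick)
  })
}

#' Assemble per-species-season modelling datasets
#'
#' Splits records by species and season, collapses coordinate duplicates,
#' spatially thins, applies the minimum-record filter, and attaches a shared
#' bias-corrected background sample. Excluded species-seasons are reported in
#' the `exclusions` element.
#'
#' @param occ occurrence data.frame (`species`, `guild`, `x`, `y`, `date`,
#'   optionally `season`).
#' @param rg reference `raster_grid`.
#' @param thin_radius thinning radius in metres.
#' @param min_n minimum records after thinning.
#' @param n_background background sample size.
#' @param bandwidth bias KDE bandwidth in metres.
#' @param seed RNG seed.
#' @return list with `datasets` (named `species.season` list: `species`,
#'   `guild`, `season`, `presences` data.frame, `background` data.frame) and
#'   `exclusions` (data.frame of dropped species-seasons with record counts).
#' @export
build_seasonal_datasets <- function(occ, rg, thin_radius = 500, min_n = 10,
                                    n_background = 10000,
                                    bandwidth = 10 * rg$cellsize, seed = 1) {
  if (is.null(occ$season)) occ$season <- assign_season(occ$date)
  occ <- occ[!is.na(occ$season), , drop = FALSE]
  bg <- sample_background(rg, occ$x, occ$y, n = n_background,
                          bandwidth = bandwidth, seed = seed)
  datasets <- list(); excl <- list()
  for (sp in unique(occ$species)) {
    for (s in SEASONS) {
      sub <- occ[occ$species == sp & occ$season == s, , drop = FALSE]
      if (nrow(sub)) {
        keep <- spatial_thin(sub$x, sub$y, radius = thin_radius,
                             seed = seed + 7L)
        sub <- sub[keep, , drop = FALSE]
      }
      if (!filter_min_records(nrow(sub), min_n)) {
        excl[[length(excl) + 1L]] <- data.frame(
          species = sp, season = s, n_records = nrow(sub))
        next
      }
      datasets[[paste(sp, s, sep = ".")]] <- list(
        species = sp, guild = sub$guild[1], season = s,
        presences = sub[, c("x", "y")], background = bg
      )
    }
  }
  list(
    datasets = datasets,
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(species = character(0), season = character(0),
                 n_records = integer(0))
  )
}
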