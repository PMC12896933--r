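# Seeded synthetic coastal landscapes: covariate stacks, species occurrences
# with planted environment responses, and recreation trajectories. Everything
# downstream of data acquisition can be exercised against these generators
# with known truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Season names in calendar order
#' @export
SEASONS <- c("spring", "summer", "autumn", "winter")

#' Bird guilds
#' @export
GUILDS <- c("wading", "songbird", "raptor", "swimming")

#' Configuration for the synthetic landscape generator
#'
#' @param grid_rows,grid_cols grid size in cells (>= 20 each).
#' @param cell_size cell edge in metres.
#' @param seed integer RNG seed; all generators are bit-reproducible given it.
#' @param n_species number of species (assigned to the four guilds in
#'   rotation).
#' @param records_per_species_season occurrence records drawn per
#'   species-season.
#' @param response_coefficients optional named list (per species) of named
#'   covariate coefficient vectors; `NULL` uses guild defaults with one
#'   dominant covariate per guild.
#' @param bias_strength exponent (>= 0) on the road-accessibility field that
#'   multiplies detection probability; 0 = unbiased sampling.
#' @param n_tracks total recreation tracks across the year.
#' @param seasonal_track_multipliers named numeric, relative track counts per
#'   season.
#' @param smooth_sigma Gaussian autocorrelation range of continuous
#'   covariates, in cells.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 60, grid_cols = 60, cell_size = 30,
                             seed = 1, n_species = 8,
                             records_per_species_season = 30,
                             response_coefficients = NULL,
                             bias_strength = 0.5, n_tracks = 60,
                             seasonal_track_multipliers =
                               c(spring = 1.5, summer = 3, autumn = 1.5, winter = 1),
                             smooth_sigma = 5) {
  cfg <- list(
    grid_rows = grid_rows, grid_cols = grid_cols, cell_size = cell_size,
    seed = as.integer(seed), n_species = n_species,
    records_per_species_season = records_per_species_season,
    response_coefficients = response_coefficients,
    bias_strength = bias_strength, n_tracks = n_tracks,
    seasonal_track_multipliers = seasonal_track_multipliers,
    smooth_sigma = smooth_sigma
  )
  if (grid_rows < 20 || grid_cols < 20) {
    stop("synthetic_config: grid must be at least 20 x 20 cells")
  }
  stopifnot(bias_strength >= 0, n_species >= 1,
            records_per_species_season >= 1, cell_size > 0)
  if (!all(SEASONS %in% names(seasonal_track_multipliers))) {
    stop("seasonal_track_multipliers must name all four seasons")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

synth_blank <- function(cfg) {
  raster_grid(matrix(0, cfg$grid_rows, cfg$grid_cols),
              xmin = 0, ymin = 0, cellsize = cfg$cell_size)
}

# smoothed standard-uniform field in [0,1]
synth_field <- function(cfg, sigma = cfg$smooth_sigma) {
  rg <- synth_blank(cfg)
  noise <- matrix(rnorm(cfg$grid_rows * cfg$grid_cols),
                  cfg$grid_rows, cfg$grid_cols)
  s <- rg_smooth(rg_with_values(rg, noise), sigma)$values
  s <- (s - min(s)) / (max(s) - min(s) + 1e-12)
  rg_with_values(rg, s)
}

# Shared physical features (sea, rivers, roads), derived deterministically
# from the config seed so the stack and the trajectory generator agree.
synth_features <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    nr <- cfg$grid_rows; nc <- cfg$grid_cols
    fwat <- synth_field(cfg)$values
    water <- matrix(FALSE, nr, nc)
    # sea along the southern margin with a noisy shoreline
    coast_depth <- pmax(1L, round(nr * 0.12 + 3 * sin(seq_len(nc) / 4) +
                                    cumsum(rnorm(nc, 0, 0.3))))
    coast_depth <- pmin(pmax(coast_depth, 1L), round(nr * 0.3))
    for (j in seq_len(nc)) water[(nr - coast_depth[j] + 1L):nr, j] <- TRUE
    # inland lakes/rivers where the smoothed field is lowest
    water[fwat < quantile(fwat, 0.08)] <- TRUE
    # two roads crossing the study area
    roads <- matrix(FALSE, nr, nc)
    r0 <- round(nr * 0.4) + cumsum(sample(c(-1L, 0L, 1L), nc, TRUE,
                                          prob = c(0.25, 0.5, 0.25)))
    r0 <- pmin(pmax(r0, 2L), nr - 1L)
    roads[cbind(r0, seq_len(nc))] <- TRUE
    c0 <- round(nc * 0.55) + cumsum(sample(c(-1L, 0L, 1L), nr, TRUE,
                                           prob = c(0.25, 0.5, 0.25)))
    c0 <- pmin(pmax(c0, 2L), nc - 1L)
    roads[cbind(seq_len(nr), c0)] <- TRUE
    roads[water] <- FALSE
    list(water = water, roads = roads)
  })
}

#' Generate the synthetic covariate raster stack
#'
#' Builds spatially autocorrelated continuous covariates (Gaussian-smoothed
#' noise), categorical land-use and soil layers, exact distance transforms to
#' generated water and road features, anthropogenic layers (night lights,
#' population, building height) tied to the built-up area, and seasonal
#' climate grids (`PREC`, `TMP`, `WIND` per season) that differ between
#' seasons. All layers share one grid.
#'
#' @param cfg a [synthetic_config()].
#' @return named list of `raster_grid`s (`ELE`, `NDVI`, `LAND`, `SOIL`,
#'   `D_WAT`, `D_ROAD`, `LIGHT`, `POP`, `BUILD_H`, and
#'   `PREC_<season>` / `TMP_<season>` / `WIND_<season>`), with attributes
#'   `water` and `roads` (logical matrices of the generating features) and
#'   `categorical` (names of categorical layers).
#' @export
generate_covariate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  feat <- synth_features(cfg)
  with_seed(cfg$seed + 202L, {
    base <- synth_blank(cfg)
    ele <- synth_field(cfg)
    ele <- rg_with_values(ele, ele$values * 500)
    d_wat <- rg_distance_to(base, feat$water)
    d_road <- rg_distance_to(base, feat$roads)
    urban_field <- synth_field(cfg)
    built <- (!feat$water) & (d_road$values < 3 * cfg$cell_size |
                                urban_field$values > 0.88)
    ndvi <- synth_field(cfg)
    nv <- 0.15 + 0.8 * ndvi$values
    nv[built] <- nv[built] * 0.3
    ndvi <- rg_with_values(base, nv)
    land <- matrix(4L, cfg$grid_rows, cfg$grid_cols)      # cropland
    land[ndvi$values > 0.6] <- 3L                          # forest
    land[d_wat$values > 0 & d_wat$values <= 5 * cfg$cell_size] <- 2L # wetland fringe
    land[built] <- 5L                                      # built-up
    land[feat$water] <- 1L                                 # water
    soil_f <- synth_field(cfg)
    soil <- findInterval(soil_f$values,
                         quantile(soil_f$values, c(0.25, 0.5, 0.75)),
                         left.open = TRUE) + 1L
    soil <- matrix(as.integer(soil), cfg$grid_rows, cfg$grid_cols)
    lum <- exp(-d_road$values / 300) + 2 * as.numeric(built)
    light <- rg_smooth(rg_with_values(base, lum), 2)
    light <- rg_with_values(base, 63 * light$values / max(light$values))
    pop <- rg_smooth(rg_with_values(base, as.numeric(built) +
                                      0.2 * urban_field$values), 3)
    pop <- rg_with_values(base, 5000 * pop$values / max(pop$values))
    bh <- synth_field(cfg, sigma = 2)
    bhv <- (5 + 55 * bh$values) * as.numeric(built)
    build_h <- rg_with_values(base, bhv)

    stack <- list(
      ELE = ele, NDVI = ndvi,
      LAND = rg_with_values(base, land + 0),
      SOIL = rg_with_values(base, soil + 0),
      D_WAT = d_wat, D_ROAD = d_road,
      LIGHT = light, POP = pop, BUILD_H = build_h
    )
    season_amp <- list(
      PREC = c(spring = 60, summer = 180, autumn = 70, winter = 20),
      TMP  = c(spring = 12, summer = 26, autumn = 14, winter = -1),
      WIND = c(spring = 5, summer = 3.5, autumn = 4.5, winter = 6)
    )
    for (varn in names(season_amp)) {
      shared <- synth_field(cfg)
      for (s in SEASONS) {
        own <- synth_field(cfg)
        v <- season_amp[[varn]][s] *
          (0.7 + 0.4 * (0.6 * shared$values + 0.4 * own$values))
        stack[[paste0(varn, "_", s)]] <- rg_with_values(base, v)
      }
    }
    attr(stack, "water") <- feat$water
    attr(stack, "roads") <- feat$roads
    attr(stack, "categorical") <- c("LAND", "SOIL")
    stack
  })
}

# Min-max standardised values of one layer
std01 <- function(v) {
  r <- range(v, na.rm = TRUE)
  if (diff(r) == 0) return(v * 0)
  (v - r[1]) / (r[2] - r[1])
}

inv_cloglog <- function(eta) 1 - exp(-exp(eta))

guild_of_species <- function(n_species) {
  GUILDS[((seq_len(n_species) - 1L) %% 4L) + 1L]
}

default_responses <- function(n_species) {
  guilds <- guild_of_species(n_species)
  dominant <- c(wading = "D_WAT", songbird = "NDVI",
                raptor = "ELE", swimming = "D_WAT")
  sign <- c(wading = -1, songbird = 1, raptor = 1, swimming = -1)
  out <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    g <- guilds[i]
    co <- c(4 * sign[g], 0.8)
    names(co) <- c(dominant[g], "TMP")
    out[[i]] <- co
  }
  names(out) <- sprintf("sp%02d", seq_len(n_species))
  out
}

season_date_range <- function(season) {
  switch(season,
    spring = c("2023-03-01", "2023-05-31"),
    summer = c("2023-06-01", "2023-08-31"),
    autumn = c("2023-09-01", "2023-11-30"),
    winter = c("2023-12-01", "2024-02-29")
  )
}

#' Generate species occurrence records with known response structure
#'
#' Presence probability at a cell is the inverse complementary-log-log of a
#' linear combination of min-max-standardised covariates with the planted
#' coefficients (`TMP` in a coefficient name refers to that season's
#' temperature grid). A smooth road-accessibility field raised to
#' `bias_strength` multiplies the detection probability, emulating uneven
#' recording effort; `bias_strength = 0` gives sampling proportional to true
#' suitability alone. Records carry a uniformly drawn date inside the season
#' window.
#'
#' @param stack output of [generate_covariate_stack()].
#' @param cfg the same [synthetic_config()].
#' @return list with `occurrences` (data.frame `species`, `guild`, `x`, `y`,
#'   `date`) and `truth` (per species-season list with `true_coefficients`
#'   and `true_suitability` raster in [0, 1]).
#' @export
generate_occurrences <- function(stack, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  responses <- cfg$response_coefficients
  if (is.null(responses)) responses <- default_responses(cfg$n_species)
  if (length(responses) != cfg$n_species) {
    stop("response_coefficients must have one entry per species")
  }
  species <- names(responses)
  guilds <- guild_of_species(cfg$n_species)
  base <- stack[[1]]
  access <- std01(exp(-stack$D_ROAD$values / 500))
  access <- 0.05 + 0.95 * access   # strictly positive accessibility
  with_seed(cfg$seed + 303L, {
    recs <- list(); truth <- list()
    for (i in seq_along(species)) {
      co <- responses[[i]]
      for (s in SEASONS) {
        eta <- matrix(0, rg_nrow(base), rg_ncol(base))
        for (nm in names(co)) {
          key <- if (nm %in% c("PREC", "TMP", "WIND")) paste0(nm, "_", s) else nm
          if (is.null(stack[[key]])) stop("unknown covariate in response: ", nm)
          eta <- eta + co[[nm]] * std01(stack[[key]]$values)
        }
        # rank-standardise the linear predictor before the inverse cloglog so
        # the planted niche occupies roughly the top decile of the landscape
        # (a raw linear predictor saturates the cloglog over half the grid)
        u <- rank(eta) / length(eta)
        p <- matrix(inv_cloglog(30 * u - 27), nrow(eta), ncol(eta))
        truth[[paste(species[i], s, sep = ".")]] <- list(
          species = species[i], season = s, true_coefficients = co,
          true_suitability = rg_with_values(base, p)
        )
        w <- as.vector(p * access^cfg$bias_strength)
        navail <- sum(w > 0)
        k <- cfg$records_per_species_season
        if (k > navail) {
          stop(sprintf(
            "generate_occurrences: %d records requested for %s/%s but only %d cells have positive weight",
            k, species[i], s, navail))
        }
        cells <- sample.int(length(w), k, replace = FALSE, prob = w)
        xy <- rg_xy(base, cells)
        jit <- (matrix(runif(2 * k), k, 2) - 0.5) * base$cellsize
        dr <- season_date_range(s)
        days <- as.integer(as.Date(dr[2]) - as.Date(dr[1]))
        dates <- as.Date(dr[1]) + sample.int(days + 1L, k, TRUE) - 1L
        recs[[length(recs) + 1L]] <- data.frame(
          species = species[i], guild = guilds[i],
          x = xy[, 1] + jit[, 1], y = xy[, 2] + jit[, 2],
          date = as.character(dates), stringsAsFactors = FALSE
        )
      }
    }
    list(occurrences = do.call(rbind, recs), truth = truth)
  })
}

#' Generate seasonal recreation trajectories
#'
#' Correlated random walks that start on or near the generated road network
#' and coastline, with per-season track counts proportional to
#' `seasonal_track_multipliers`. Timestamps are uniform dates inside the
#' track's season with 10-second point spacing.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame `track_id`, `x`, `y`, `timestamp`, `season`.
#' @export
generate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), cfg$n_tracks >= 1)
  feat <- synth_features(cfg)
  base <- synth_blank(cfg)
  near_coast <- rg_distance_to(base, feat$water)$values <= 2 * cfg$cell_size
  start_ok <- which((feat$roads | near_coast) & !feat$water)
  mult <- cfg$seasonal_track_multipliers[SEASONS]
  n_per <- round(cfg$n_tracks * mult / sum(mult))
  with_seed(cfg$seed + 404L, {
    out <- list(); tid <- 0L
    xmax <- cfg$grid_cols * cfg$cell_size
    ymax <- cfg$grid_rows * cfg$cell_size
    for (s in SEASONS) {
      ns <- n_per[[s]]
      if (is.na(ns) || ns < 1) next
      for (t in seq_len(ns)) {
        tid <- tid + 1L
        start <- rg_xy(base, sample(start_ok, 1L))
        nstep <- sample(30:80, 1L)
        theta <- runif(1, 0, 2 * pi)
        step <- cfg$cell_size * 0.8
        xs <- numeric(nstep); ys <- numeric(nstep)
        x <- start[1]; y <- start[2]
        for (k in seq_len(nstep)) {
          theta <- theta + rnorm(1, 0, 0.35)
          x <- min(max(x + step * cos(theta), 0), xmax)
          y <- min(max(y + step * sin(theta), 0), ymax)
          xs[k] <- x; ys[k] <- y
        }
        dr <- season_date_range(s)
        days <- as.integer(as.Date(dr[2]) - as.Date(dr[1]))
        d0 <- as.Date(dr[1]) + sample.int(days + 1L, 1L) - 1L
        t0 <- as.POSIXct(paste(d0, "08:00:00"), tz = "UTC") +
          round(runif(1, 0, 8 * 3600))
        out[[tid]] <- data.frame(
          track_id = tid, x = xs, y = ys,
          timestamp = format(t0 + 10 * (seq_len(nstep) - 1L),
                             "%Y-%m-%d %H:%M:%S"),
          season = s, stringsAsFactors = FALSE
        )
      }
    }
    if (!length(out)) {
      return(data.frame(track_id = integer(), x = numeric(), y = numeric(),
                        timestamp = character(), season = character()))
    }
    do.call(rbind, out)
  })
}

#' Write a covariate stack to a directory of ASCII grids
#' @param stack named list of `raster_grid`s.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(stack)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(stack[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a covariate stack from a directory of ASCII grids
#' @param dir directory containing `<LAYER>.asc` files.
#' @param categorical layer names to treat as categorical.
#' @return named list of `raster_grid`s with a `categorical` attribute.
#' @export
read_stack <- function(dir, categorical = c("LAND", "SOIL")) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files)) stop("no .asc layers found in ", dir)
  stack <- lapply(files, read_asc)
  names(stack) <- sub("\\.asc$", "", basename(files))
  for (nm in names(stack)[-1]) {
    stop_if_grid_mismatch(stack[[1]], stack[[nm]],
                          paste("layers", names(stack)[1], "and", nm))
  }
  attr(stack, "categorical") <- intersect(categorical, names(stack))
  stack
}
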