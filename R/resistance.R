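# Guild- and season-specific movement-resistance surfaces: seven factors
# (trajectory-based recreation pressure, distance to roads, building height,
# night lights, NDVI, land use, distance to water) scored 1-100 per guild and
# combined with weights averaged between the analytic hierarchy process
# (expert pairwise matrix) and the entropy weight method (data-driven).

RESISTANCE_FACTORS <- c("recreation", "d_road", "building_height",
                        "night_lights", "ndvi", "land_use", "d_water")

# Global factor weights reproduced by the default (perfectly consistent)
# AHP pairwise matrix.
DEFAULT_FACTOR_WEIGHTS <- c(
  recreation = 0.228, d_road = 0.037, building_height = 0.223,
  night_lights = 0.146, ndvi = 0.133, land_use = 0.148, d_water = 0.085
)

#' Default AHP pairwise comparison matrix for the seven resistance factors
#'
#' Constructed as the perfectly consistent reciprocal matrix whose principal
#' eigenvector equals the default factor weights (consistency ratio 0).
#' Intended as a documented, replaceable starting point for expert input.
#' @return 7 x 7 reciprocal matrix with factor dimnames.
#' @export
default_ahp_matrix <- function() {
  w <- DEFAULT_FACTOR_WEIGHTS
  m <- outer(w, w, "/")
  dimnames(m) <- list(names(w), names(w))
  m
}

#' Default guild calibration of factor resistance scores
#'
#' For each factor and guild, the resistance score (1-100) of the five
#' equal-interval classes of the factor (class 1 = lowest factor value), or
#' of the land-use categories. Reflects guild mobility and barrier
#' sensitivity: e.g. songbirds receive lower built-up resistance than other
#' guilds, water is near-costless for swimming birds, and raptors are the
#' most sensitive to roads and night lights.
#'
#' @return nested list `factor -> guild -> numeric scores` (five per
#'   continuous factor; named per land-use class for `land_use`, classes
#'   `water`, `wetland`, `forest`, `cropland`, `builtup`).
#' @export
default_guild_calibration <- function() {
  inc <- c(1, 25, 50, 75, 100)   # cost rises with factor value
  dec <- rev(inc)                # cost falls with factor value
  lu <- function(water, wetland, forest, cropland, builtup) {
    c(water = water, wetland = wetland, forest = forest,
      cropland = cropland, builtup = builtup)
  }
  list(
    recreation = list(wading = inc, songbird = c(1, 20, 40, 60, 80),
                      raptor = inc, swimming = inc),
    d_road = list(wading = dec, songbird = c(80, 60, 40, 20, 1),
                  raptor = c(100, 80, 55, 30, 5), swimming = dec),
    building_height = list(wading = inc, songbird = c(1, 15, 35, 55, 75),
                           raptor = inc, swimming = inc),
    night_lights = list(wading = inc, songbird = c(1, 20, 40, 60, 80),
                        raptor = c(1, 30, 55, 80, 100), swimming = inc),
    ndvi = list(wading = dec, songbird = dec, raptor = dec, swimming = dec),
    land_use = list(
      wading = lu(10, 1, 60, 40, 95),
      songbird = lu(70, 30, 1, 20, 60),
      raptor = lu(40, 20, 10, 1, 90),
      swimming = lu(1, 5, 70, 55, 95)
    ),
    d_water = list(wading = inc, songbird = c(1, 20, 40, 60, 80),
                   raptor = c(1, 15, 30, 45, 60), swimming = inc)
  )
}

#' Seasonal recreation-pressure surface from trajectories
#'
#' Gaussian kernel density of the season's trajectory points, rescaled to
#' [0, 1] by the seasonal maximum. A season with no points yields an all-zero
#' surface.
#'
#' @param rg reference `raster_grid`.
#' @param traj trajectory data.frame (`x`, `y`, and `season` or `timestamp`).
#' @param season season to select.
#' @param bandwidth KDE bandwidth in metres.
#' @return `raster_grid` in [0, 1].
#' @export
recreation_pressure <- function(rg, traj, season, bandwidth = 250) {
  if (is.null(traj$season)) traj$season <- assign_season(traj$timestamp)
  pts <- traj[traj$season == season, , drop = FALSE]
  if (!nrow(pts)) return(rg_with_values(rg, matrix(0, rg_nrow(rg), rg_ncol(rg))))
  d <- kde_raster(rg, pts$x, pts$y, bandwidth = bandwidth)
  mx <- max(d$values, na.rm = TRUE)
  rg_with_values(rg, if (mx > 0) d$values / mx else d$values)
}

#' Score a resistance factor for a guild
#'
#' Continuous factors are binned into five equal-interval classes over their
#' observed range and mapped through the guild's five class scores (class 1 =
#' lowest value). Categorical factors (land use) map each category through
#' the guild's category score table; an unmapped category is an error.
#'
#' @param rg factor `raster_grid`.
#' @param scores numeric vector: five class scores for continuous factors, or
#'   named per-category scores for categorical ones.
#' @param categorical whether the factor is categorical.
#' @param category_codes for categorical factors, named integer codes mapping
#'   raster values to score names (default the synthetic land-use coding).
#' @return `raster_grid` of resistance scores in [1, 100].
#' @export
score_factor <- function(rg, scores, categorical = FALSE,
                         category_codes = c(water = 1, wetland = 2, forest = 3,
                                            cropland = 4, builtup = 5)) {
  v <- rg$values
  if (categorical) {
    out <- matrix(NA_real_, nrow(v), ncol(v))
    present <- sort(unique(v[!is.na(v)]))
    for (code in present) {
      nm <- names(category_codes)[match(code, category_codes)]
      if (is.na(nm) || is.na(scores[nm])) {
        stop(sprintf("score_factor: no guild score for category code %g", code))
      }
      out[v == code] <- scores[[nm]]
    }
  } else {
    stopifnot(length(scores) == 5)
    r <- range(v, na.rm = TRUE)
    if (diff(r) == 0) {
      cls <- ifelse(is.na(v), NA_integer_, 1L)
    } else {
      edges <- seq(r[1], r[2], length.out = 6)[2:5]
      cls <- findInterval(v, edges, left.open = FALSE) + 1L
    }
    out <- matrix(scores[cls], nrow(v), ncol(v))
  }
  rg_with_values(rg, out)
}

#' AHP weights from a pairwise comparison matrix
#'
#' Principal-eigenvector weights by power iteration, with the standard
#' consistency ratio CR = ((lambda_max - n)/(n - 1)) / RI_n. A matrix with
#' CR >= 0.1 triggers a warning but remains usable.
#'
#' @param m square positive reciprocal matrix (`m[i,j] = 1/m[j,i]`).
#' @param tol power-iteration convergence tolerance.
#' @return list `weights` (sums to 1), `lambda_max`, `consistency_ratio`.
#' @export
ahp_weights <- function(m, tol = 1e-10) {
  n <- nrow(m)
  stopifnot(is.matrix(m), n == ncol(m), all(m > 0))
  if (max(abs(m * t(m) - 1)) > 1e-6) {
    stop("ahp_weights: matrix is not reciprocal (m[i,j] != 1/m[j,i])")
  }
  w <- rep(1 / n, n)
  repeat {
    w2 <- as.vector(m %*% w)
    w2 <- w2 / sum(w2)
    if (max(abs(w2 - w)) < tol) break
    w <- w2
  }
  lambda <- mean((m %*% w2) / w2)
  # random consistency index (Saaty) for n = 1..10
  ri <- c(0, 0, 0.58, 0.9, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  cr <- if (n <= 2) 0 else ((lambda - n) / (n - 1)) / ri[min(n, 10)]
  if (cr >= 0.1) {
    warning(sprintf("ahp_weights: consistency ratio %.3f >= 0.1", cr))
  }
  names(w2) <- rownames(m)
  list(weights = w2, lambda_max = lambda, consistency_ratio = cr)
}

#' Entropy weights from scored factor rasters
#'
#' For factor j with values x_ij over the m shared valid cells:
#' p_ij = x_ij / sum_i x_ij, entropy e_j = -(1/ln m) * sum_i p_ij ln p_ij
#' (0 ln 0 = 0), and weight w_j = (1 - e_j) / sum_k (1 - e_k). A constant
#' factor has maximal entropy and weight 0; if every factor is constant,
#' weights are uniform with a warning.
#'
#' @param scored named list of scored factor `raster_grid`s (>= 2).
#' @return named weight vector summing to 1.
#' @export
ewm_weights <- function(scored) {
  stopifnot(length(scored) >= 2)
  valid <- Reduce(`&`, lapply(scored, function(r) !is.na(r$values)))
  m <- sum(valid)
  e <- vapply(scored, function(r) {
    x <- r$values[valid]
    p <- x / sum(x)
    -sum(ifelse(p > 0, p * log(p), 0)) / log(m)
  }, numeric(1))
  d <- 1 - e
  d[d < 0] <- 0
  if (sum(d) <= 1e-15) {
    warning("ewm_weights: all factors constant; uniform weights")
    w <- rep(1 / length(scored), length(scored))
  } else {
    w <- d / sum(d)
  }
  names(w) <- names(scored)
  w
}

#' Combine AHP and EWM weights
#' @param ahp,ewm weight vectors over the same factors (each sums to 1).
#' @return element-wise average (sums to 1).
#' @export
combine_weights <- function(ahp, ewm) {
  stopifnot(length(ahp) == length(ewm))
  (ahp + ewm[names(ahp)]) / 2
}

#' Compose a resistance surface from scored factors and weights
#'
#' Cell cost is the weighted sum of factor scores, floored at 1; nodata in
#' any factor propagates.
#'
#' @param scored named list of scored factor `raster_grid`s.
#' @param weights named weight vector (same factors, sums to 1).
#' @return `raster_grid` of positive movement costs.
#' @export
compose_resistance <- function(scored, weights) {
  stopifnot(length(scored) == length(weights),
            all(names(scored) %in% names(weights)))
  ref <- scored[[1]]
  acc <- matrix(0, rg_nrow(ref), rg_ncol(ref))
  for (nm in names(scored)) {
    stop_if_grid_mismatch(ref, scored[[nm]], "scored factor rasters")
    acc <- acc + weights[[nm]] * scored[[nm]]$values
  }
  rg_with_values(ref, pmax(acc, 1))
}

#' Build the guild-season resistance surface from a covariate stack
#'
#' Assembles the seven resistance factors (recreation pressure from
#' trajectories; `D_ROAD`, `BUILD_H`, `LIGHT`, `NDVI`, `LAND`, `D_WAT` from
#' the stack), scores each for the guild, derives AHP, entropy and combined
#' weights, and composes the surface.
#'
#' @param stack covariate stack.
#' @param traj trajectory data.frame.
#' @param guild guild name.
#' @param season season name.
#' @param calibration guild calibration table
#'   (default [default_guild_calibration()]).
#' @param ahp_matrix AHP pairwise matrix (default [default_ahp_matrix()]).
#' @param kde_bandwidth recreation KDE bandwidth in metres.
#' @return list `surface` (`raster_grid`), `weights` (data.frame `factor`,
#'   `ahp`, `ewm`, `combined`), `scored` (list of scored factor rasters),
#'   `consistency_ratio`.
#' @export
build_resistance <- function(stack, traj, guild, season,
                             calibration = default_guild_calibration(),
                             ahp_matrix = default_ahp_matrix(),
                             kde_bandwidth = 250) {
  ref <- stack[[1]]
  rec <- recreation_pressure(ref, traj, season, kde_bandwidth)
  layer_of <- c(d_road = "D_ROAD", building_height = "BUILD_H",
                night_lights = "LIGHT", ndvi = "NDVI", land_use = "LAND",
                d_water = "D_WAT")
  scored <- list(recreation = score_factor(rec, calibration$recreation[[guild]]))
  for (f in names(layer_of)) {
    if (is.null(stack[[layer_of[f]]])) {
      stop("build_resistance: stack lacks layer ", layer_of[f])
    }
    scored[[f]] <- score_factor(stack[[layer_of[f]]], calibration[[f]][[guild]],
                                categorical = f == "land_use")
  }
  scored <- scored[RESISTANCE_FACTORS]
  ahp <- ahp_weights(ahp_matrix)
  ewm <- ewm_weights(scored)
  comb <- combine_weights(ahp$weights, ewm)
  list(surface = compose_resistance(scored, comb),
       weights = data.frame(factor = RESISTANCE_FACTORS,
                            ahp = as.numeric(ahp$weights[RESISTANCE_FACTORS]),
                            ewm = as.numeric(ewm[RESISTANCE_FACTORS]),
                            combined = as.numeric(comb[RESISTANCE_FACTORS])),
       scored = scored, consistency_ratio = ahp$consistency_ratio)
}
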