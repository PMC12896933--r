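test_that("AHP weights reproduce closed forms and the eigen oracle", {
  w2 <- ahp_weights(matrix(c(1, 1 / 3, 3, 1), 2, 2))
  expect_equal(unname(w2$weights), c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(w2$consistency_ratio, 0)
  w3 <- ahp_weights(matrix(1, 3, 3))  # indifference matrix: uniform weights
  expect_equal(unname(w3$weights), rep(1 / 3, 3), tolerance = 1e-9)
  # random reciprocal 4x4 vs dense eigen decomposition
  set.seed(12)
  u <- matrix(1, 4, 4)
  u[upper.tri(u)] <- sample(c(1 / 3, 1 / 2, 1, 2, 3, 5), 6, replace = TRUE)
  u[lower.tri(u)] <- 1 / t(u)[lower.tri(u)]
  res <- suppressWarnings(ahp_weights(u))
  ev <- eigen(u)
  pv <- Re(ev$vectors[, 1]); pv <- pv / sum(pv)
  expect_equal(unname(res$weights), pv, tolerance = 1e-8)
  expect_equal(res$lambda_max, Re(ev$values[1]), tolerance = 1e-8)
  # non-reciprocal matrices are rejected
  bad <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(ahp_weights(bad), "reciprocal")
})

test_that("entropy weights match a hand-computed toy table", {
  # 3 factors over 4 cells; hand-computed entropy weights
  mk <- function(v) raster_grid(matrix(v, 2, 2), cellsize = 30)
  x <- list(f1 = mk(c(1, 2, 3, 4)), f2 = mk(c(4, 4, 4, 4)),
            f3 = mk(c(1, 1, 1, 7)))
  hand <- local({
    ej <- vapply(list(c(1, 2, 3, 4), c(4, 4, 4, 4), c(1, 1, 1, 7)),
                 function(v) {
                   p <- v / sum(v)
                   -sum(p * log(p)) / log(4)
                 }, numeric(1))
    d <- 1 - ej
    d / sum(d)
  })
  w <- ewm_weights(x)
  expect_equal(unname(w), hand, tolerance = 1e-10)
  # a constant factor gets zero weight
  expect_equal(unname(w["f2"]), 0, tolerance = 1e-12)
  # identical factors share equal weight
  y <- list(a = mk(c(1, 5, 2, 8)), b = mk(c(1, 5, 2, 8)))
  wy <- ewm_weights(y)
  expect_equal(unname(wy[1]), unname(wy[2]))
  # all-constant: uniform with warning
  expect_warning(wz <- ewm_weights(list(a = mk(rep(2, 4)), b = mk(rep(3, 4)))),
                 "constant")
  expect_equal(unname(wz), c(0.5, 0.5))
})

test_that("factor scoring honours direction and guild calibration", {
  cal <- default_guild_calibration()
  # dense vegetation (top NDVI class) gets the minimum resistance class
  ndvi <- raster_grid(matrix(seq(0, 1, length.out = 25), 5, 5), cellsize = 30)
  sc <- score_factor(ndvi, cal$ndvi$wading)
  expect_equal(sc$values[ndvi$values == max(ndvi$values)], min(cal$ndvi$wading))
  # built-up land: songbirds pay less than waders
  lu <- raster_grid(matrix(5, 3, 3), cellsize = 30)     # all built-up
  s_song <- score_factor(lu, cal$land_use$songbird, categorical = TRUE)
  s_wad <- score_factor(lu, cal$land_use$wading, categorical = TRUE)
  expect_lt(s_song$values[1, 1], s_wad$values[1, 1])
  # constant continuous raster: single class, uniform score
  const <- raster_grid(matrix(7, 4, 4), cellsize = 30)
  expect_equal(unique(as.vector(score_factor(const, cal$ndvi$raptor)$values)),
               cal$ndvi$raptor[1])
  # unmapped category fails loudly
  lu_bad <- raster_grid(matrix(9, 2, 2), cellsize = 30)
  expect_error(score_factor(lu_bad, cal$land_use$wading, categorical = TRUE),
               "category")
})

test_that("resistance composition is weight-normalised and bounded", {
  mk <- function(v) raster_grid(matrix(v, 4, 4), cellsize = 30)
  s1 <- mk(runif(16, 1, 100)); s2 <- mk(runif(16, 1, 100))
  # single factor with weight 1 reproduces the factor
  expect_equal(compose_resistance(list(a = s1), c(a = 1))$values, s1$values)
  # equal scores with normalised weights give a uniform surface
  u <- mk(rep(40, 16))
  expect_equal(unique(as.vector(
    compose_resistance(list(a = u, b = u), c(a = 0.3, b = 0.7))$values)), 40)
  # composed surface bounded by the score range under weights summing to 1
  comp <- compose_resistance(list(a = s1, b = s2), c(a = 0.4, b = 0.6))
  expect_true(all(comp$values >= pmin(s1$values, s2$values) - 1e-9))
  expect_true(all(comp$values <= pmax(s1$values, s2$values) + 1e-9))
})

test_that("recreation pressure surfaces are rescaled and season-filtered", {
  rg <- raster_grid(matrix(0, 20, 20), cellsize = 30)
  traj <- data.frame(track_id = 1, x = c(300, 310), y = c(300, 300),
                     timestamp = "2023-07-10 09:00:00")
  # zero points in the requested season: all-zero surface
  z <- recreation_pressure(rg, traj, "winter")
  expect_true(all(z$values == 0))
  # single cluster: maximum 1 at the occupied cell, decaying outward
  r <- recreation_pressure(rg, traj, "summer", bandwidth = 90)
  expect_equal(max(r$values), 1)
  expect_equal(which.max(r$values), rg_cell_at(rg, 305, 300), tolerance = 1)
  # duplicating every point leaves the rescaled surface unchanged
  r2 <- recreation_pressure(rg, rbind(traj, traj), "summer", bandwidth = 90)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
})

test_that("the default AHP matrix and full build keep weight invariants", {
  ahp <- ahp_weights(default_ahp_matrix())
  expect_equal(sum(ahp$weights), 1, tolerance = 1e-9)
  expect_lt(ahp$consistency_ratio, 0.1)
  cfg <- synthetic_config(grid_rows = 25, grid_cols = 25, seed = 2,
                          n_species = 4, records_per_species_season = 12)
  st <- generate_covariate_stack(cfg)
  traj <- generate_trajectories(cfg)
  res <- build_resistance(st, traj, "songbird", "summer")
  for (col in c("ahp", "ewm", "combined")) {
    expect_equal(sum(res$weights[[col]]), 1, tolerance = 1e-9)
  }
  expect_equal(res$weights$combined,
               (res$weights$ahp + res$weights$ewm) / 2)
  expect_true(all(res$surface$values >= 1))
  expect_true(all(is.finite(res$surface$values)))
  # guild differentiation on built-up cells under the default calibration
  res_w <- build_resistance(st, traj, "wading", "summer")
  built <- st$LAND$values == 5
  if (any(built)) {
    expect_true(mean(res$surface$values[built]) <=
                  mean(res_w$surface$values[built]))
  }
})
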