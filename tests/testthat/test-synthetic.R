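cfg_small <- synthetic_config(grid_rows = 30, grid_cols = 30, seed = 9,
                              n_species = 4, records_per_species_season = 15)

test_that("all three generators are bit-identical under a fixed seed", {
  s1 <- generate_covariate_stack(cfg_small)
  s2 <- generate_covariate_stack(cfg_small)
  for (nm in names(s1)) expect_identical(s1[[nm]]$values, s2[[nm]]$values)
  o1 <- generate_occurrences(s1, cfg_small)
  o2 <- generate_occurrences(s2, cfg_small)
  expect_identical(o1$occurrences, o2$occurrences)
  t1 <- generate_trajectories(cfg_small)
  t2 <- generate_trajectories(cfg_small)
  expect_identical(t1, t2)
})

test_that("stack layers share one grid and honour their constraints", {
  st <- generate_covariate_stack(cfg_small)
  ref <- st[[1]]
  for (nm in names(st)) {
    expect_identical(dim(st[[nm]]$values), dim(ref$values))
    expect_equal(st[[nm]]$cellsize, ref$cellsize)
  }
  # distance transform identity on generated water features
  expect_true(all(st$D_WAT$values[attr(st, "water")] == 0))
  expect_true(all(st$D_WAT$values[!attr(st, "water")] > 0))
  # categorical layers have at least 4 classes
  expect_gte(length(unique(as.vector(st$LAND$values))), 4)
  expect_gte(length(unique(as.vector(st$SOIL$values))), 4)
  # seasonal climate layers differ between seasons
  expect_lt(cor(as.vector(st$PREC_spring$values),
                as.vector(st$PREC_summer$values)), 1)
  expect_false(identical(st$TMP_winter$values, st$TMP_summer$values))
})

test_that("degenerate grids and infeasible record counts are rejected", {
  expect_error(synthetic_config(grid_rows = 10, grid_cols = 50), "20")
  cfg_bad <- synthetic_config(grid_rows = 20, grid_cols = 20,
                              records_per_species_season = 1000,
                              n_species = 1)
  st <- generate_covariate_stack(cfg_bad)
  expect_error(generate_occurrences(st, cfg_bad), "cells")
})

test_that("occurrences follow the planted response and season windows", {
  cfg <- synthetic_config(grid_rows = 40, grid_cols = 40, seed = 21,
                          n_species = 1, records_per_species_season = 150,
                          bias_strength = 0)
  st <- generate_covariate_stack(cfg)
  occ <- generate_occurrences(st, cfg)
  # wading sp01 has a strong negative D_WAT response: presences closer to
  # water than random cells
  rg <- st[[1]]
  pres_d <- st$D_WAT$values[rg_cell_at(rg, occ$occurrences$x,
                                       occ$occurrences$y)]
  set.seed(1)
  rand_d <- st$D_WAT$values[sample(length(rg$values), 2000, replace = TRUE)]
  expect_lt(mean(pres_d), mean(rand_d))
  # dates map to the season the record was generated for
  expect_identical(assign_season(occ$occurrences$date),
                   rep(SEASONS, each = cfg$records_per_species_season))
  # truth rasters are probabilities
  for (tr in occ$truth) {
    expect_true(all(tr$true_suitability$values >= 0 &
                      tr$true_suitability$values <= 1))
  }
})

test_that("unbiased planted signals support high-discrimination models", {
  # recoverability invariant: >= 200 unbiased records allow a fit with
  # training AUC above 0.9 against random background
  fx <- make_recovery_fixture(71, n_pres = 200, n_bg = 1000)
  m <- suppressWarnings(fit_maxent(fx$pres, fx$bg, "LQ", rm = 1))
  expect_gt(evaluate_model(m, fx$pres, fx$bg)$auc, 0.9)
})

test_that("seasonal track multipliers scale trajectory effort", {
  cfg <- synthetic_config(grid_rows = 30, grid_cols = 30, seed = 4,
                          n_tracks = 120,
                          seasonal_track_multipliers =
                            c(spring = 0, summer = 3, autumn = 1, winter = 1))
  tr <- generate_trajectories(cfg)
  counts <- table(factor(tr$season, levels = SEASONS))
  expect_equal(unname(counts["spring"]), 0L)
  ratio <- counts["summer"] / counts["winter"]
  expect_gt(ratio, 3 * 0.8)
  expect_lt(ratio, 3 * 1.2)
  # timestamps fall inside the track's season
  expect_identical(unname(assign_season(substr(tr$timestamp, 1, 10))),
                   tr$season)
})
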