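test_that("lattice construction follows the conductance conventions", {
  # cost 1 and 3 neighbours: edge conductance 2/(1+3) = 0.5
  rg <- raster_grid(matrix(c(1, 3), 1, 2), cellsize = 30)
  lat <- build_lattice(rg, 4)
  expect_equal(lat$edges$cond, 0.5)
  # uniform cost 1 with 4-connectivity: all cardinal conductances 1
  rg2 <- raster_grid(matrix(1, 3, 3), cellsize = 30)
  expect_true(all(build_lattice(rg2, 4)$edges$cond == 1))
  # 3x3 grid, 8-connectivity: 12 cardinal + 8 diagonal = 20 edges
  lat8 <- build_lattice(rg2, 8)
  expect_equal(nrow(lat8$edges), 20)
  # diagonal conductance scaled by 1/sqrt(2)
  expect_setequal(round(unique(lat8$edges$cond), 9),
                  round(c(1, 1 / sqrt(2)), 9))
  expect_error(build_lattice(raster_grid(matrix(NA_real_, 3, 3))), "nodata")
})

test_that("series and parallel closed forms are reproduced exactly", {
  # 3-node series chain of unit resistors: Reff = 2, middle carries 1 unit
  chain <- build_lattice(raster_grid(matrix(1, 1, 3), cellsize = 30), 4)
  sol <- solve_current(chain, 1, 3)
  expect_equal(sol$effective_resistance, 2, tolerance = 1e-10)
  expect_equal(sol$node_current[2], 1, tolerance = 1e-10)
  # ring of 8 unit resistors, opposite corners: two 4-resistor paths in
  # parallel carry half a unit each
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  ring <- build_lattice(raster_grid(m, cellsize = 30), 4)
  rg <- raster_grid(m, cellsize = 30)
  s <- ring$node_of[1, 1]; g <- ring$node_of[3, 3]
  sol2 <- solve_current(ring, s, g)
  expect_equal(sol2$effective_resistance, 4 * 4 / 8, tolerance = 1e-10)
  # symmetric branches carry equal current
  top <- ring$node_of[1, 2]; left <- ring$node_of[2, 1]
  expect_equal(sol2$node_current[top], sol2$node_current[left],
               tolerance = 1e-6)
  expect_equal(sol2$node_current[top], 0.5, tolerance = 1e-6)
})

test_that("current is conserved and reciprocal on random lattices", {
  set.seed(77)
  rg <- raster_grid(matrix(runif(25, 1, 20), 5, 5), cellsize = 30)
  lat <- build_lattice(rg, 8)
  sol <- solve_current(lat, 3, 22)
  # net current at interior nodes vanishes
  net <- numeric(lat$n)
  for (e in seq_len(nrow(lat$edges))) {
    net[lat$edges$a[e]] <- net[lat$edges$a[e]] - sol$branch_currents[e]
    net[lat$edges$b[e]] <- net[lat$edges$b[e]] + sol$branch_currents[e]
  }
  expect_lt(max(abs(net[-c(3, 22)])), 1e-6)
  # reciprocity under source/ground exchange
  sol_rev <- solve_current(lat, 22, 3)
  expect_equal(sol$effective_resistance, sol_rev$effective_resistance,
               tolerance = 1e-8)
  expect_equal(sol$node_current, sol_rev$node_current, tolerance = 1e-8)
  # disconnected source/ground fails with a component message
  m <- matrix(c(1, NA, 1), 1, 3)
  lat2 <- build_lattice(raster_grid(m, cellsize = 30), 4)
  expect_error(solve_current(lat2, 1, 2), "disconnected")
})

test_that("cumulative current audits injections and resolves corridors", {
  # two patches joined by a 1-cell-wide uniform corridor: every corridor
  # cell carries the full unit of current
  m <- matrix(NA_real_, 5, 7)
  m[, 1] <- 1; m[, 7] <- 1; m[3, 2:6] <- 1
  rg <- raster_grid(m, cellsize = 30)
  lat <- build_lattice(rg, 4)
  p1 <- lat$node_of[, 1]; p2 <- lat$node_of[, 7]
  cur <- cumulative_current(lat, list(p1, p2), "pairwise")
  corridor_cells <- rg_cell_at(rg, (2:6 - 0.5) * 30, 2.5 * 30)
  expect_equal(unname(cur$current$values[corridor_cells]), rep(1, 5),
               tolerance = 1e-8)
  expect_equal(cur$total_injected, 1)
  # pairwise injection audit over 3 patches: 3 pairs, 1 unit each
  set.seed(5)
  rg3 <- raster_grid(matrix(runif(64, 1, 5), 8, 8), cellsize = 30)
  lat3 <- build_lattice(rg3, 8)
  patches <- list(lat3$node_of[1:2, 1], lat3$node_of[8, 7:8],
                  lat3$node_of[1, 8])
  cur3 <- cumulative_current(lat3, patches, "pairwise")
  expect_equal(cur3$total_injected, 3)
  expect_true(all(cur3$current$values[lat3$cells] >= -1e-12))
  # all_to_one grounds each patch once
  cur_a <- cumulative_current(lat3, patches, "all_to_one")
  expect_equal(cur_a$total_injected, 6)
  expect_error(cumulative_current(lat3, patches[1], "pairwise"), "2 patches")
})

test_that("least-cost paths match the independent Dijkstra oracle", {
  # uniform cost: straight path, cwd = cost x length
  m <- matrix(2, 5, 9)
  rg <- raster_grid(m, cellsize = 30)
  corr <- least_cost_corridors(rg, list(rg_cell_at(rg, 15, 75),
                                        rg_cell_at(rg, 255, 75)), 1)
  expect_equal(corr$corridors$cwd, 2 * 8 * 30, tolerance = 1e-9)
  # wall with a gap: the path routes through the gap
  w <- matrix(1, 9, 9); w[, 5] <- 1000; w[5, 5] <- 1
  rgw <- raster_grid(w, cellsize = 30)
  corrw <- least_cost_corridors(rgw, list(rg_cell_at(rgw, 15, 135),
                                          rg_cell_at(rgw, 255, 135)), 1,
                                connectivity = 4)
  gap_cell <- rg_cell_at(rgw, 135, 135)
  expect_true(gap_cell %in% corrw$paths[[1]])
  expect_lt(corrw$corridors$cwd, 1000)
  # random 10x10 fixture: cwd equals brute-force Dijkstra
  set.seed(31)
  rr <- raster_grid(matrix(runif(100, 1, 30), 10, 10), cellsize = 30)
  lat <- build_lattice(rr, 8)
  c_from <- rg_cell_at(rr, 15, 15); c_to <- rg_cell_at(rr, 285, 285)
  corr_r <- least_cost_corridors(rr, list(c_from, c_to), 1)
  d <- oracle_dijkstra(lat$n, lat$edges, lat$node_of[c_from])
  expect_equal(corr_r$corridors$cwd, d[lat$node_of[c_to]], tolerance = 1e-9)
})

test_that("pinch points honour the area rule and degenerate cases", {
  # synthetic current map over a two-patch corridor landscape
  set.seed(9)
  rg <- raster_grid(matrix(runif(400, 1, 4), 20, 20), cellsize = 100)
  corr <- least_cost_corridors(rg, list(rg_cell_at(rg, 150, 1950),
                                        rg_cell_at(rg, 1850, 50)), 1)
  lat <- corr$lattice
  pn <- list(lat$node_of[rg_cell_at(rg, 150, 1950)],
             lat$node_of[rg_cell_at(rg, 1850, 50)])
  cur <- cumulative_current(lat, pn, "all_to_one")
  pp <- suppressWarnings(pinch_points(cur$current, corr,
                                      cwd_cutoff = 2000, min_area_ha = 5))
  if (nrow(pp$pinch_points)) {
    expect_true(all(pp$pinch_points$area_ha > 5))
  }
  # at 100 m cells one cell is 1 ha: a 4-cell (4 ha) top class is excluded,
  # a 6-cell (6 ha) one retained -- emulate via min_area filtering directly
  pp_all <- suppressWarnings(pinch_points(cur$current, corr,
                                          cwd_cutoff = 2000,
                                          min_area_ha = 0))
  if (nrow(pp_all$pinch_points)) {
    small <- pp_all$pinch_points$area_ha <= 5
    expect_equal(nrow(pp$pinch_points), sum(!small))
  }
  # uniform current: no pinch points, with a warning
  ucur <- rg_with_values(cur$current,
                         matrix(1, rg_nrow(rg), rg_ncol(rg)))
  expect_warning(ppu <- pinch_points(ucur, corr, cwd_cutoff = 2000),
                 "uniform")
  expect_equal(nrow(ppu$pinch_points), 0)
})

test_that("current-flow centrality matches the pseudo-inverse oracle", {
  # 3-node path: the cut vertex is strictly most central
  edges <- data.frame(a = c(1, 2), b = c(2, 3), resistance = c(1, 1))
  cfc <- current_flow_centrality(3, edges)
  expect_gt(cfc$node[2], cfc$node[1])
  expect_gt(cfc$node[2], cfc$node[3])
  # symmetric star: all leaves equal
  star <- data.frame(a = rep(1, 4), b = 2:5, resistance = rep(2, 4))
  cfs <- current_flow_centrality(5, star)
  expect_equal(length(unique(round(cfs$node[2:5], 10))), 1)
  expect_gt(cfs$node[1], cfs$node[2])
  # random weighted 5-node graph vs dense pseudo-inverse oracle
  set.seed(41)
  g <- data.frame(a = c(1, 1, 2, 2, 3, 4), b = c(2, 3, 3, 4, 5, 5),
                  resistance = runif(6, 0.5, 4))
  impl <- current_flow_centrality(5, g)
  orac <- oracle_cfc(5, g)
  expect_equal(impl$node, orac$node, tolerance = 1e-8)
  expect_equal(impl$edge, orac$edge, tolerance = 1e-8)
  # singleton network: zeros
  expect_equal(current_flow_centrality(1, g[0, ])$node, 0)
})

test_that("centrality classification is stable and labelled correctly", {
  v <- c(1, 1, 1, 10, 10, 10, 100, 100)
  cls <- classify_centrality(v)
  expect_identical(cls, c(rep("low", 3), rep("medium", 3), rep("high", 2)))
  # duplication leaves class boundaries unchanged
  expect_identical(classify_centrality(rep(v, 2)), rep(cls, 2))
  expect_warning(all_eq <- classify_centrality(rep(3, 5)), "equal")
  expect_identical(all_eq, rep("low", 5))
})
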