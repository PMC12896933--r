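test_that("corridor nodes appear exactly at cross-guild intersections", {
  horiz <- matrix(c(0, 50, 100, 50), 2, 2, byrow = TRUE)
  vert <- matrix(c(50, 0, 50, 100), 2, 2, byrow = TRUE)
  out <- corridor_nodes(list(wading = list(horiz), raptor = list(vert)), 30)
  expect_equal(nrow(out$nodes), 1)
  expect_equal(c(out$nodes$x, out$nodes$y), c(50, 50))
  # parallel corridors never intersect
  par2 <- matrix(c(0, 60, 100, 60), 2, 2, byrow = TRUE)
  none <- corridor_nodes(list(wading = list(horiz), raptor = list(par2)), 30)
  expect_equal(nrow(none$nodes), 0)
  # same-guild crossings are not nodes
  same <- corridor_nodes(list(wading = list(horiz, vert)), 30)
  expect_equal(nrow(same$nodes), 0)
  # X fixture with 3 guilds: pair counts match hand enumeration
  diag1 <- matrix(c(0, 0, 100, 100), 2, 2, byrow = TRUE)
  x3 <- corridor_nodes(list(a = list(horiz), b = list(vert),
                            c = list(diag1)), 5)
  # a-b cross at (50,50); a-c at (50,50)->merged?; distances: a-c cross at
  # (50,50) exactly too; merged within one cell: counts still per-pair
  expect_equal(sum(x3$pair_counts$n), nrow(x3$nodes))
  expect_true(all(x3$pair_counts$guild_a != x3$pair_counts$guild_b))
})

test_that("source overlaps capture multi-guild richness regions", {
  a <- matrix(0, 12, 12); a[1:8, 1:8] <- 1
  b <- matrix(0, 12, 12); b[3:10, 3:10] <- 1
  c_ <- matrix(0, 12, 12); c_[5:6, 5:6] <- 1
  mk <- function(m) raster_grid(m, cellsize = 100)
  # identical layers: overlap equals the layer with richness 2
  same <- source_overlaps(list(mk(a), mk(a)))
  expect_equal(nrow(same$overlaps), 1)
  expect_equal(same$overlaps$richness, 2)
  expect_equal(same$overlaps$area_km2, sum(a) * 0.01)
  # disjoint layers: no overlap
  d <- matrix(0, 12, 12); d[10:12, 10:12] <- 1
  expect_equal(nrow(source_overlaps(list(mk(a), mk(d)))$overlaps), 0)
  # nested layers: richness takes values {1,2,3}, only >= 2 polygonised
  nest <- source_overlaps(list(mk(a), mk(b), mk(c_)))
  expect_setequal(unique(as.vector(nest$richness$values)), c(0, 1, 2, 3))
  expect_equal(max(nest$overlaps$richness), 3)
  expect_equal(sum(nest$overlaps$area_km2),
               sum(nest$richness$values >= 2) * 0.01)
})

test_that("element densities are linear in weights", {
  rg <- raster_grid(matrix(0, 20, 20), cellsize = 30)
  cellA <- rg_cell_at(rg, 300, 300)
  d1 <- element_density(rg, list(cellA), weights = 1, bandwidth = 120)
  d2 <- element_density(rg, list(cellA), weights = 2, bandwidth = 120)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  # two identical elements double the density
  dd <- element_density(rg, list(cellA, cellA), weights = c(1, 1),
                        bandwidth = 120)
  expect_equal(dd$values, 2 * d1$values, tolerance = 1e-12)
  # uniform weights reduce to the unweighted KDE
  cells <- list(rg_cell_at(rg, 150, 150), rg_cell_at(rg, 450, 450))
  du <- element_density(rg, cells, weights = c(1, 1), bandwidth = 120)
  dn <- element_density(rg, cells, weights = NULL, bandwidth = 120)
  expect_equal(du$values, dn$values)
  # empty set: zero raster flagged empty
  de <- element_density(rg, list(), bandwidth = 120)
  expect_true(all(de$values == 0))
  expect_true(isTRUE(attr(de, "empty")))
})

test_that("layer standardisation maps to the 0-4 ordinal scale", {
  rg <- raster_grid(matrix(0, 10, 10), cellsize = 30)
  # lone hotspot: its cells get 4
  v <- matrix(0, 10, 10); v[5, 5] <- 100
  out <- suppressWarnings(standardize_layer(rg_with_values(rg, v)))
  expect_equal(out$values[5, 5], 4)
  expect_equal(out$values[1, 1], 0)
  # constant raster: all 0
  expect_true(all(standardize_layer(rg_with_values(rg, matrix(3, 10, 10)))
                  $values == 0))
  # rich raster: full 0..4 scale used
  set.seed(2)
  r5 <- standardize_layer(rg_with_values(rg, matrix(rnorm(100), 10, 10)))
  expect_setequal(unique(as.vector(r5$values)), 0:4)
})

test_that("composite priority is monotone with ordered classes", {
  rg <- raster_grid(matrix(0, 12, 12), cellsize = 30)
  mk <- function(m) rg_with_values(rg, m)
  z <- matrix(0, 12, 12)
  blob1 <- z; blob1[2:4, 2:4] <- 4
  blob2 <- z; blob2[9:11, 9:11] <- 4
  layers <- list(sources = mk(blob1), corridors = mk(blob2),
                 pinch_points = mk(z), nodes = mk(z), overlaps = mk(z))
  out <- composite_priority(layers)
  # two disjoint hotspots both land in the high class
  expect_true(all(out$classes$values[2:4, 2:4] == 3))
  expect_true(all(out$classes$values[9:11, 9:11] == 3))
  expect_gte(out$high_priority_fraction, 0)
  expect_lte(out$high_priority_fraction, 1)
  # class-3 cells have composite at least as large as any class-2 cell
  c3 <- out$composite$values[out$classes$values == 3]
  c2 <- out$composite$values[out$classes$values == 2]
  if (length(c2)) expect_gte(min(c3), max(c2))
  # raising one layer at a cell never lowers the composite
  blob1b <- blob1; blob1b[6, 6] <- 2
  out2 <- composite_priority(modifyList(layers, list(sources = mk(blob1b))))
  expect_true(all(out2$composite$values >= out$composite$values))
  # constant composite: single class and zero high-priority area
  expect_warning(flat <- composite_priority(list(sources = mk(z + 4),
                                                 corridors = NULL,
                                                 pinch_points = NULL,
                                                 nodes = NULL,
                                                 overlaps = NULL)),
                 "constant")
  expect_equal(flat$high_priority_fraction, 0)
  expect_setequal(flat$missing_elements,
                  c("corridors", "pinch_points", "nodes", "overlaps"))
})
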