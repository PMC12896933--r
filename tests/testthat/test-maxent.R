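toy_bg <- data.frame(a = runif(50), b = runif(50), c = runif(50))

test_that("feature expansion counts follow the construction rules", {
  expect_equal(ncol(build_features(toy_bg, "L")), 3)
  expect_equal(ncol(build_features(toy_bg, "LQ")), 6)
  # LQHP with 10 knots: 3 linear + 3 quadratic + 3*20 hinge + 3 products
  expect_equal(ncol(build_features(toy_bg, "LQHP", hinge_knots = 10)), 69)
  expect_error(build_features(toy_bg, "XYZ"), "unknown feature set")
  # categorical covariates expand to indicators regardless of feature set
  bg2 <- cbind(toy_bg, lu = sample(1:4, 50, replace = TRUE))
  X <- build_features(bg2, "L", categorical = "lu")
  expect_equal(ncol(X), 3 + 4)
  expect_true(all(X[, attr(X, "feature_class") == "categorical"] %in% 0:1))
})

test_that("features are standardised by the background range", {
  bg <- data.frame(a = c(2, 4, 6))
  spec <- build_feature_spec(bg, "L")
  X <- apply_features(spec, data.frame(a = c(2, 6, 4, 8, 0)))
  expect_equal(as.vector(X), c(0, 1, 0.5, 1, 0))   # clamped outside range
})

test_that("the AICc formula matches its closed form", {
  # k = 3, n = 20, LL = -50 -> 2*3 + 100 + 24/16 = 107.5
  aicc <- function(k, n, ll) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(aicc(3, 20, -50), 107.5)
  fx <- make_recovery_fixture(31, n_pres = 40, n_bg = 300)
  m <- suppressWarnings(fit_maxent(fx$pres[1:40, ], fx$bg, "L", rm = 1))
  a <- model_aicc(m, fx$pres[1:40, ])
  expect_equal(a$aicc, aicc(a$k, a$n, a$ll))
})

test_that("extreme regularization shrinks every coefficient to zero", {
  fx <- make_recovery_fixture(32, n_pres = 60, n_bg = 400)
  m <- suppressWarnings(fit_maxent(fx$pres[1:60, ], fx$bg, "LQ", rm = 1e6))
  expect_true(all(m$beta == 0))
  p <- predict(m, fx$bg)
  expect_equal(length(unique(round(p, 12))), 1)   # uniform prediction
})

test_that("a separating binary feature gets a positive coefficient", {
  pres <- data.frame(f = rep(1, 30))
  bg <- data.frame(f = rep(c(0, 1), each = 50))
  m <- suppressWarnings(fit_maxent(pres, bg, "L", rm = 0.5))
  expect_gt(m$beta[1], 0)
})

test_that("presences score above background under a planted 1-D response", {
  set.seed(14)
  bg <- data.frame(z = runif(400))
  pres <- data.frame(z = rbeta(80, 5, 1))     # concentrated at high z
  m <- suppressWarnings(fit_maxent(pres, bg, "L", rm = 1))
  expect_gt(mean(predict(m, pres)), mean(predict(m, bg)))
})

test_that("stronger regularization shrinks the coefficient path", {
  fx <- make_recovery_fixture(33, n_pres = 100, n_bg = 600)
  fits <- lapply(c(0.5, 1, 2, 4, 8), function(r) {
    suppressWarnings(fit_maxent(fx$pres[1:100, ], fx$bg, "LQ", rm = r))
  })
  # the L1 norm of the solution is non-increasing along the penalty path
  # (the active-set SIZE need not be monotone for L1 paths)
  l1 <- vapply(fits, function(m) sum(abs(m$beta)), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
  # and the most-penalised fit uses no more features than the least
  expect_lte(sum(fits[[5]]$beta != 0), sum(fits[[1]]$beta != 0))
})

test_that("MaxTSS threshold matches an exhaustive scan", {
  # separable case: sensitivity and specificity both 1 at the returned value
  thr <- maxtss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(mean(c(0.8, 0.9) >= thr), 1)
  expect_equal(mean(c(0.1, 0.2) < thr), 1)
  set.seed(20)
  for (rep in 1:10) {
    ps <- round(runif(30), 2); bs <- round(runif(50), 2)
    thr <- maxtss_threshold(ps, bs)
    cand <- sort(unique(c(ps, bs)))
    tss <- vapply(cand, function(t) mean(ps >= t) + mean(bs < t), numeric(1))
    expect_equal(mean(ps >= thr) + mean(bs < thr), max(tss))
    expect_equal(thr, cand[which.max(tss)])   # lowest tied threshold
  }
  # identical distributions: max sens+spec is 1
  thr <- maxtss_threshold(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mean(c(1, 2, 3) >= thr) + mean(c(1, 2, 3) < thr), 1)
})

test_that("binarization respects the threshold, nodata and monotonicity", {
  v <- matrix(runif(100), 10, 10); v[1, 1] <- NA
  rg <- raster_grid(v)
  expect_equal(sum(binarize(rg, 0)$values, na.rm = TRUE), 99)
  expect_equal(sum(binarize(rg, 1 + 1e-9)$values, na.rm = TRUE), 0)
  expect_true(is.na(binarize(rg, 0.5)$values[1, 1]))
  counts <- vapply(seq(0, 1, 0.1), function(t)
    sum(binarize(rg, t)$values, na.rm = TRUE), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("omission and AUC evaluation count correctly", {
  fx <- make_recovery_fixture(34, n_pres = 20, n_bg = 100)
  m <- suppressWarnings(fit_maxent(fx$pres[1:20, ], fx$bg, "L", rm = 1))
  # direct omission count on a hand fixture via the same rule
  expect_equal(mean(c(0.9, 0.4) < 0.5), 0.5)
  ev <- evaluate_model(m, fx$pres[1:20, ], fx$bg, threshold = 0.5)
  expect_equal(ev$omission, mean(predict(m, fx$pres[1:20, ]) < 0.5))
})

test_that("collinearity screening drops the less important of a flagged pair", {
  set.seed(3)
  base <- runif(200)
  cov <- data.frame(p = base + rnorm(200, 0, 0.05),     # r > 0.8 with q
                    q = base + rnorm(200, 0, 0.05),
                    r = runif(200))
  imp <- c(p = 10, q = 5, r = 20)
  out <- screen_collinearity(cov, imp, 0.8)
  expect_setequal(out$retained, c("p", "r"))
  expect_identical(out$removed$variable, "q")
  # all below threshold: everything retained
  cov2 <- data.frame(p = runif(100), q = runif(100))
  expect_setequal(screen_collinearity(cov2, c(p = 1, q = 2))$retained,
                  c("p", "q"))
  # three mutually correlated: only the most important survives
  cov3 <- data.frame(x1 = base, x2 = base + rnorm(200, 0, 0.01),
                     x3 = base + rnorm(200, 0, 0.01))
  out3 <- screen_collinearity(cov3, c(x1 = 1, x2 = 9, x3 = 5), 0.8)
  expect_identical(out3$retained, "x2")
  # constant covariate dropped with a warning
  cov4 <- data.frame(x = runif(50), k = rep(1, 50))
  expect_warning(out4 <- screen_collinearity(cov4, c(x = 1, k = 1)),
                 "constant")
  expect_identical(out4$retained, "x")
})

test_that("jackknife importances are symmetric, normalised and signal-seeking", {
  set.seed(15)
  bg <- data.frame(u = runif(300), v = runif(300))
  pres <- data.frame(u = rbeta(60, 6, 1), v = runif(60))
  # duplicated covariates: near-equal importance
  dup_bg <- data.frame(a = bg$u, b = bg$u)
  dup_pres <- data.frame(a = pres$u, b = pres$u)
  imp_dup <- suppressWarnings(jackknife_importance(dup_pres, dup_bg, "L"))
  expect_equal(imp_dup$importance[1], imp_dup$importance[2], tolerance = 5)
  expect_equal(sum(imp_dup$importance), 100, tolerance = 1e-6)
  # planted signal dominates
  imp <- jackknife_importance(pres, bg, "LQ")
  expect_identical(imp$variable[which.max(imp$importance)], "u")
  expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
})

test_that("cross-validation scheme follows the record-count rule", {
  fx <- make_recovery_fixture(35, n_pres = 60, n_bg = 300)
  sub14 <- fx$pres[1:14, ]
  cv14 <- suppressWarnings(cross_validate(sub14, fx$bg, fx$stack, "spring",
                                          feature_set = "L", rm = 1))
  expect_identical(cv14$scheme, "loo")
  expect_equal(cv14$n_folds, 14)
  sub15 <- fx$pres[1:15, ]
  cv15 <- suppressWarnings(cross_validate(sub15, fx$bg, fx$stack, "spring",
                                          feature_set = "L", rm = 1))
  expect_identical(cv15$scheme, "five_fold")
  expect_equal(cv15$n_folds, 5)
  expect_true(all(cv15$suitability$values >= 0 & cv15$suitability$values <= 1))
})

test_that("tuning selects among delta-AICc-eligible candidates", {
  fx <- make_recovery_fixture(36, n_pres = 80, n_bg = 500)
  tn <- suppressWarnings(tune_maxent(fx$pres[1:80, ], fx$bg, fx$pres_xy[1:80, ],
                                     feature_sets = c("L", "LQ"),
                                     rm_grid = c(1, 2)))
  expect_equal(nrow(tn$table), 4)
  expect_true(all(tn$table$delta_aicc >= 0, na.rm = TRUE))
  sel <- tn$table[tn$table$feature_set == tn$selected$feature_set &
                    tn$table$rm == tn$selected$rm, ]
  expect_lt(sel$delta_aicc, 2)
  # the selected candidate has the lowest CV omission among eligibles
  elig <- tn$table[!is.na(tn$table$cv_omission) & tn$table$delta_aicc < 2, ]
  expect_equal(sel$cv_omission, min(elig$cv_omission))
})
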