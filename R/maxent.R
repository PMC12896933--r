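# Presence-background maximum-entropy habitat modelling: feature
# construction (linear/quadratic/hinge/product + categorical indicators),
# L1-penalised fitting by diagonal proximal-Newton coordinate updates,
# AICc-based tuning over feature-set x regularization-multiplier grids with
# spatial-block cross-validation, jackknife variable importance, collinearity
# screening, MaxTSS binarization.

MX_FEATURE_SETS <- c("L", "H", "LQ", "LQH", "LQHP")

#' Seasonal covariate frame
#'
#' Extracts the covariate layers relevant to one season into a data.frame
#' over grid cells, renaming seasonal climate layers (`PREC_<season>` etc.)
#' to their generic names so models fitted in different seasons share a
#' variable vocabulary.
#'
#' @param stack named list of `raster_grid`s.
#' @param season one of `SEASONS`.
#' @param cells linear cell indices (default all cells).
#' @return data.frame of covariate values, one row per cell.
#' @export
seasonal_covariate_frame <- function(stack, season, cells = NULL) {
  nm <- names(stack)
  seasonal <- grepl(paste0("_(", paste(SEASONS, collapse = "|"), ")$"), nm)
  keep <- nm[!seasonal]
  this_season <- nm[seasonal & endsWith(nm, paste0("_", season))]
  out <- list()
  for (v in keep) out[[v]] <- as.vector(stack[[v]]$values)
  for (v in this_season) {
    out[[sub(paste0("_", season, "$"), "", v)]] <- as.vector(stack[[v]]$values)
  }
  df <- as.data.frame(out)
  if (!is.null(cells)) df <- df[cells, , drop = FALSE]
  df
}

#' Build a feature expansion specification from background covariates
#'
#' Continuous covariates are min-max standardised to [0, 1] using the
#' background range. Feature classes: `L` identity, `Q` squares, `P` all
#' pairwise products of continuous covariates, `H` forward and reverse hinges
#' at evenly spaced interior knots. Categorical covariates always expand to
#' one indicator per observed class, whatever the feature set, and never
#' enter products.
#'
#' @param bg data.frame of covariates at background points.
#' @param feature_set one of `"L"`, `"H"`, `"LQ"`, `"LQH"`, `"LQHP"`.
#' @param categorical names of categorical covariates.
#' @param hinge_knots number of interior hinge knots per covariate.
#' @return a `feature_spec` object.
#' @export
build_feature_spec <- function(bg, feature_set = "LQH",
                               categorical = character(0), hinge_knots = 10) {
  if (!feature_set %in% MX_FEATURE_SETS) {
    stop("unknown feature set '", feature_set, "'; use one of ",
         paste(MX_FEATURE_SETS, collapse = ", "))
  }
  vars <- names(bg)
  cont <- setdiff(vars, categorical)
  ranges <- lapply(bg[cont], range, na.rm = TRUE)
  cat_levels <- lapply(bg[intersect(categorical, vars)],
                       function(v) sort(unique(v[!is.na(v)])))
  knots <- if (hinge_knots > 0) {
    seq(0, 1, length.out = hinge_knots + 2)[-c(1, hinge_knots + 2)]
  } else numeric(0)
  structure(list(vars = vars, cont = cont, categorical = names(cat_levels),
                 ranges = ranges, cat_levels = cat_levels,
                 feature_set = feature_set, knots = knots),
            class = "feature_spec")
}

#' Apply a feature specification to covariate values
#'
#' @param spec a `feature_spec` from [build_feature_spec()].
#' @param df data.frame of covariates (same columns as the background used to
#'   build the spec).
#' @return numeric matrix with one column per feature; columns carry a
#'   `feature_class` attribute (`linear`, `quadratic`, `hinge`, `product`,
#'   `categorical`).
#' @export
apply_features <- function(spec, df) {
  fs <- strsplit(spec$feature_set, "")[[1]]
  z <- lapply(spec$cont, function(v) {
    r <- spec$ranges[[v]]
    if (diff(r) == 0) rep(0, nrow(df)) else
      pmin(pmax((df[[v]] - r[1]) / (r[2] - r[1]), 0), 1)
  })
  names(z) <- spec$cont
  cols <- list(); classes <- character(0)
  addcol <- function(vals, nm, cl) {
    cols[[length(cols) + 1L]] <<- vals
    names(cols)[length(cols)] <<- nm
    classes <<- c(classes, cl)
  }
  if ("L" %in% fs) for (v in spec$cont) addcol(z[[v]], v, "linear")
  if ("Q" %in% fs) for (v in spec$cont) addcol(z[[v]]^2, paste0(v, "^2"), "quadratic")
  if ("H" %in% fs && length(spec$knots)) {
    for (v in spec$cont) {
      for (k in spec$knots) {
        addcol(pmax(0, (z[[v]] - k) / (1 - k)),
               sprintf("h(%s>%.3f)", v, k), "hinge")
        addcol(pmax(0, (k - z[[v]]) / k),
               sprintf("h(%s<%.3f)", v, k), "hinge")
      }
    }
  }
  if ("P" %in% fs && length(spec$cont) >= 2) {
    cc <- spec$cont
    for (i in seq_len(length(cc) - 1)) {
      for (j in (i + 1):length(cc)) {
        addcol(z[[cc[i]]] * z[[cc[j]]], paste0(cc[i], "*", cc[j]), "product")
      }
    }
  }
  for (v in spec$categorical) {
    for (lv in spec$cat_levels[[v]]) {
      addcol(as.numeric(df[[v]] == lv), sprintf("%s==%g", v, lv), "categorical")
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "feature_class") <- classes
  X
}

#' Convenience feature matrix builder
#' @inheritParams build_feature_spec
#' @param df points at which to evaluate features (default the background).
#' @return feature matrix (see [apply_features()]).
#' @export
build_features <- function(bg, feature_set = "LQH", df = bg,
                           categorical = character(0), hinge_knots = 10) {
  apply_features(
    build_feature_spec(bg, feature_set, categorical, hinge_knots), df)
}

# per-feature L1 penalty: class constant x background sd / sqrt(n presences)
mx_lambda <- function(Xb, classes, rm, n_pres) {
  cl_c <- c(linear = 1, quadratic = 1, product = 1,
            hinge = 0.5, categorical = 0.25)
  sds <- apply(Xb, 2, sd)
  rm * cl_c[classes] * pmax(sds, 0.02) / sqrt(n_pres)
}

mx_penalized_loss <- function(beta, Xp, Xb, lambda) {
  eb <- as.vector(Xb %*% beta)
  m <- max(eb)
  log(sum(exp(eb - m))) + m - mean(Xp %*% beta) + sum(lambda * abs(beta))
}

#' Fit the penalised maximum-entropy model
#'
#' Minimises the regularised presence-background loss: the log-partition
#' function over background minus the mean feature value at presences, plus
#' per-feature L1 penalties scaled by the regularization multiplier. Solved
#' by damped diagonal proximal-Newton coordinate updates with soft
#' thresholding and backtracking; converged when the maximal
#' Karush-Kuhn-Tucker violation falls below `tol`.
#'
#' @param Xp feature matrix at presences.
#' @param Xb feature matrix at background points.
#' @param lambda per-feature penalty vector.
#' @param maxit maximum sweeps.
#' @param tol KKT tolerance.
#' @return list `beta`, `converged`, `iter`.
#' @export
mx_solve <- function(Xp, Xb, lambda, maxit = 500, tol = 1e-5) {
  p <- ncol(Xb)
  beta <- numeric(p)
  mp <- colMeans(Xp)
  loss <- mx_penalized_loss(beta, Xp, Xb, lambda)
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    eb <- as.vector(Xb %*% beta)
    mx <- max(eb)
    w <- exp(eb - mx)
    q <- w / sum(w)
    Eq <- as.vector(crossprod(Xb, q))
    g <- Eq - mp
    h <- as.vector(crossprod(Xb^2, q)) - Eq^2
    # KKT violation
    viol <- ifelse(beta != 0, abs(g + lambda * sign(beta)),
                   pmax(abs(g) - lambda, 0))
    if (max(viol) < tol) { converged <- TRUE; break }
    h <- pmax(h, 1e-8)
    prop <- sign(h * beta - g) * pmax(abs(h * beta - g) - lambda, 0) / h
    step <- 1
    repeat {
      cand <- beta + step * (prop - beta)
      lc <- mx_penalized_loss(cand, Xp, Xb, lambda)
      if (lc <= loss + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    if (lc > loss - 1e-12 && step < 1e-4) break  # no further progress
    beta <- cand
    loss <- lc
  }
  list(beta = beta, converged = converged, iter = it)
}

#' Fit a maxent model to a presence/background dataset
#'
#' @param pres data.frame of covariates at presence points.
#' @param bg data.frame of covariates at background points.
#' @param feature_set feature classes, one of `MX_FEATURE_SETS`.
#' @param rm regularization multiplier (> 0).
#' @param categorical categorical covariate names.
#' @param hinge_knots interior hinge knots per covariate.
#' @param maxit,tol optimiser controls.
#' @return object of class `maxent_model`: feature spec, coefficients,
#'   log-partition over background, entropy of the background distribution
#'   (for the cloglog transform), convergence flag.
#' @export
fit_maxent <- function(pres, bg, feature_set = "LQH", rm = 1,
                       categorical = character(0), hinge_knots = 10,
                       maxit = 500, tol = 1e-5) {
  stopifnot(rm > 0, nrow(bg) > 0)
  if (nrow(pres) < 2) stop("fit_maxent needs at least 2 presence points")
  spec <- build_feature_spec(bg, feature_set, categorical, hinge_knots)
  Xb <- apply_features(spec, bg)
  Xp <- apply_features(spec, pres)
  lambda <- mx_lambda(Xb, attr(Xb, "feature_class"), rm, nrow(Xp))
  sol <- mx_solve(Xp, Xb, lambda, maxit = maxit, tol = tol)
  if (!sol$converged) {
    warning("fit_maxent: optimiser returned best iterate without full convergence")
  }
  eb <- as.vector(Xb %*% sol$beta)
  mx <- max(eb)
  logZ <- log(sum(exp(eb - mx))) + mx
  q <- exp(eb - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(spec = spec, beta = sol$beta,
                 feature_names = colnames(Xb),
                 feature_class = attr(Xb, "feature_class"),
                 rm = rm, lambda = lambda, logZ = logZ, entropy = H,
                 n_pres = nrow(Xp), n_bg = nrow(Xb),
                 converged = sol$converged),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s features, rm = %g: %d/%d nonzero coefficients (%s)\n",
    x$spec$feature_set, x$rm, sum(x$beta != 0), length(x$beta),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict from a maxent model
#'
#' @param object a `maxent_model`.
#' @param newdata data.frame of covariates.
#' @param type `"cloglog"` (default, in [0, 1]), `"raw"` (normalised to sum
#'   to 1 over the background), or `"link"` (linear predictor).
#' @param ... unused.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "raw", "link"), ...) {
  type <- match.arg(type)
  X <- apply_features(object$spec, newdata)
  link <- as.vector(X %*% object$beta)
  if (type == "link") return(link)
  raw <- exp(link - object$logZ)
  if (type == "raw") return(raw)
  1 - exp(-exp(object$entropy) * raw)
}

#' Predict a suitability raster for a season
#' @param model a `maxent_model`.
#' @param stack covariate stack.
#' @param season season whose climate layers to use.
#' @return `raster_grid` of cloglog suitability in [0, 1].
#' @export
predict_suitability <- function(model, stack, season) {
  df <- seasonal_covariate_frame(stack, season)
  p <- predict(model, df)
  rg_with_values(stack[[1]], matrix(p, rg_nrow(stack[[1]]), rg_ncol(stack[[1]])))
}

#' Training gain of a maxent model
#'
#' Mean linear predictor at presences minus the log mean exponentiated
#' predictor over background; 0 for the null model.
#'
#' @param model a `maxent_model`.
#' @param pres presence covariate data.frame.
#' @param bg background covariate data.frame.
#' @export
maxent_gain <- function(model, pres, bg) {
  lp <- predict(model, pres, type = "link")
  lb <- predict(model, bg, type = "link")
  mx <- max(lb)
  mean(lp) - (log(mean(exp(lb - mx))) + mx)
}

#' AICc of a maxent model
#'
#' Likelihood is the presence log-likelihood under the raw model normalised
#' over the background; `k` is the number of nonzero coefficients. Returns
#' `NA` (candidate unusable) when `n - k - 1 <= 0`.
#'
#' @param model a `maxent_model`.
#' @param pres presence covariate data.frame.
#' @return list `aicc`, `ll`, `k`, `n`.
#' @export
model_aicc <- function(model, pres) {
  k <- sum(model$beta != 0)
  n <- nrow(pres)
  ll <- sum(log(predict(model, pres, type = "raw")))
  aicc <- if (n - k - 1 > 0) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
          else NA_real_
  list(aicc = aicc, ll = ll, k = k, n = n)
}

#' Checkerboard spatial blocks
#'
#' Assigns points to a 2 x 2 checkerboard of spatial blocks over their
#' bounding box, round-robin into folds.
#'
#' @param x,y point coordinates.
#' @param n_folds number of folds (default 4 = one block per fold).
#' @return integer fold per point.
#' @export
checkerboard_folds <- function(x, y, n_folds = 4) {
  bx <- as.integer(x > (min(x) + max(x)) / 2)
  by <- as.integer(y > (min(y) + max(y)) / 2)
  block <- 2L * by + bx           # 0..3
  block %% n_folds + 1L
}

#' Evaluate a model on test presences vs background
#'
#' @param model a `maxent_model`.
#' @param test_pres covariates at test presences.
#' @param bg covariates at background points.
#' @param threshold omission threshold on the cloglog scale.
#' @return list `auc`, `omission`, `n_params`.
#' @export
evaluate_model <- function(model, test_pres, bg, threshold = NULL) {
  sp <- predict(model, test_pres)
  sb <- predict(model, bg)
  auc <- if (all(c(sp, sb) == c(sp, sb)[1])) 0.5 else rank_auc(sp, sb)
  om <- if (is.null(threshold)) NA_real_ else mean(sp < threshold)
  list(auc = auc, omission = om, n_params = sum(model$beta != 0))
}

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans candidate thresholds (the sorted unique scores) and returns the one
#' maximising sensitivity + specificity; ties break toward the lowest
#' threshold. Sensitivity counts presences scoring at or above the
#' threshold; specificity counts background scoring below it.
#'
#' @param pres_scores,bg_scores numeric score vectors.
#' @return the selected threshold.
#' @export
maxtss_threshold <- function(pres_scores, bg_scores) {
  stopifnot(length(pres_scores) > 0, length(bg_scores) > 0)
  cand <- sort(unique(c(pres_scores, bg_scores)))
  sens <- vapply(cand, function(t) mean(pres_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(bg_scores < t), numeric(1))
  tss <- sens + spec
  cand[which.max(tss)]  # which.max returns the first (lowest) maximiser
}

#' Binarize a suitability raster at a threshold
#' @param rg suitability `raster_grid`.
#' @param threshold cells with suitability >= threshold become 1, others 0;
#'   nodata preserved.
#' @return binary `raster_grid`.
#' @export
binarize <- function(rg, threshold) {
  v <- rg$values
  b <- ifelse(is.na(v), NA, as.numeric(v >= threshold))
  rg_with_values(rg, b)
}

#' Jackknife variable importance
#'
#' For each covariate, refits the model without it; importance is the drop in
#' training gain relative to the full model, normalised to sum to 100
#' percent (negative drops are floored at zero). With-only gains are also
#' reported. When the full model has no positive gain, importances are
#' uniform with a warning.
#'
#' @param pres,bg covariate data.frames (>= 2 covariates).
#' @param feature_set,rm,categorical,hinge_knots model settings.
#' @return data.frame `variable`, `gain_without`, `gain_with_only`,
#'   `importance` (percent, sums to 100).
#' @export
jackknife_importance <- function(pres, bg, feature_set = "LQ", rm = 1,
                                 categorical = character(0), hinge_knots = 10) {
  vars <- names(bg)
  stopifnot(length(vars) >= 2)
  fit1 <- function(v) {
    suppressWarnings(fit_maxent(pres[v], bg[v], feature_set, rm,
                                intersect(categorical, v), hinge_knots))
  }
  full <- fit1(vars)
  gain_full <- maxent_gain(full, pres[vars], bg[vars])
  gw <- go <- numeric(length(vars))
  for (i in seq_along(vars)) {
    rest <- vars[-i]
    mw <- fit1(rest)
    gw[i] <- maxent_gain(mw, pres[rest], bg[rest])
    mo <- fit1(vars[i])
    go[i] <- maxent_gain(mo, pres[vars[i]], bg[vars[i]])
  }
  drop <- pmax(gain_full - gw, 0)
  if (gain_full <= 0 || sum(drop) <= 0) {
    warning("jackknife_importance: no positive training gain; uniform importances")
    imp <- rep(100 / length(vars), length(vars))
  } else {
    imp <- 100 * drop / sum(drop)
  }
  data.frame(variable = vars, gain_without = gw, gain_with_only = go,
             importance = imp)
}

#' Iterative collinearity screening
#'
#' Computes Spearman correlations between covariates over the supplied cells
#' and repeatedly removes, from the most-correlated pair exceeding the
#' threshold, the member with the lower jackknife importance, until no pair
#' exceeds the threshold. Constant covariates (undefined correlation) are
#' dropped first with a warning.
#'
#' @param cov data.frame of covariate values over valid cells.
#' @param importances named numeric importances (percent) for all covariates.
#' @param r_threshold absolute Spearman correlation threshold.
#' @return list `retained` (names), `removed` (data.frame `variable`,
#'   `partner`, `r` in removal order).
#' @export
screen_collinearity <- function(cov, importances, r_threshold = 0.8) {
  vars <- names(cov)
  stopifnot(all(vars %in% names(importances)))
  const <- vars[vapply(cov, function(v) var(v, na.rm = TRUE) == 0, logical(1))]
  removed <- list()
  if (length(const)) {
    warning("screen_collinearity: dropping constant covariate(s): ",
            paste(const, collapse = ", "))
    for (v in const) removed[[length(removed) + 1L]] <-
      data.frame(variable = v, partner = NA_character_, r = NA_real_)
    vars <- setdiff(vars, const)
  }
  repeat {
    if (length(vars) < 2) break
    cm <- suppressWarnings(cor(cov[vars], method = "spearman",
                               use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(abs(cm), na.rm = TRUE) <= r_threshold) break
    ij <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- vars[ij[1]]; b <- vars[ij[2]]
    drop <- if (importances[a] < importances[b]) a else b
    keepv <- setdiff(c(a, b), drop)
    removed[[length(removed) + 1L]] <- data.frame(
      variable = drop, partner = keepv, r = cm[ij[1], ij[2]])
    vars <- setdiff(vars, drop)
  }
  list(retained = vars,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(variable = character(0), partner = character(0),
                    r = numeric(0)))
}

#' Tune feature set and regularization multiplier
#'
#' Fits every candidate on the full dataset, computes AICc (k = nonzero
#' coefficients, presence likelihood under the background-normalised raw
#' model), and among candidates with delta AICc < 2 selects the lowest mean
#' omission rate under checkerboard spatial-block cross-validation; ties
#' break toward fewer parameters, then lower rm. Candidates whose AICc is
#' undefined (too few presences for their parameter count) are skipped.
#'
#' @param pres,bg covariate data.frames.
#' @param pres_xy two-column matrix of presence coordinates (for blocks).
#' @param feature_sets candidate feature class sets.
#' @param rm_grid candidate regularization multipliers.
#' @param categorical,hinge_knots feature settings.
#' @param n_folds spatial-block folds.
#' @param cv_all also cross-validate AICc-ineligible candidates (slower).
#' @return list `selected` (`feature_set`, `rm`), `model` (refit on all
#'   data), `table` (per-candidate diagnostics).
#' @export
tune_maxent <- function(pres, bg, pres_xy,
                        feature_sets = MX_FEATURE_SETS,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        categorical = character(0), hinge_knots = 10,
                        n_folds = 4, cv_all = FALSE) {
  grid <- expand.grid(feature_set = feature_sets, rm = rm_grid,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  tab <- grid
  tab$aicc <- tab$n_params <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- suppressWarnings(fit_maxent(pres, bg, grid$feature_set[i],
                                     grid$rm[i], categorical, hinge_knots))
    fits[[i]] <- m
    a <- model_aicc(m, pres)
    tab$aicc[i] <- a$aicc
    tab$n_params[i] <- a$k
  }
  if (all(is.na(tab$aicc))) stop("tune_maxent: AICc undefined for every candidate")
  tab$delta_aicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  eligible <- which(!is.na(tab$delta_aicc) & tab$delta_aicc < 2)
  tab$cv_auc <- tab$cv_omission <- NA_real_
  folds <- checkerboard_folds(pres_xy[, 1], pres_xy[, 2], n_folds)
  do_cv <- if (cv_all) which(!is.na(tab$aicc)) else eligible
  for (i in do_cv) {
    aucs <- oms <- c()
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (sum(tr) < 2 || sum(!tr) < 1) next
      m <- suppressWarnings(fit_maxent(pres[tr, , drop = FALSE], bg,
                                       grid$feature_set[i], grid$rm[i],
                                       categorical, hinge_knots))
      thr <- maxtss_threshold(predict(m, pres[tr, , drop = FALSE]),
                              predict(m, bg))
      ev <- evaluate_model(m, pres[!tr, , drop = FALSE], bg, thr)
      aucs <- c(aucs, ev$auc); oms <- c(oms, ev$omission)
    }
    tab$cv_auc[i] <- mean(aucs)
    tab$cv_omission[i] <- mean(oms)
  }
  cand <- tab[eligible, , drop = FALSE]
  ord <- order(cand$cv_omission, cand$n_params, cand$rm)
  best <- eligible[ord[1]]
  list(selected = list(feature_set = tab$feature_set[best], rm = tab$rm[best]),
       model = fits[[best]], table = tab)
}

#' Cross-validated suitability prediction
#'
#' Species-seasons with at least 15 presences use five-fold cross-validation;
#' those with 10-14 use leave-one-out with as many replicates as records. The
#' final suitability raster is the mean prediction over folds.
#'
#' @param pres,bg covariate data.frames.
#' @param stack covariate stack for raster prediction.
#' @param season season of the dataset.
#' @param feature_set,rm,categorical,hinge_knots model settings.
#' @param seed seed for the five-fold split.
#' @return list `suitability` (mean `raster_grid`), `fold_evals`
#'   (data.frame), `scheme`, `n_folds`.
#' @export
cross_validate <- function(pres, bg, stack, season, feature_set = "LQ",
                           rm = 1, categorical = character(0),
                           hinge_knots = 10, seed = 1) {
  n <- nrow(pres)
  if (n < 10) stop("cross_validate requires at least 10 presences")
  scheme <- if (n >= 15) "five_fold" else "loo"
  folds <- if (scheme == "five_fold") {
    with_seed(seed, sample(rep_len(1:5, n)))
  } else seq_len(n)
  acc <- NULL; evals <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- suppressWarnings(fit_maxent(pres[tr, , drop = FALSE], bg, feature_set,
                                     rm, categorical, hinge_knots))
    sr <- predict_suitability(m, stack, season)
    acc <- if (is.null(acc)) sr$values else acc + sr$values
    thr <- maxtss_threshold(predict(m, pres[tr, , drop = FALSE]),
                            predict(m, bg))
    ev <- evaluate_model(m, pres[!tr, , drop = FALSE], bg, thr)
    evals[[f]] <- data.frame(fold = f, n_test = sum(!tr),
                             auc = ev$auc, omission = ev$omission)
  }
  k <- length(unique(folds))
  list(suitability = rg_with_values(stack[[1]], acc / k),
       fold_evals = do.call(rbind, evals), scheme = scheme, n_folds = k)
}
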