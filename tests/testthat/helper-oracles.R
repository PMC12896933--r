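# Independent brute-force oracles used to verify package implementations.

# Exhaustive Jenks: minimal within-class sum of squared deviations over all
# ordered partitions of the sorted values into k contiguous nonempty classes.
oracle_jenks_ssd <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- combn(n - 1, k - 1)
  if (k == 1) return(ssd(xs))
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ssd(xs[(cuts[i] + 1):cuts[i + 1]])
    best <- min(best, tot)
  }
  best
}

jenks_total_ssd <- function(x, breaks) {
  cls <- jenks_assign(x, breaks)
  sum(unlist(lapply(split(x, cls), function(g) (g - mean(g))^2)))
}

# Trapezoidal ROC integration oracle for AUC.
oracle_roc_auc <- function(pos, neg) {
  thr <- rev(sort(unique(c(pos, neg, -Inf, Inf))))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# O(n^2) Dijkstra oracle over an explicit edge list (undirected).
oracle_dijkstra <- function(n, edges, from) {
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges$a[e]; b <- edges$b[e]; w <- edges$w[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
  }
  dist
}

# Dense Laplacian pseudo-inverse oracle for current-flow centrality.
oracle_cfc <- function(n, edges) {
  cv <- 1 / edges$resistance
  L <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    a <- edges$a[e]; b <- edges$b[e]
    L[a, b] <- L[a, b] - cv[e]; L[b, a] <- L[b, a] - cv[e]
    L[a, a] <- L[a, a] + cv[e]; L[b, b] <- L[b, b] + cv[e]
  }
  Lp <- MASS::ginv(L)
  prs <- combn(n, 2)
  node <- numeric(n); edge <- numeric(nrow(edges))
  for (pp in seq_len(ncol(prs))) {
    s <- prs[1, pp]; t <- prs[2, pp]
    v <- Lp[, s] - Lp[, t]
    ie <- cv * (v[edges$a] - v[edges$b])
    edge <- edge + abs(ie)
    thr <- numeric(n)
    for (e in seq_len(nrow(edges))) {
      thr[edges$a[e]] <- thr[edges$a[e]] + abs(ie[e]) / 2
      thr[edges$b[e]] <- thr[edges$b[e]] + abs(ie[e]) / 2
    }
    thr[c(s, t)] <- 1
    node <- node + thr
  }
  list(node = node / ncol(prs), edge = edge / ncol(prs))
}

# small standard synthetic dataset reused across maxent tests
make_recovery_fixture <- function(seed, n_pres = 200, n_bg = 1000,
                                  rows = 40, cols = 40) {
  cfg <- synthetic_config(grid_rows = rows, grid_cols = cols, seed = seed,
                          n_species = 1, records_per_species_season = n_pres,
                          bias_strength = 0)
  st <- generate_covariate_stack(cfg)
  occ <- generate_occurrences(st, cfg)
  sub <- occ$occurrences[assign_season(occ$occurrences$date) == "spring", ]
  rg <- st[[1]]
  set.seed(seed + 5000)
  bgc <- sample(length(rg$values), n_bg)
  vars <- c("D_WAT", "TMP", "NDVI", "ELE", "LIGHT")
  list(
    stack = st, cfg = cfg,
    pres = seasonal_covariate_frame(st, "spring",
                                    rg_cell_at(rg, sub$x, sub$y))[vars],
    bg = seasonal_covariate_frame(st, "spring", bgc)[vars],
    pres_xy = cbind(sub$x, sub$y),
    truth = occ$truth[["sp01.spring"]]
  )
}
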