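# End-to-end orchestration: configuration, seasonal runs across guilds,
# output writing and the reproducibility manifest.

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: thinning
#' radius 500 m, minimum 10 records per species-season, 10,000 background
#' points from the pooled-record bias kernel, the five feature sets with
#' regularization multipliers 0.5-4 (step 0.5), MaxTSS binarization, guild
#' minimum patch areas (0.5 km2 songbirds, 2 km2 others), recreation KDE
#' bandwidth 250 m, 8-neighbour lattices, 4 nearest corridor neighbours,
#' cost-weighted distance cutoff 10,000 for pinch points, and 500 m element
#' KDE bandwidth for priority mapping.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seasons = SEASONS,
    guilds = GUILDS,
    seed = 1L,
    thin_radius = 500,
    min_records = 10,
    n_background = 10000,
    bias_bandwidth_cells = 10,
    feature_sets = MX_FEATURE_SETS,
    rm_grid = seq(0.5, 4, by = 0.5),
    hinge_knots = 10,
    collinearity_threshold = 0.8,
    recreation_bandwidth = 250,
    connectivity = 8,
    k_nearest = 4,
    cwd_cutoff = 10000,
    pinch_min_area_ha = 5,
    element_bandwidth = 500,
    output_dir = NULL
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys override [default_run_config()].
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, yaml::read_yaml(path))
}

#' Run the full seasonal, guild-specific network pipeline
#'
#' Executes occurrence preparation, per-species-season habitat modelling,
#' guild source extraction, resistance construction, circuit connectivity,
#' network indices and priority mapping for every requested season. Failures
#' in one species-season or guild-season are logged and isolated; dependent
#' downstream products are skipped.
#'
#' @param stack covariate stack (e.g. [generate_covariate_stack()] or
#'   [read_stack()]).
#' @param occurrences occurrence data.frame (`species`, `guild`, `x`, `y`,
#'   `date`).
#' @param trajectories trajectory data.frame (`track_id`, `x`, `y`,
#'   `timestamp` and/or `season`).
#' @param config a [default_run_config()].
#' @return list with `sdm` (per species-season fits), `guild_networks` (per
#'   guild-season sources/corridors/currents/indices), `season_summaries`
#'   (pooled indices per season), `priority` (per season), `exclusions`,
#'   `log` (character vector of stage messages), and `manifest` (when
#'   `config$output_dir` is set).
#' @export
run_pipeline <- function(stack, occurrences, trajectories,
                         config = default_run_config()) {
  t0 <- Sys.time()
  ref <- stack[[1]]
  categorical <- attr(stack, "categorical")
  if (is.null(categorical)) categorical <- intersect(c("LAND", "SOIL"),
                                                     names(stack))
  logline <- character(0)
  note <- function(fmt, ...) {
    logline <<- c(logline, sprintf(fmt, ...))
  }

  ds <- build_seasonal_datasets(
    occurrences, ref, thin_radius = config$thin_radius,
    min_n = config$min_records, n_background = config$n_background,
    bandwidth = config$bias_bandwidth_cells * ref$cellsize,
    seed = config$seed)
  for (i in seq_len(nrow(ds$exclusions))) {
    note("excluded %s/%s: %d records after thinning",
         ds$exclusions$species[i], ds$exclusions$season[i],
         ds$exclusions$n_records[i])
  }

  sdm <- list()
  screened <- list()
  for (s in intersect(SEASONS, config$seasons)) {
    season_ds <- ds$datasets[vapply(ds$datasets, function(d) d$season == s,
                                    logical(1))]
    if (!length(season_ds)) next
    # season-level collinearity screening on pooled presences
    bg_cells <- season_ds[[1]]$background$cell
    bg_cov <- seasonal_covariate_frame(stack, s, bg_cells)
    pooled_xy <- do.call(rbind, lapply(season_ds, function(d) d$presences))
    pooled_cov <- seasonal_covariate_frame(
      stack, s, rg_cell_at(ref, pooled_xy$x, pooled_xy$y))
    imp <- tryCatch(
      suppressWarnings(jackknife_importance(
        pooled_cov, bg_cov, feature_set = "LQ", rm = 1,
        categorical = categorical, hinge_knots = config$hinge_knots)),
      error = function(e) NULL)
    impv <- if (is.null(imp)) {
      setNames(rep(1, ncol(bg_cov)), names(bg_cov))
    } else setNames(imp$importance, imp$variable)
    scr <- screen_collinearity(bg_cov, impv, config$collinearity_threshold)
    screened[[s]] <- scr
    for (r in seq_len(nrow(scr$removed))) {
      note("season %s: removed collinear covariate %s (vs %s, r=%.2f)",
           s, scr$removed$variable[r], scr$removed$partner[r],
           scr$removed$r[r])
    }
    vars <- scr$retained
    for (nm in names(season_ds)) {
      d <- season_ds[[nm]]
      res <- tryCatch({
        pres_cov <- seasonal_covariate_frame(
          stack, s, rg_cell_at(ref, d$presences$x, d$presences$y))[vars]
        bgc <- bg_cov[vars]
        tn <- tune_maxent(pres_cov, bgc, as.matrix(d$presences),
                          feature_sets = config$feature_sets,
                          rm_grid = config$rm_grid,
                          categorical = intersect(categorical, vars),
                          hinge_knots = config$hinge_knots)
        cv <- cross_validate(pres_cov, bgc,
                             stack = stack[c(vars[vars %in% names(stack)],
                                             grep("_(spring|summer|autumn|winter)$",
                                                  names(stack), value = TRUE))],
                             season = s,
                             feature_set = tn$selected$feature_set,
                             rm = tn$selected$rm,
                             categorical = intersect(categorical, vars),
                             hinge_knots = config$hinge_knots,
                             seed = config$seed)
        thr <- maxtss_threshold(predict(tn$model, pres_cov),
                                predict(tn$model, bgc))
        binary <- binarize(cv$suitability, thr)
        ev <- evaluate_model(tn$model, pres_cov, bgc, thr)
        list(species = d$species, guild = d$guild, season = s,
             selected = tn$selected, tune_table = tn$table,
             suitability = cv$suitability, threshold = thr, binary = binary,
             auc = ev$auc, omission = ev$omission, scheme = cv$scheme)
      }, error = function(e) {
        note("sdm failed for %s: %s", nm, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) sdm[[nm]] <- res
    }
  }

  guild_networks <- list()
  for (s in intersect(SEASONS, config$seasons)) {
    for (g in intersect(GUILDS, config$guilds)) {
      members <- sdm[vapply(sdm, function(m)
        m$season == s && m$guild == g, logical(1))]
      if (!length(members)) next
      key <- paste(g, s, sep = ".")
      gn <- tryCatch({
        suit <- Reduce(`+`, lapply(members, function(m) m$suitability$values)) /
          length(members)
        suit_rg <- rg_with_values(ref, suit)
        src <- guild_source_layer(lapply(members, `[[`, "binary"), g,
                                  suitability = suit_rg,
                                  connectivity = config$connectivity)
        res <- build_resistance(stack, trajectories, g, s,
                                kde_bandwidth = config$recreation_bandwidth)
        out <- list(guild = g, season = s, sources = src, resistance = res,
                    suitability = suit_rg)
        if (nrow(src$patches) >= 2) {
          corr <- least_cost_corridors(res$surface, src$cells,
                                       k_nearest = config$k_nearest,
                                       connectivity = config$connectivity)
          patch_nodes <- lapply(src$cells,
                                function(cc) corr$lattice$node_of[cc])
          cur <- cumulative_current(corr$lattice, patch_nodes,
                                    mode = "all_to_one")
          pp <- pinch_points(cur$current, corr,
                             cwd_cutoff = config$cwd_cutoff,
                             min_area_ha = config$pinch_min_area_ha)
          cfc <- current_flow_centrality(
            nrow(src$patches),
            data.frame(a = corr$corridors$patch_a,
                       b = corr$corridors$patch_b,
                       resistance = corr$corridors$cwd))
          corr$corridors$centrality <- cfc$edge
          corr$corridors$centrality_class <-
            suppressWarnings(classify_centrality(cfc$edge))
          net <- summarize_network(src$patches, corr$corridors)
          out <- c(out, list(corridors = corr, current = cur$current,
                             pinch = pp, node_centrality = cfc$node,
                             network = net))
        } else {
          note("guild %s season %s: %d patch(es); no corridor network",
               g, s, nrow(src$patches))
        }
        out
      }, error = function(e) {
        note("network failed for %s/%s: %s", g, s, conditionMessage(e))
        NULL
      })
      if (!is.null(gn)) guild_networks[[key]] <- gn
    }
  }

  season_summaries <- list()
  priority <- list()
  for (s in intersect(SEASONS, config$seasons)) {
    gns <- guild_networks[vapply(guild_networks, function(x) x$season == s,
                                 logical(1))]
    if (!length(gns)) next
    V <- sum(vapply(gns, function(x) nrow(x$sources$patches), numeric(1)))
    E <- sum(vapply(gns, function(x)
      if (!is.null(x$network)) x$network$graph$E else 0, numeric(1)))
    season_summaries[[s]] <- suppressWarnings(compute_indices(V, E = E))

    pr <- tryCatch({
      lines_by_guild <- lapply(gns, function(x) {
        if (is.null(x$corridors)) return(list())
        lapply(x$corridors$paths, function(cc) rg_xy(ref, cc))
      })
      names(lines_by_guild) <- vapply(gns, `[[`, "", "guild")
      nodes <- corridor_nodes(lines_by_guild, ref$cellsize)
      ov <- source_overlaps(lapply(gns, function(x) x$sources$union))
      bw <- config$element_bandwidth
      src_cells <- unlist(lapply(gns, function(x) x$sources$cells),
                          recursive = FALSE)
      src_w <- unlist(lapply(gns, function(x) x$sources$patches$mean_suitability))
      src_w[!is.finite(src_w)] <- 1
      corr_cells <- list(); corr_w <- numeric(0)
      pinch_cells <- list(); pinch_w <- numeric(0)
      for (x in gns) {
        if (!is.null(x$corridors)) {
          for (pi in seq_along(x$corridors$paths)) {
            cc <- x$corridors$paths[[pi]]
            corr_cells[[length(corr_cells) + 1L]] <- cc
            corr_w <- c(corr_w, mean(x$current$values[cc], na.rm = TRUE))
          }
        }
        if (!is.null(x$pinch) && length(x$pinch$cells)) {
          pinch_cells <- c(pinch_cells, x$pinch$cells)
          pinch_w <- c(pinch_w, x$pinch$pinch_points$area_ha)
        }
      }
      node_cells <- if (nrow(nodes$nodes)) {
        as.list(rg_cell_at(ref, nodes$nodes$x, nodes$nodes$y))
      } else list()
      layers <- list(
        sources = standardize_layer(
          element_density(ref, src_cells, src_w, bw)),
        corridors = standardize_layer(
          element_density(ref, corr_cells, corr_w, bw)),
        pinch_points = standardize_layer(
          element_density(ref, pinch_cells, pinch_w, bw)),
        nodes = standardize_layer(
          element_density(ref, node_cells, NULL, bw)),
        overlaps = standardize_layer(
          element_density(ref, ov$cells,
                          if (nrow(ov$overlaps)) ov$overlaps$richness, bw))
      )
      comp <- composite_priority(layers)
      list(season = s, nodes = nodes, overlaps = ov, layers = layers,
           composite = comp$composite, classes = comp$classes,
           high_priority_fraction = comp$high_priority_fraction,
           summary = data.frame(
             season = s,
             n_pinch = sum(vapply(gns, function(x)
               if (is.null(x$pinch)) 0L else nrow(x$pinch$pinch_points),
               integer(1))),
             n_nodes = nrow(nodes$nodes),
             overlap_area_km2 = sum(ov$overlaps$area_km2),
             high_priority_pct = 100 * comp$high_priority_fraction))
    }, error = function(e) {
      note("priority mapping failed for %s: %s", s, conditionMessage(e))
      NULL
    })
    if (!is.null(pr)) priority[[s]] <- pr
  }

  result <- list(sdm = sdm, screened = screened,
                 guild_networks = guild_networks,
                 season_summaries = season_summaries, priority = priority,
                 exclusions = ds$exclusions, log = logline)
  if (!is.null(config$output_dir)) {
    result$manifest <- write_outputs(result, config, t0)
  }
  result
}

# Write all tabular/spatial outputs and build the checksum manifest.
write_outputs <- function(result, config, t0) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "output_dir")], cfg_path)

  evals <- do.call(rbind, lapply(result$sdm, function(m) {
    tb <- m$tune_table
    tb$species <- m$species; tb$season <- m$season
    tb
  }))
  if (!is.null(evals)) {
    utils::write.csv(evals, file.path(dir, "sdm_evaluation.csv"),
                     row.names = FALSE)
  }
  net_rows <- list(); weight_rows <- list()
  for (key in names(result$guild_networks)) {
    x <- result$guild_networks[[key]]
    write_asc(x$resistance$surface,
              file.path(dir, sprintf("resistance_%s.asc", key)))
    wr <- x$resistance$weights
    wr$guild <- x$guild; wr$season <- x$season
    weight_rows[[key]] <- wr
    utils::write.csv(x$sources$patches,
                     file.path(dir, sprintf("sources_%s.csv", key)),
                     row.names = FALSE)
    if (!is.null(x$network)) {
      write_asc(x$current, file.path(dir, sprintf("current_%s.asc", key)))
      utils::write.csv(x$corridors$corridors,
                       file.path(dir, sprintf("corridors_%s.csv", key)),
                       row.names = FALSE)
      if (!is.null(x$pinch)) {
        utils::write.csv(x$pinch$pinch_points,
                         file.path(dir, sprintf("pinch_%s.csv", key)),
                         row.names = FALSE)
      }
      idx <- x$network$indices
      net_rows[[key]] <- data.frame(
        guild = x$guild, season = x$season, V = idx$V, E = idx$E,
        alpha = idx$alpha, beta = idx$beta, gamma = idx$gamma,
        alpha3 = idx$alpha3, beta3 = idx$beta3, gamma3 = idx$gamma3)
    }
  }
  for (s in names(result$season_summaries)) {
    idx <- result$season_summaries[[s]]
    net_rows[[paste0("season.", s)]] <- data.frame(
      guild = "all", season = s, V = idx$V, E = idx$E,
      alpha = idx$alpha, beta = idx$beta, gamma = idx$gamma,
      alpha3 = idx$alpha3, beta3 = idx$beta3, gamma3 = idx$gamma3)
  }
  if (length(net_rows)) {
    utils::write.csv(do.call(rbind, net_rows),
                     file.path(dir, "network_indices.csv"), row.names = FALSE)
  }
  if (length(weight_rows)) {
    utils::write.csv(do.call(rbind, weight_rows),
                     file.path(dir, "resistance_weights.csv"),
                     row.names = FALSE)
  }
  pr_rows <- list()
  for (s in names(result$priority)) {
    p <- result$priority[[s]]
    write_asc(p$composite, file.path(dir, sprintf("priority_composite_%s.asc", s)))
    write_asc(p$classes, file.path(dir, sprintf("priority_classes_%s.asc", s)))
    utils::write.csv(p$overlaps$overlaps,
                     file.path(dir, sprintf("overlaps_%s.csv", s)),
                     row.names = FALSE)
    utils::write.csv(p$nodes$nodes,
                     file.path(dir, sprintf("nodes_%s.csv", s)),
                     row.names = FALSE)
    pr_rows[[s]] <- p$summary
  }
  if (length(pr_rows)) {
    utils::write.csv(do.call(rbind, pr_rows),
                     file.path(dir, "priority_summary.csv"), row.names = FALSE)
  }
  writeLines(result$log, file.path(dir, "run_log.txt"))

  files <- sort(list.files(dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  manifest <- data.frame(file = basename(files), md5 = unname(sums))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs"))
  manifest
}
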