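#' Assemble a pipeline configuration
#'
#' A single self-describing configuration drives the end-to-end run:
#' scene source (a synthetic decade, or a directory of `.asc` scenes
#' with a manifest), index settings, period scheme, trend, statistics
#' and attribution settings, output directory and the mandatory seed.
#' All defaults are echoed into the run manifest so a run is
#' reproducible from its outputs alone.
#'
#' @param out_dir output directory (created; stages write under
#'   `<out_dir>/<stage>/`).
#' @param seed integer seed used by every stochastic stage.
#' @param simulate list of [sim_config()] arguments (excluding `seed`),
#'   or `NULL` to read scenes from `input_dir`.
#' @param input_dir directory holding `red_YYYY_MM.asc`,
#'   `nir_YYYY_MM.asc`, `qa_YYYY_MM.asc` and optionally `zones.asc`,
#'   `climate.csv`.
#' @param L soil adjustment factor for SAVI.
#' @param clamp_reflectance apply the \[-0.2, 1.6\] plausibility clamp.
#' @param confidence_threshold QA cloud-confidence cut (see
#'   [qa_rule()]).
#' @param periods list of biannual periods (default 2011-2020 five
#'   periods).
#' @param trend_aggregation `"yearly"` or `"monthly"`.
#' @param alpha significance level for trend classes and tests.
#' @param n_perm DistLM permutations.
#' @param run_climate run the climate-attribution stage (skipped and
#'   recorded as skipped when no climate table exists).
#' @return an object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(out_dir, seed, simulate = list(),
                            input_dir = NULL, L = 0.5,
                            clamp_reflectance = TRUE,
                            confidence_threshold = 3,
                            periods = NULL,
                            trend_aggregation = "yearly", alpha = 0.05,
                            n_perm = 199L, run_climate = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input_dir = input_dir, L = L,
                 clamp_reflectance = clamp_reflectance,
                 confidence_threshold = confidence_threshold,
                 periods = periods, trend_aggregation = trend_aggregation,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 run_climate = run_climate),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

scene_path <- function(dir, band, year, month)
  file.path(dir, sprintf("%s_%04d_%02d.asc", band, year, month))

#' Write a synthetic decade of scenes to disk
#'
#' Simulates the SAVI field, inverts each monthly grid to a
#' (nir, red, qa) reflectance triplet stored as Collection-2-style
#' digital numbers, and writes them as `.asc` scenes plus a `zones.asc`
#' map, a TerraClimate-convention `climate.csv` and a
#' `manifest.csv` (year, month, band, path). Ground truth goes to
#' `truth.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param climate data.frame from [simulate_climate()], or `NULL` to
#'   simulate one from the same seed.
#' @return invisible list with the manifest data.frame and the truth.
#' @export
write_synthetic_scenes <- function(config, dir, climate = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_index_stack(config)
  ts <- sim$stack$timestamps
  rows <- list()
  for (k in seq_len(nrow(ts))) {
    bands <- simulate_reflectance_pair(sim$stack$grids[[k]],
                                       seed = config$seed + k, as_dn = TRUE)
    for (b in c("nir", "red", "qa")) {
      p <- scene_path(dir, b, ts$year[k], ts$month[k])
      write_grid(bands[[b]], p, nodata = -9999)
      rows[[length(rows) + 1L]] <- data.frame(year = ts$year[k],
                                              month = ts$month[k],
                                              band = b, path = basename(p))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  zones <- grid_new(matrix(as.numeric(config$zones), config$rows, config$cols),
                    meta = sim$stack$grids[[1]]$meta)
  write_grid(zones, file.path(dir, "zones.asc"), nodata = 0)
  if (is.null(climate)) climate <- simulate_climate(config$years,
                                                    seed = config$seed)
  write_climate(climate, file.path(dir, "climate.csv"))
  truth <- sim$truth
  truth$latent <- NULL
  truth$slope <- NULL; truth$trend_class <- NULL  # matrices: keep JSON small
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, truth = sim$truth, zones = config$zones,
                 zone_names = config$zone_names))
}

#' Read the per-band scene stacks of a scene directory
#'
#' Consumes the directory's `manifest.csv` (columns year, month, band,
#' path) and assembles one aligned, time-ordered stack per band.
#'
#' @param dir directory holding the manifest and `.asc` scenes.
#' @return named list of `scene_stack`s (typically `red`, `nir`, `qa`).
#' @export
read_scene_stacks <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  stacks <- lapply(split(man, man$band), function(df) {
    df <- df[order(df$year, df$month), ]
    assemble_stack(grids = lapply(file.path(dir, df$path), read_grid),
                   years = df$year, months = df$month,
                   band_label = df$band[1])
  })
  stacks
}

#' Compute masked SAVI and NDVI stacks from raw band stacks
#'
#' The preprocess + index chain for every scene: decode the QA bitmask
#' into a validity grid, scale digital numbers to reflectance, intersect
#' masks, and compute both indices.
#'
#' @param stacks named list with `red`, `nir`, `qa` stacks (from
#'   [read_scene_stacks()]).
#' @param L soil adjustment factor for SAVI.
#' @param clamp apply the reflectance plausibility clamp.
#' @param confidence_threshold QA cloud-confidence cut.
#' @return list with `savi` and `ndvi` `scene_stack`s.
#' @export
build_index_stacks <- function(stacks, L = 0.5, clamp = TRUE,
                               confidence_threshold = 3) {
  for (b in c("red", "nir", "qa"))
    if (is.null(stacks[[b]])) stop(sprintf("missing %s band stack", b))
  rule <- qa_rule(confidence_threshold = confidence_threshold)
  rspec <- reflectance_scaling(clamp = clamp)
  ts <- stacks$nir$timestamps
  savi_grids <- ndvi_grids <- vector("list", nrow(ts))
  for (k in seq_len(nrow(ts))) {
    ok <- decode_qa_mask(stacks$qa$grids[[k]], rule)
    nir_k <- mask_scene(apply_scaling(stacks$nir$grids[[k]], rspec), ok)
    red_k <- mask_scene(apply_scaling(stacks$red$grids[[k]], rspec), ok)
    savi_grids[[k]] <- savi(nir_k, red_k, L = L)
    ndvi_grids[[k]] <- ndvi(nir_k, red_k)
  }
  list(savi = assemble_stack(grids = savi_grids, years = ts$year,
                             months = ts$month, band_label = "index"),
       ndvi = assemble_stack(grids = ndvi_grids, years = ts$year,
                             months = ts$month, band_label = "index"))
}

#' Run the full vegetation-dynamics pipeline
#'
#' Executes preprocess (QA decode + scaling + masking), index
#' computation (SAVI and NDVI), biannual median compositing, density
#' classification with cover and change tables, per-pixel Mann-Kendall
#' trend mapping, zone/season rank statistics, and (when a climate
#' table is available) DistLM/dbRDA climate attribution. Every stage
#' writes its products under `<out_dir>/<stage>/`; a JSON run manifest
#' records the configuration, per-stage record counts and the md5 of
#' every output file, so a rerun with identical inputs reproduces
#' identical hashes.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return the run manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()

  # --- scenes ---------------------------------------------------------
  if (!is.null(config$input_dir)) {
    scene_dir <- config$input_dir
  } else {
    scene_dir <- file.path(out, "scenes")
    sim_cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    write_synthetic_scenes(sim_cfg, scene_dir)
  }
  stacks <- read_scene_stacks(scene_dir)
  for (b in c("red", "nir", "qa"))
    if (is.null(stacks[[b]])) stop(sprintf("stage scenes: missing %s band", b))
  stage_counts$scenes <- stack_length(stacks$nir)

  zones_path <- file.path(scene_dir, "zones.asc")
  zone_grid <- if (file.exists(zones_path)) read_grid(zones_path) else NULL

  # --- preprocess + indices ------------------------------------------
  idx <- build_index_stacks(stacks, L = config$L,
                            clamp = config$clamp_reflectance,
                            confidence_threshold = config$confidence_threshold)
  savi_stack <- idx$savi
  ndvi_stack <- idx$ndvi
  stage_counts$index <- stack_length(savi_stack)

  # --- composite ------------------------------------------------------
  comp_dir <- file.path(out, "composite")
  dir.create(comp_dir, showWarnings = FALSE)
  scheme <- if (is.null(config$periods)) period_scheme()
            else period_scheme(config$periods)
  layers <- biannual_layers(savi_stack, scheme)
  for (nm in names(layers))
    write_grid(layers[[nm]], file.path(comp_dir, sprintf("savi_%s.asc", nm)))
  zone_masks <- zone_mask_list(zone_grid, savi_stack)
  series <- do.call(rbind, lapply(names(zone_masks), function(z) {
    s <- seasonal_series(savi_stack, zone_masks[[z]])
    s$zone <- z
    s
  }))
  utils::write.csv(series, file.path(comp_dir, "seasonal_series.csv"),
                   row.names = FALSE)
  stage_counts$composite <- length(layers)

  # --- classify -------------------------------------------------------
  cls_dir <- file.path(out, "classify")
  dir.create(cls_dir, showWarnings = FALSE)
  cat_scheme <- category_scheme()
  catmaps <- lapply(names(layers), function(nm) {
    cm <- classify_savi(layers[[nm]], cat_scheme)
    write_grid(cm, file.path(cls_dir, sprintf("category_%s.asc", nm)),
               nodata = 0)
    cm
  })
  names(catmaps) <- names(layers)
  covers <- do.call(rbind, lapply(names(catmaps), function(nm)
    cover_percentages(catmaps[[nm]], cat_scheme, period = nm)))
  utils::write.csv(covers, file.path(cls_dir, "cover_tables.csv"),
                   row.names = FALSE)
  if (length(catmaps) >= 2) {
    changes <- do.call(rbind, lapply(seq_len(length(catmaps) - 1), function(i)
      cover_difference(cover_percentages(catmaps[[i + 1]], cat_scheme,
                                         period = names(catmaps)[i + 1]),
                       cover_percentages(catmaps[[i]], cat_scheme,
                                         period = names(catmaps)[i]))))
    utils::write.csv(changes, file.path(cls_dir, "change_tables.csv"),
                     row.names = FALSE)
  }
  stage_counts$classify <- length(catmaps)

  # --- trend ----------------------------------------------------------
  trend_dir <- file.path(out, "trend")
  dir.create(trend_dir, showWarnings = FALSE)
  tm <- trend_map(savi_stack, aggregation = config$trend_aggregation,
                  alpha = config$alpha)
  write_grid(tm$tau, file.path(trend_dir, "tau.asc"))
  write_grid(tm$p, file.path(trend_dir, "pvalue.asc"))
  write_grid(tm$class, file.path(trend_dir, "trend_class.asc"), nodata = 127)
  utils::write.csv(trend_summary(tm), file.path(trend_dir, "summary.csv"),
                   row.names = FALSE)
  stage_counts$trend <- sum(tm$class$valid_mask)

  # --- group stats ----------------------------------------------------
  stats_dir <- file.path(out, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  reports <- pipeline_group_stats(series, savi_stack, ndvi_stack, zone_masks)
  utils::write.csv(reports, file.path(stats_dir, "tests.csv"),
                   row.names = FALSE)
  stage_counts$stats <- nrow(reports)

  # --- climate attribution -------------------------------------------
  climate_path <- file.path(scene_dir, "climate.csv")
  if (config$run_climate && file.exists(climate_path)) {
    att_dir <- file.path(out, "attrib")
    dir.create(att_dir, showWarnings = FALSE)
    climate <- read_climate(climate_path)
    att <- lapply(names(zone_masks), function(z) {
      tab <- attribution_table(series[series$zone == z, ], climate)
      covs <- tab[, c("tmx_c", "tmn_c", "prep_mm")]
      dl <- distlm(as.matrix(tab$savi_mean), covs, n_perm = config$n_perm,
                   seed = config$seed)
      db <- dbrda(as.matrix(tab$savi_mean), covs)
      marg <- dl$marginal; marg$zone <- z
      utils::write.csv(cbind(tab[, c("year", "month", "season")],
                             as.data.frame(db$scores)),
                       file.path(att_dir, sprintf("dbrda_scores_%s.csv", z)),
                       row.names = FALSE)
      list(marginal = marg, selection = dl$selection,
           dbrda = list(zone = z, pct_fitted = db$pct_fitted,
                        pct_total = db$pct_total, n_axes = db$n_axes))
    })
    names(att) <- names(zone_masks)
    utils::write.csv(do.call(rbind, lapply(att, `[[`, "marginal")),
                     file.path(att_dir, "distlm_marginal.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(att, function(a)
      list(selection = a$selection, dbrda = a$dbrda)),
      file.path(att_dir, "attribution.json"), auto_unbox = TRUE, digits = NA)
    climate_status <- "run"
  } else climate_status <- "skipped"

  # --- manifest -------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- substring(names(hashes), nchar(out) + 2)
  manifest <- list(
    config = unclass(config),
    stages = stage_counts,
    n_biannual_layers = length(layers),
    climate_attribution = climate_status,
    files = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Logical zone masks from a zone-id grid
#'
#' Splits a grid of integer zone ids into one logical mask per zone,
#' named `NZ`/`SZ` for the two-zone case. With no zone grid a single
#' all-`TRUE` mask named `all` is returned.
#'
#' @param zone_grid a `dune_grid` of zone ids, or `NULL`.
#' @param stack a `scene_stack` the masks must align with.
#' @return named list of logical matrices.
#' @export
zone_mask_list <- function(zone_grid, stack) {
  m <- stack$grids[[1]]$meta
  if (is.null(zone_grid)) return(list(all = matrix(TRUE, m$rows, m$cols)))
  stop_if_misaligned(stack$grids[[1]], zone_grid, "stack and zone map")
  ids <- sort(unique(zone_grid$values[zone_grid$valid_mask]))
  nm <- if (length(ids) == 2) c("NZ", "SZ") else sprintf("zone%d", ids)
  out <- lapply(seq_along(ids), function(i)
    zone_grid$valid_mask & zone_grid$values == ids[i])
  names(out) <- nm
  out
}

pipeline_group_stats <- function(series, savi_stack, ndvi_stack, zone_masks) {
  rows <- list()
  add <- function(scope, rep) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, test = rep$test, statistic = rep$statistic, p = rep$p,
      p_adjusted = rep$p_adjusted,
      groups = if (is.null(rep$groups)) NA_character_
               else paste(rep$groups, collapse = " vs "))
  }
  for (z in names(zone_masks)) {
    s_full <- series[series$zone == z, ]
    s_z <- s_full[!is.na(s_full$mean), ]
    add(sprintf("normality savi %s", z), ks_normality(s_z$mean))
    by_season <- split(s_z$mean, s_z$season)
    if (length(by_season) >= 2) {
      add(sprintf("seasons %s", z), kruskal_wallis(by_season, exact = FALSE))
      for (rep in bonferroni_pairwise(by_season, exact = FALSE))
        add(sprintf("seasons %s post hoc", z), rep)
    }
    nd <- seasonal_series(ndvi_stack, zone_masks[[z]])
    ok <- !is.na(s_full$mean) & !is.na(nd$mean)
    add(sprintf("savi vs ndvi %s", z), spearman(s_full$mean[ok], nd$mean[ok]))
  }
  if (length(zone_masks) >= 2) {
    z1 <- series[series$zone == names(zone_masks)[1] & !is.na(series$mean), "mean"]
    z2 <- series[series$zone == names(zone_masks)[2] & !is.na(series$mean), "mean"]
    rep <- mann_whitney_u(z1, z2, exact = FALSE)
    rep$groups <- names(zone_masks)[1:2]
    add("zones", rep)
  }
  do.call(rbind, rows)
}
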