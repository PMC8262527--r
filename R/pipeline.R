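#' Demo run configuration
#'
#' A complete workable configuration: a Portugal-like observational grid
#' (10 x 10, emulating the finer observational product), a coarser 8 x 8
#' scenario grid that everything is regridded to, two mock model pairs with
#' a known warm bias, two scenarios with moderate / strong warming
#' (0.02 and 0.045 degC/yr, RCP4.5- and RCP8.5-like), baseline years
#' 1989-2005 and a future horizon of 2080, and eight synthetic fruit
#' regions.
#'
#' @param outdir output directory.
#' @param seed integer seed controlling all randomness.
#' @return list of class `run_config`.
#' @export
demo_config <- function(outdir = tempfile("chillforce_run_"), seed = 1L) {
  scen_grid <- grid_spec(lat = seq(36.5, 42.5, length.out = 8),
                         lon = seq(-9.5, -6.0, length.out = 8))
  obs_grid <- grid_spec(lat = seq(36.5, 42.5, length.out = 10),
                        lon = seq(-9.5, -6.0, length.out = 10))
  run_config(
    weather = weather_gen_config(grid = obs_grid, year_start = 1989,
                                 year_end = 2005, bias_offset = 1.5,
                                 bias_scale = 1.02, seed = seed),
    scenario_grid = scen_grid,
    n_models = 2,
    scenarios = c(rcp45 = 0.02, rcp85 = 0.045),
    future_end = 2080,
    regions = demo_regions(),
    outdir = outdir,
    seed = seed)
}

#' Assemble a run configuration
#'
#' @param weather a [weather_gen_config()] describing the observational
#'   baseline (its grid is the observational grid; scenario series are
#'   generated directly on `scenario_grid`).
#' @param scenario_grid [grid_spec()] of the scenario product; observations
#'   are bilinearly regridded onto it before quantile-map fitting.
#' @param n_models number of mock model pairs.
#' @param scenarios named numeric vector of warming trends (degC/yr).
#' @param future_end last future year.
#' @param regions named list of [region_mask()] objects, or a GeoJSON path.
#' @param n_quantiles quantile-map levels, default 99.
#' @param level safe-index percentile level, default 0.1.
#' @param outdir output directory.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(weather, scenario_grid, n_models = 2,
                       scenarios = c(rcp45 = 0.02, rcp85 = 0.045),
                       future_end = 2080, regions = demo_regions(),
                       n_quantiles = 99, level = 0.1,
                       outdir = tempfile("chillforce_run_"), seed = 1L) {
  if (is.character(regions)) regions <- read_regions_geojson(regions)
  cfg <- list(weather = weather, scenario_grid = scenario_grid,
              n_models = n_models, scenarios = scenarios,
              future_end = future_end, regions = regions,
              n_quantiles = n_quantiles, level = level,
              outdir = outdir, seed = as.integer(seed))
  stopifnot(inherits(cfg$weather, "weather_gen_config"),
            inherits(cfg$scenario_grid, "grid_spec"))
  bad <- which(sapply(cfg$regions, function(r) !inherits(r, "region_mask")))
  if (length(bad)) stop("regions must be region_mask objects")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; grids are
#' given as `{lat: [from, to, n], lon: [from, to, n]}`, the weather block
#' passes its remaining fields to [weather_gen_config()], `scenarios` is a
#' mapping from label to warming trend, and `regions` is a GeoJSON path.
#'
#' @param path YAML file.
#' @param outdir,seed optional overrides.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  to_grid <- function(g) grid_spec(lat = seq(g$lat[[1]], g$lat[[2]], length.out = g$lat[[3]]),
                                   lon = seq(g$lon[[1]], g$lon[[2]], length.out = g$lon[[3]]))
  w <- y$weather
  wg <- to_grid(w$grid); w$grid <- NULL
  if (!is.null(seed)) w$seed <- seed
  weather <- do.call(weather_gen_config, c(list(grid = wg), w))
  regions <- if (is.null(y$regions)) demo_regions() else {
    p <- y$regions
    if (!file.exists(p)) p <- file.path(dirname(path), y$regions)
    read_regions_geojson(p)
  }
  run_config(weather = weather,
             scenario_grid = to_grid(y$scenario_grid),
             n_models = y$n_models %||% 2,
             scenarios = unlist(y$scenarios),
             future_end = y$future_end %||% 2080,
             regions = regions,
             n_quantiles = y$n_quantiles %||% 99,
             level = y$level %||% 0.1,
             outdir = outdir %||% y$outdir %||% tempfile("chillforce_run_"),
             seed = seed %||% y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eight synthetic demo fruit regions
#'
#' Small rectangular polygon masks tiling the default Portugal-like grid,
#' with fruit labels in the proportions typical of temperate fruit-region
#' studies (several apple regions, plus pear, plum and orange). These are
#' synthetic stand-ins, not legal denomination boundaries.
#'
#' @return named list of [region_mask()] objects.
#' @export
demo_regions <- function() {
  rect <- function(lon0, lon1, lat0, lat1)
    cbind(lon = c(lon0, lon1, lon1, lon0), lat = c(lat0, lat0, lat1, lat1))
  defs <- list(
    list("plum-south",     rect(-8.2, -7.3, 38.0, 39.3), "plum"),
    list("apple-west",     rect(-9.2, -8.4, 39.5, 40.1), "apple"),
    list("apple-north",    rect(-7.8, -6.9, 41.2, 42.0), "apple"),
    list("apple-east",     rect(-7.2, -6.3, 39.6, 40.3), "apple"),
    list("apple-inland",   rect(-7.7, -6.8, 38.9, 39.3), "apple"),
    list("apple-estuary",  rect(-9.2, -8.4, 38.0, 38.5), "apple"),
    list("pear-west",      rect(-9.7, -9.3, 38.9, 40.1), "pear"),
    list("orange-south",   rect(-8.2, -6.8, 36.2, 37.0), "orange"))
  masks <- lapply(defs, function(d) region_mask(d[[1]], polygon = d[[2]],
                                                fruit = d[[3]]))
  names(masks) <- vapply(masks, `[[`, "", "id")
  masks
}

# one hourly interpolation per cell, both CP and GDH totals
totals_both <- function(daily, cp_params = dynamic_model_params(),
                        gdhp = gdh_params()) {
  chill <- seasonal_totals_fast(daily, "chill", cp_params, gdhp)
  force <- seasonal_totals_fast(daily, "forcing", cp_params, gdhp, chill$hourly)
  out <- rbind(chill$totals, force$totals)
  rownames(out) <- NULL
  class(out) <- c("seasonal_totals", "data.frame")
  out
}

# like seasonal_totals() but reusing cached per-cell hourly vectors
seasonal_totals_fast <- function(daily, kind, cp_params, gdhp,
                                 hourly_cache = NULL) {
  if (any(daily$grid$lat < 0))
    stop("southern-hemisphere latitudes are not supported: ",
         "accumulation windows are northern-hemisphere")
  d0 <- min(daily$dates); d1 <- max(daily$dates)
  yr <- as.integer(format(daily$dates, "%Y"))
  win <- season_windows(seq(min(yr), max(yr)), kind)
  win <- win[win$start >= d0 & win$end <= d1, , drop = FALSE]
  row_start <- as.numeric(win$start - d0) * 24 + 1
  row_end <- (as.numeric(win$end - d0) + 1) * 24
  coords <- cell_coords(daily$grid)
  if (is.null(hourly_cache)) hourly_cache <- vector("list", nrow(coords))
  varname <- if (kind == "chill") "CP" else "GDH"
  res <- vector("list", nrow(coords))
  for (cell in seq_len(nrow(coords))) {
    if (is.null(hourly_cache[[cell]]))
      hourly_cache[[cell]] <- interpolate_hourly(daily, cell)$temp
    temps <- hourly_cache[[cell]]
    vals <- numeric(nrow(win))
    for (i in seq_len(nrow(win))) {
      tw <- temps[row_start[i]:row_end[i]]
      vals[i] <- if (kind == "chill") chill_portions(tw, cp_params)$total
      else gdh_accumulate(tw, params = gdhp)$total
    }
    res[[cell]] <- data.frame(cell = cell, lat = coords$lat[cell],
                              lon = coords$lon[cell],
                              season_year = win$season_year,
                              variable = varname, value = vals)
  }
  list(totals = do.call(rbind, res), hourly = hourly_cache)
}

#' Run the full baseline-vs-scenario assessment pipeline
#'
#' Stages, in order: `generate` (synthetic observations and scenario
#' series), `correct` (regrid observations to the scenario grid, fit and
#' apply the quantile map per model pair), `accumulate` (hourly
#' interpolation and CP/GDH seasonal totals per cell), `indices` (safe
#' chill/forcing indices per period, scenario and member; ensemble
#' statistics; change maps), `report` (regional extraction, boxplot
#' statistics, linear trends; all CSV outputs and the JSON run manifest).
#' The run is a deterministic function of the configuration and seed;
#' rerunning into a fresh directory reproduces the CSV outputs
#' byte-for-byte.
#'
#' @param config a [run_config()] (e.g. [demo_config()]).
#' @param through last stage to execute: one of `"generate"`, `"correct"`,
#'   `"accumulate"`, `"indices"`, `"report"` or `"all"` (default).
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with all intermediate and final products:
#'   `obs`, `obs_regridded`, `sims`, `sims_corrected`, `totals`
#'   (tidy data.frame over all sources), `safe_indices`, `ensemble`,
#'   `changes`, `boxstats`, `annual_regional`, `trends`, `manifest`.
#' @export
run_pipeline <- function(config, through = "all", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("generate", "correct", "accumulate", "indices", "report")
  through <- match.arg(through, c(stages, "all"))
  last <- if (through == "all") length(stages) else match(through, stages)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  timings <- counters <- list()
  out <- list(config = config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage_clock <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("stage %s done in %.1f s", name, timings[[name]])
    v
  }

  # -- generate -------------------------------------------------------
  counters$n_cells_obs <- n_cells(config$weather$grid)
  counters$n_cells_scenario <- n_cells(config$scenario_grid)
  counters$n_members <- config$n_models * length(config$scenarios)
  gen <- stage_clock({
    obs <- generate_baseline(config$weather)
    scen_cfg <- config$weather
    scen_cfg$grid <- config$scenario_grid
    sims <- generate_scenario_set(scen_cfg, config$n_models,
                                  config$scenarios, config$future_end)
    list(obs = obs, sims = sims)
  }, "generate")
  out$obs <- gen$obs; out$sims <- gen$sims
  if (last < 2) return(write_outputs(out, timings, counters, quiet))

  # -- correct --------------------------------------------------------
  corr <- stage_clock({
    obs_rg <- suppressWarnings(regrid_bilinear(gen$obs, config$scenario_grid))
    corrected <- lapply(gen$sims, function(s) {
      qmap <- fit_eqm(obs_rg, s, config$n_quantiles)
      suppressMessages(apply_eqm(qmap, s))
    })
    list(obs_rg = obs_rg, corrected = corrected)
  }, "correct")
  out$obs_regridded <- corr$obs_rg
  out$sims_corrected <- corr$corrected
  if (last < 3) return(write_outputs(out, timings, counters, quiet))

  # -- accumulate -----------------------------------------------------
  out$totals <- stage_clock({
    tt <- suppressWarnings(totals_both(corr$obs_rg))
    tt$source <- "observed"; tt$model <- NA; tt$scenario <- "baseline"
    all_tt <- list(tt)
    for (nm in names(corr$corrected)) {
      s <- corr$corrected[[nm]]
      ti <- suppressWarnings(totals_both(s))
      ti$source <- "model"
      ti$model <- s$provenance$model
      ti$scenario <- s$provenance$scenario
      all_tt[[length(all_tt) + 1]] <- ti
    }
    do.call(rbind, all_tt)
  }, "accumulate")
  if (last < 4) return(write_outputs(out, timings, counters, quiet))

  # -- indices --------------------------------------------------------
  idx <- stage_clock({
    per <- subperiods()
    base_years <- c(config$weather$year_start, config$weather$year_end)
    grid <- config$scenario_grid
    tt <- out$totals
    si_rows <- list(); ens_rows <- list(); chg_rows <- list()
    add_si <- function(f, variable, scenario, model, period) {
      cbind(data.frame(scenario = scenario, model = model,
                       period = period, variable = variable), f)
    }
    baseline_fields <- list()
    for (v in c("CP", "GDH")) {
      b <- tt[tt$source == "observed" & tt$variable == v, ]
      f <- suppressWarnings(safe_index(b, base_years, config$level))
      baseline_fields[[v]] <- f
      si_rows[[length(si_rows) + 1]] <- add_si(f, v, "baseline", "observed",
                                               "baseline")
    }
    for (sc in names(config$scenarios)) {
      for (p in seq_len(nrow(per))) {
        prd <- c(per$start[p], per$end[p])
        for (v in c("CP", "GDH")) {
          members <- list()
          for (md in unique(tt$model[tt$source == "model"])) {
            mt <- tt[tt$source == "model" & tt$scenario == sc &
                       tt$model == md & tt$variable == v, ]
            f <- suppressWarnings(safe_index(mt, prd, config$level))
            members[[md]] <- f
            si_rows[[length(si_rows) + 1]] <-
              add_si(f, v, sc, md, per$label[p])
          }
          es <- ensemble_stats(members)
          ens_rows[[length(ens_rows) + 1]] <-
            cbind(data.frame(scenario = sc, period = per$label[p],
                             variable = v), es)
          ens_field <- data.frame(cell = es$cell, lat = es$lat,
                                  lon = es$lon, value = es$mean)
          cm <- change_map(ens_field, baseline_fields[[v]])
          chg_rows[[length(chg_rows) + 1]] <-
            cbind(data.frame(scenario = sc, period = per$label[p],
                             variable = v), cm)
        }
      }
    }
    list(safe_indices = do.call(rbind, si_rows),
         ensemble = do.call(rbind, ens_rows),
         changes = do.call(rbind, chg_rows))
  }, "indices")
  out$safe_indices <- idx$safe_indices
  out$ensemble <- idx$ensemble
  out$changes <- idx$changes
  if (last < 5) return(write_outputs(out, timings, counters, quiet))

  # -- report ---------------------------------------------------------
  rep <- stage_clock({
    grid <- config$scenario_grid
    tt <- out$totals
    per <- rbind(data.frame(label = "baseline",
                            start = config$weather$year_start,
                            end = config$weather$year_end),
                 subperiods())
    box_rows <- list(); ann_rows <- list()
    for (rn in names(config$regions)) {
      mask <- config$regions[[rn]]
      cells <- region_cells(mask, grid)
      for (v in c("CP", "GDH")) {
        for (p in seq_len(nrow(per))) {
          yrs <- seq(per$start[p], per$end[p])
          if (per$label[p] == "baseline") {
            vals <- tt$value[tt$source == "observed" & tt$variable == v &
                               tt$cell %in% cells & tt$season_year %in% yrs]
            box_rows[[length(box_rows) + 1]] <-
              cbind(data.frame(region = rn, fruit = mask$fruit,
                               variable = v, scenario = "baseline",
                               period = "baseline"),
                    regional_boxstats(vals))
          } else {
            for (sc in names(config$scenarios)) {
              vals <- tt$value[tt$source == "model" & tt$scenario == sc &
                                 tt$variable == v & tt$cell %in% cells &
                                 tt$season_year %in% yrs]
              box_rows[[length(box_rows) + 1]] <-
                cbind(data.frame(region = rn, fruit = mask$fruit,
                                 variable = v, scenario = sc,
                                 period = per$label[p]),
                      regional_boxstats(vals))
            }
          }
        }
        # annual regional ensemble-mean series over the future period
        for (sc in names(config$scenarios)) {
          sel <- tt$source == "model" & tt$scenario == sc &
            tt$variable == v & tt$cell %in% cells &
            tt$season_year >= 2021 & tt$season_year <= config$future_end
          agg <- stats::aggregate(value ~ season_year, data = tt[sel, ], mean)
          ann_rows[[length(ann_rows) + 1]] <-
            data.frame(region = rn, fruit = mask$fruit, variable = v,
                       scenario = sc, year = agg$season_year,
                       value = agg$value)
        }
      }
    }
    annual <- do.call(rbind, ann_rows)
    trends <- do.call(rbind, lapply(c("CP", "GDH"), function(v) {
      a <- annual[annual$variable == v, ]
      tr <- linear_trend(a[, c("region", "scenario", "year", "value")])
      cbind(data.frame(variable = v), tr)
    }))
    list(boxstats = do.call(rbind, box_rows), annual = annual,
         trends = trends)
  }, "report")
  out$boxstats <- rep$boxstats
  out$annual_regional <- rep$annual
  out$trends <- rep$trends
  timings$total <- round(proc.time()[["elapsed"]] - t_start, 2)
  write_outputs(out, timings, counters, quiet)
}

# serialize everything available; returns `out` invisibly with manifest
write_outputs <- function(out, timings, counters, quiet) {
  cfg <- out$config
  od <- cfg$outdir
  wr <- function(df, name) {
    if (!is.null(df))
      write.csv(format_for_csv(df), file.path(od, name), row.names = FALSE)
  }
  if (is.null(out$totals) && !is.null(out$obs)) {
    # weather-only run: gridded daily series go out as NetCDF when available
    if (requireNamespace("ncdf4", quietly = TRUE)) {
      write_weather_netcdf(out$obs, file.path(od, "observed.nc"))
      for (nm in names(out$sims))
        write_weather_netcdf(out$sims[[nm]], file.path(od, paste0(nm, ".nc")))
    } else if (!quiet) {
      message("ncdf4 not installed: gridded weather kept in memory only")
    }
  }
  wr(out$totals, "seasonal_totals.csv")
  wr(out$safe_indices, "safe_indices.csv")
  wr(out$ensemble, "ensemble_summary.csv")
  wr(out$changes, "change_maps.csv")
  wr(out$boxstats, "regional_boxstats.csv")
  wr(out$annual_regional, "regional_annual_series.csv")
  wr(out$trends, "trends.csv")

  cfg_json <- jsonlite::toJSON(config_fingerprint(cfg), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  manifest <- list(
    package = "chillforce",
    version = as.character(utils::packageVersion("chillforce")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tf)),
    config = config_fingerprint(cfg),
    timings_s = timings,
    counters = counters)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  if (!quiet) message(sprintf("outputs written to %s", od))
  invisible(out)
}

# values written with full precision but fixed formatting so that reruns
# are byte-identical
format_for_csv <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  }
  df
}

config_fingerprint <- function(cfg) {
  w <- cfg$weather
  list(weather = w[setdiff(names(w), "grid")],
       obs_grid = list(lat = w$grid$lat, lon = w$grid$lon),
       scenario_grid = list(lat = cfg$scenario_grid$lat,
                            lon = cfg$scenario_grid$lon),
       n_models = cfg$n_models, scenarios = as.list(cfg$scenarios),
       future_end = cfg$future_end,
       regions = names(cfg$regions),
       n_quantiles = cfg$n_quantiles, level = cfg$level, seed = cfg$seed)
}
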