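# fixtures built in code; no data files

`%||%` <- function(a, b) if (is.null(a)) b else a

one_cell_grid <- function(lat = 40, lon = -8) grid_spec(lat, lon)

# 3-day hand fixture used by the hourly-curve oracle test
fixture_3day <- function() {
  daily_weather(one_cell_grid(40, -8),
                dates = seq(as.Date("2001-01-10"), as.Date("2001-01-12"), "day"),
                tmin = matrix(c(2, 0, 4), ncol = 1),
                tmax = matrix(c(12, 10, 14), ncol = 1))
}

# single warm-temperate site with three complete chill and forcing seasons
three_season_site <- function(seed = 11) {
  cfg <- weather_gen_config(grid = one_cell_grid(39.5, -8),
                            year_start = 1999, year_end = 2002, seed = seed)
  generate_baseline(cfg)
}

# hourly temperatures of one chill season at the fixture site
three_season_hourly_fixture <- function() {
  obs <- three_season_site()
  h <- interpolate_hourly(obs)
  w <- season_windows(2001, "chill")
  h$temp[h$date >= w$start & h$date <= w$end]
}

# small warm-region domain for the trend experiments
warm_domain <- function() grid_spec(lat = c(37.0, 37.9), lon = c(-8.5, -7.9))

# regional annual ensemble-mean CP series (2021-2080) under a given
# imposed warming trend
annual_cp_series <- function(seed, trend, n_models = 2, grid = warm_domain()) {
  cfg <- weather_gen_config(grid = grid, year_start = 1989, year_end = 2005,
                            bias_jitter = 0, seed = seed)
  sims <- generate_scenario_set(cfg, n_models, c(s = trend), future_end = 2080)
  ann <- lapply(sims, function(s) {
    tt <- suppressWarnings(seasonal_totals(s, "chill", years = 2021:2080))
    stats::aggregate(value ~ season_year, tt, mean)
  })
  data.frame(region = "warm", year = ann[[1]]$season_year,
             value = rowMeans(sapply(ann, `[[`, "value")))
}
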