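test_that("noise-free baseline follows the closed-form seasonal sinusoid", {
  cfg <- weather_gen_config(grid = one_cell_grid(lat = 40), year_start = 2000,
                            year_end = 2001, lat_ref = 40, noise_sd = 0,
                            warming_trend = 0)
  obs <- generate_baseline(cfg)
  doy <- as.POSIXlt(obs$dates)$yday + 1
  expected_mean <- cfg$mean_annual_T +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  expect_equal(obs$tmax[, 1], expected_mean + cfg$diurnal_range / 2)
  expect_equal(obs$tmin[, 1], expected_mean - cfg$diurnal_range / 2)
  # warmest day of year at the northern-hemisphere peak
  expect_equal(doy[which.max(obs$tmax[1:365, 1])], 196)
})

test_that("generation is a deterministic function of config and seed", {
  cfg <- weather_gen_config(grid = grid_spec(c(38, 40), c(-9, -8)),
                            year_start = 1995, year_end = 1997, seed = 99)
  a <- generate_baseline(cfg)
  b <- generate_baseline(cfg)
  expect_identical(a$tmin, b$tmin)
  expect_identical(a$tmax, b$tmax)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_baseline(cfg2)$tmin, a$tmin))
})

test_that("tmin <= tmax holds on every cell-day for noisy series", {
  for (seed in 1:5) {
    cfg <- weather_gen_config(grid = grid_spec(c(37, 41), c(-9, -7)),
                              year_start = 2000, year_end = 2001,
                              noise_sd = 4, seed = seed)
    obs <- generate_baseline(cfg)
    expect_true(all(obs$tmin <= obs$tmax))
    expect_true(all(diff(obs$dates) == 1))
  }
})

test_that("an imposed warming trend is recovered from annual means by OLS", {
  slopes <- vapply(1:20, function(seed) {
    cfg <- weather_gen_config(grid = one_cell_grid(), year_start = 2001,
                              year_end = 2060, noise_sd = 1,
                              warming_trend = 0.05, seed = seed)
    obs <- generate_baseline(cfg)
    yr <- as.integer(format(obs$dates, "%Y"))
    tm <- (obs$tmin[, 1] + obs$tmax[, 1]) / 2
    ann <- tapply(tm, yr, mean)
    unname(coef(lm(ann ~ as.integer(names(ann))))[2])
  }, 0)
  expect_true(all(abs(slopes - 0.05) < 0.02))
})

test_that("scenario historical segment carries the configured additive bias", {
  cfg <- weather_gen_config(grid = grid_spec(c(38, 39), c(-9, -8)),
                            bias_offset = 3, bias_scale = 1, bias_jitter = 0,
                            seed = 5)
  base <- generate_baseline(cfg)
  sim <- generate_scenario_set(cfg, 1, c(s = 0.03), future_end = 2040)[[1]]
  hist <- sim$dates <= max(base$dates)
  dmean <- mean((sim$tmin[hist, ] + sim$tmax[hist, ]) / 2) -
    mean((base$tmin + base$tmax) / 2)
  expect_lt(abs(dmean - 3), 0.1)
  expect_equal(sim$meta$true_bias$offset, 3)
  expect_equal(sim$meta$true_bias$scale, 1)
})

test_that("scenario sets have one labeled member per model and scenario", {
  cfg <- weather_gen_config(grid = one_cell_grid(), seed = 3)
  sims <- generate_scenario_set(cfg, 4, c(rcp45 = 0.02, rcp85 = 0.045),
                                future_end = 2030)
  expect_length(sims, 8)
  labs <- t(sapply(sims, function(s)
    c(s$provenance$model, s$provenance$scenario)))
  expect_equal(anyDuplicated(labs), 0)
  expect_setequal(unique(labs[, 1]),
                  c("model01", "model02", "model03", "model04"))
  expect_error(generate_scenario_set(cfg, 4, character(0)), "empty")
  expect_error(generate_scenario_set(cfg, 0, c(a = 0)), "n_models")
})

test_that("zero bias and identical seed reproduce the baseline historically", {
  cfg <- weather_gen_config(grid = grid_spec(c(38, 39), c(-9, -8)),
                            bias_offset = 0, bias_scale = 1, bias_jitter = 0,
                            seed = 21)
  base <- generate_baseline(cfg)
  sim <- generate_scenario_set(cfg, 1, c(s = 0.05), future_end = 2050)[[1]]
  hist <- sim$dates <= max(base$dates)
  expect_equal(sim$tmin[hist, ], base$tmin, tolerance = 1e-12)
  expect_equal(sim$tmax[hist, ], base$tmax, tolerance = 1e-12)
  # and the future segment warms: last decade exceeds the first
  yr <- as.integer(format(sim$dates, "%Y"))
  expect_gt(mean(sim$tmax[yr >= 2041, ]), mean(sim$tmax[yr <= 2005, ]))
})

test_that("config validation rejects degenerate parameters", {
  g <- one_cell_grid()
  expect_error(weather_gen_config(g, 2000, 1999), "year_end")
  expect_error(weather_gen_config(g, diurnal_range = 0), "diurnal_range")
  expect_error(weather_gen_config(g, ar1_coef = 1), "ar1_coef")
  expect_error(weather_gen_config(g, noise_sd = -1), "noise_sd")
  expect_error(weather_gen_config(g, mean_annual_T = NaN), "non-finite")
  expect_error(grid_spec(c(40, 38), -8), "increasing")
  expect_error(grid_spec(91, -8), "lat")
})

test_that("per-site CSV round trip preserves the series", {
  obs <- three_season_site()
  f <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(obs, f)
  back <- read_weather_csv(f, lat = 39.5, lon = -8)
  expect_equal(back$dates, obs$dates)
  expect_equal(back$tmin[, 1], obs$tmin[, 1], tolerance = 1e-6)
  expect_equal(back$tmax[, 1], obs$tmax[, 1], tolerance = 1e-6)
})

test_that("NetCDF export writes CF-style tasmin/tasmax in degC", {
  obs <- generate_baseline(weather_gen_config(grid_spec(c(38, 39), c(-9, -8)),
                                              2000, 2000, seed = 2))
  f <- withr::local_tempfile(fileext = ".nc")
  write_weather_netcdf(obs, f)
  nc <- ncdf4::nc_open(f)
  on.exit(ncdf4::nc_close(nc))
  expect_setequal(names(nc$var), c("tasmin", "tasmax"))
  v <- ncdf4::ncvar_get(nc, "tasmax")
  expect_equal(dim(v), c(2, 2, length(obs$dates)))
  expect_equal(v[1, 1, ], obs$tmax[, 1], tolerance = 1e-6)
  # cell 2 is the next longitude at the first latitude
  expect_equal(v[2, 1, ], obs$tmax[, 2], tolerance = 1e-6)
})
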