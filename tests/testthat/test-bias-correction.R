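make_field <- function(grid, fun, dates = seq(as.Date("2001-06-01"),
                                              by = "day", length.out = 3)) {
  cc <- cell_coords(grid)
  v <- fun(cc$lat, cc$lon)
  daily_weather(grid, dates,
                tmin = matrix(rep(v, each = length(dates)), length(dates)),
                tmax = matrix(rep(v + 5, each = length(dates)), length(dates)))
}

test_that("bilinear regridding is exact on constant and linear fields", {
  src <- grid_spec(lat = seq(36, 42, by = 1), lon = seq(-10, -6, by = 1))
  tgt <- grid_spec(lat = seq(36.5, 41.5, by = 1.25), lon = seq(-9.5, -6.5, by = 1.5))
  const <- make_field(src, function(lat, lon) rep(7, length(lat)))
  rc <- regrid_bilinear(const, tgt)
  expect_true(all(rc$tmin == 7) && all(rc$tmax == 12))
  lin <- make_field(src, function(lat, lon) 2 * lat + 3 * lon)
  rl <- regrid_bilinear(lin, tgt)
  cc <- cell_coords(tgt)
  expect_equal(rl$tmin[1, ], 2 * cc$lat + 3 * cc$lon, tolerance = 1e-10)
})

test_that("bilinear weights at a 2x2 cell center average the corners", {
  src <- grid_spec(lat = c(0, 1), lon = c(0, 1))
  # corner values 0,1 (lat 0) and 1,2 (lat 1): center is 1.0
  f <- daily_weather(src, as.Date("2001-01-01"),
                     tmin = matrix(c(0, 1, 1, 2), 1), tmax = matrix(c(0, 1, 1, 2) + 1, 1))
  r <- regrid_bilinear(f, grid_spec(0.5, 0.5))
  expect_equal(r$tmin[1, 1], 1.0)
  expect_error(regrid_bilinear(f, grid_spec(50, 50)), "disjoint")
  expect_warning(regrid_bilinear(f, grid_spec(c(0.5), c(-0.2, 0.5))),
                 "extrapolation")
})

test_that("quantile map of identical series is the identity", {
  obs <- generate_baseline(weather_gen_config(grid_spec(c(38, 39), c(-9, -8)),
                                              seed = 31))
  qm <- fit_eqm(obs, obs)
  expect_equal(qm$obs_q, qm$sim_q)
  corr <- apply_eqm(qm, obs)
  expect_equal(corr$tmin, obs$tmin, tolerance = 1e-9)
  expect_equal(corr$tmax, obs$tmax, tolerance = 1e-9)
})

test_that("an additive bias appears verbatim in the fitted quantiles and is undone", {
  obs <- generate_baseline(weather_gen_config(grid_spec(c(38, 39), c(-9, -8)),
                                              seed = 32))
  sim <- daily_weather(obs$grid, obs$dates, obs$tmin + 3, obs$tmax + 3)
  qm <- fit_eqm(obs, sim)
  expect_equal(qm$sim_q - qm$obs_q, array(3, dim(qm$sim_q)),
               ignore_attr = TRUE, tolerance = 1e-9)
  # a fresh series with the same bias is shifted back by 3 inside the range
  sim2 <- daily_weather(obs$grid, obs$dates, obs$tmin + 3.5, obs$tmax + 2.5)
  corr <- apply_eqm(qm, sim2)
  inside <- sim2$tmin > apply(sim$tmin, 2, quantile, 0.02)[col(sim2$tmin)] &
    sim2$tmin < apply(sim$tmin, 2, quantile, 0.98)[col(sim2$tmin)]
  expect_equal(corr$tmin[inside], sim2$tmin[inside] - 3, tolerance = 1e-9)
})

test_that("values beyond the fitted range get the outermost-quantile shift", {
  obs <- generate_baseline(weather_gen_config(grid_spec(38, -8), seed = 33))
  sim <- daily_weather(obs$grid, obs$dates, obs$tmin + 3, obs$tmax + 3)
  qm <- fit_eqm(obs, sim)
  probe <- sim
  probe$tmax[1, 1] <- max(sim$tmax[, 1]) + 10   # beyond every fitted quantile
  probe$tmin[1, 1] <- probe$tmax[1, 1] - 1
  corr <- apply_eqm(qm, probe)
  k <- length(qm$probs)
  mon <- as.POSIXlt(obs$dates[1])$mon + 1
  shift <- unname(qm$obs_q[k, mon, 1, "tmax"] - qm$sim_q[k, mon, 1, "tmax"])
  expect_equal(corr$tmax[1, 1], probe$tmax[1, 1] + shift, tolerance = 1e-9)
  expect_gt(corr$tmax[1, 1], max(obs$tmax[, 1]))  # shifted, not clamped
})

test_that("the correction transform is monotone per cell and month", {
  obs <- generate_baseline(weather_gen_config(grid_spec(38, -8), seed = 34))
  sim <- daily_weather(obs$grid, obs$dates, 1.15 * obs$tmin - 1,
                       1.15 * obs$tmax + 1)
  qm <- fit_eqm(obs, sim)
  x <- seq(-15, 45, by = 0.1)
  for (m in c(1, 7)) {
    y <- chillforce:::eqm_transform(x, qm$sim_q[, m, 1, "tmax"],
                                    qm$obs_q[, m, 1, "tmax"])
    expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("a multiplicative bias is removed on held-out realizations", {
  errs <- vapply(1:20, function(seed) {
    g <- grid_spec(39, -8)
    obs <- generate_baseline(weather_gen_config(g, seed = seed))
    truth <- generate_baseline(weather_gen_config(g, seed = seed + 500))
    sim <- daily_weather(g, truth$dates, 1.2 * truth$tmin, 1.2 * truth$tmax)
    corr <- suppressMessages(apply_eqm(fit_eqm(obs, sim), sim))
    mean(corr$tmax - truth$tmax)
  }, 0)
  # corrected series should sit close to the unbiased truth on average
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("fitting fails loudly on mismatched grids or thin pools", {
  obs <- generate_baseline(weather_gen_config(grid_spec(38, -8), seed = 35))
  other <- generate_baseline(weather_gen_config(grid_spec(39, -8), seed = 35))
  expect_error(fit_eqm(obs, other), "same grid")
  short <- daily_weather(obs$grid, obs$dates[1:60],
                         obs$tmin[1:60, , drop = FALSE],
                         obs$tmax[1:60, , drop = FALSE])
  expect_error(fit_eqm(short, short), "fewer than 30 days")
  expect_error(fit_eqm(obs, obs, n_quantiles = 1), "n_quantiles")
})
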