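#' Configuration for the synthetic weather generator
#'
#' The generator emulates the statistical structure of gridded daily
#' temperature products used in fruit-climate studies: a seasonal cycle, a
#' latitudinal gradient, AR(1) day-to-day persistence, an optional linear
#' warming trend, and (for scenario series) a known additive/multiplicative
#' bias. Defaults describe a Portugal-like temperate climate on an 8 x 8
#' grid spanning 36.5-42.5 degN, 9.5-6 degW.
#'
#' The daily mean temperature of cell c on day d is
#' \deqn{T(c,d) = T_0 + g (lat_c - lat_{ref})
#'   + A \cos(2\pi (doy_d - doy_{peak}) / 365.25) + w \, t_d + \epsilon(c,d)}
#' where \eqn{t_d} is time in years since the series start, and
#' \eqn{\epsilon} is stationary AR(1) noise with marginal standard deviation
#' `noise_sd`. Daily extremes are `tmax = mean + diurnal_range/2 + e1` and
#' `tmin = mean - diurnal_range/2 + e2` with independent extra noise of sd
#' `noise_sd/2`, followed by a swap repair wherever noise inverts the pair.
#' The peak day-of-year is fixed at 196 (northern-hemisphere mid-July).
#'
#' @param grid a [grid_spec()].
#' @param year_start,year_end first and last calendar year (inclusive).
#' @param mean_annual_T annual-mean daily-mean temperature at `lat_ref`, degC.
#' @param lat_ref reference latitude for `mean_annual_T`, degrees north.
#' @param lat_gradient change in mean temperature per degree latitude
#'   (degC/deg; negative means the north is cooler).
#' @param seasonal_amplitude half peak-to-trough seasonal amplitude, degC.
#' @param diurnal_range mean tmax - tmin, degC (> 0).
#' @param ar1_coef lag-1 autocorrelation of daily-mean noise, in \[0, 1).
#' @param noise_sd marginal standard deviation of daily-mean noise, degC.
#' @param warming_trend linear trend in degC per year.
#' @param bias_offset additive bias for scenario series, degC.
#' @param bias_scale multiplicative bias for scenario series (applied as
#'   `scale * T + offset`).
#' @param bias_jitter sd of the deterministic per-model perturbation of
#'   `bias_offset` in [generate_scenario_set()] (degC); 0 gives every model
#'   exactly the central bias.
#' @param seed integer RNG seed; all output is a deterministic function of
#'   the configuration including the seed.
#' @return A list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(grid = grid_spec(lat = seq(36.5, 42.5, length.out = 8),
                                                lon = seq(-9.5, -6.0, length.out = 8)),
                               year_start = 1989, year_end = 2005,
                               mean_annual_T = 15, lat_ref = 40,
                               lat_gradient = -0.7,
                               seasonal_amplitude = 6.5,
                               diurnal_range = 10,
                               ar1_coef = 0.7, noise_sd = 2,
                               warming_trend = 0,
                               bias_offset = 0, bias_scale = 1,
                               bias_jitter = 0.2,
                               seed = 1L) {
  cfg <- list(grid = grid, year_start = as.integer(year_start),
              year_end = as.integer(year_end),
              mean_annual_T = mean_annual_T, lat_ref = lat_ref,
              lat_gradient = lat_gradient,
              seasonal_amplitude = seasonal_amplitude,
              diurnal_range = diurnal_range,
              ar1_coef = ar1_coef, noise_sd = noise_sd,
              warming_trend = warming_trend,
              bias_offset = bias_offset, bias_scale = bias_scale,
              bias_jitter = bias_jitter,
              seed = as.integer(seed))
  validate_weather_gen_config(cfg)
  structure(cfg, class = "weather_gen_config")
}

validate_weather_gen_config <- function(cfg) {
  stopifnot(inherits(cfg$grid, "grid_spec"))
  num <- c(cfg$mean_annual_T, cfg$lat_ref, cfg$lat_gradient,
           cfg$seasonal_amplitude, cfg$diurnal_range, cfg$ar1_coef,
           cfg$noise_sd, cfg$warming_trend, cfg$bias_offset,
           cfg$bias_scale, cfg$bias_jitter)
  if (!all(is.finite(num))) stop("non-finite value in weather_gen_config")
  if (cfg$year_end < cfg$year_start) stop("year_end < year_start")
  if (cfg$diurnal_range <= 0) stop("diurnal_range must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(cfg$ar1_coef) >= 1) stop("|ar1_coef| must be < 1")
  invisible(cfg)
}

# peak of the seasonal cycle: northern-hemisphere mid-July
PEAK_DOY <- 196

#' @export
print.weather_gen_config <- function(x, ...) {
  cat(sprintf("<weather_gen_config> %d-%d, %d cells, T0=%.1f degC, trend=%+.3f degC/yr, seed=%d\n",
              x$year_start, x$year_end, n_cells(x$grid),
              x$mean_annual_T, x$warming_trend, x$seed))
  invisible(x)
}

#' Daily weather series container
#'
#' @param grid a [grid_spec()].
#' @param dates a gap-free `Date` vector (proleptic Gregorian, leap days
#'   included).
#' @param tmin,tmax numeric matrices `length(dates) x n_cells(grid)`, degC,
#'   with `tmin <= tmax` everywhere.
#' @param provenance list with elements `source` ("observed" or "model"),
#'   and optionally `model` and `scenario` labels.
#' @param meta free-form list (e.g. true imposed bias, for test assertions).
#' @return An object of class `daily_weather`.
#' @export
daily_weather <- function(grid, dates, tmin, tmax,
                          provenance = list(source = "observed"),
                          meta = list()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(dates, "Date"))
  nc <- n_cells(grid)
  tmin <- as.matrix(tmin); tmax <- as.matrix(tmax)
  if (nrow(tmin) != length(dates) || ncol(tmin) != nc ||
      !all(dim(tmin) == dim(tmax)))
    stop("tmin/tmax must be length(dates) x n_cells matrices")
  if (length(dates) > 1 && any(diff(dates) != 1))
    stop("date axis has gaps")
  if (any(tmin > tmax + 1e-12, na.rm = TRUE))
    stop("tmin > tmax found")
  structure(list(grid = grid, dates = dates, tmin = tmin, tmax = tmax,
                 provenance = provenance, meta = meta),
            class = "daily_weather")
}

#' @export
print.daily_weather <- function(x, ...) {
  pv <- paste(unlist(x$provenance), collapse = "/")
  cat(sprintf("<daily_weather> %s: %s..%s (%d days) x %d cells\n",
              pv, format(min(x$dates)), format(max(x$dates)),
              length(x$dates), n_cells(x$grid)))
  invisible(x)
}

# deterministic per-(seed, cell, component) substream so that a longer
# series shares its historical prefix with a shorter one bit-for-bit
substream_seed <- function(seed, cell, component) {
  (as.integer(seed) %% 100000L) * 20011L + cell * 13L + component
}

# shared engine: deterministic seasonal/gradient/trend surface + seeded
# AR(1) noise. trend_fun(tyears) returns the warming contribution in degC
# as a function of time in years since `dates[1]`.
gen_daily_series <- function(cfg, dates, trend_fun) {
  coords <- cell_coords(cfg$grid)
  n_days <- length(dates)
  nc <- nrow(coords)
  doy <- as.POSIXlt(dates)$yday + 1
  tyears <- as.numeric(dates - dates[1]) / 365.25
  seasonal <- cfg$seasonal_amplitude * cos(2 * pi * (doy - PEAK_DOY) / 365.25)
  base_t <- seasonal + trend_fun(tyears)

  tmin <- matrix(0, n_days, nc)
  tmax <- matrix(0, n_days, nc)
  innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coef^2)
  for (cell in seq_len(nc)) {
    mu <- cfg$mean_annual_T + cfg$lat_gradient * (coords$lat[cell] - cfg$lat_ref) +
      base_t
    if (cfg$noise_sd > 0) {
      set.seed(substream_seed(cfg$seed, cell, 1L))
      z <- rnorm(n_days)
      e <- numeric(n_days)
      e[1] <- cfg$noise_sd * z[1]
      if (n_days > 1)
        for (d in 2:n_days) e[d] <- cfg$ar1_coef * e[d - 1] + innov_sd * z[d]
      set.seed(substream_seed(cfg$seed, cell, 2L))
      e_min <- 0.5 * cfg$noise_sd * rnorm(n_days)
      set.seed(substream_seed(cfg$seed, cell, 3L))
      e_max <- 0.5 * cfg$noise_sd * rnorm(n_days)
    } else {
      e <- e_min <- e_max <- numeric(n_days)
    }
    m <- mu + e
    lo <- m - cfg$diurnal_range / 2 + e_min
    hi <- m + cfg$diurnal_range / 2 + e_max
    sw <- lo > hi
    if (any(sw)) {  # swap repair preserves the tmin <= tmax invariant
      tmp <- lo[sw]; lo[sw] <- hi[sw]; hi[sw] <- tmp
    }
    tmin[, cell] <- lo
    tmax[, cell] <- hi
  }
  list(tmin = tmin, tmax = tmax)
}

#' Generate an observational-baseline-like daily weather series
#'
#' See [weather_gen_config()] for the generating model. The output is a
#' deterministic function of the configuration (including its seed); any
#' warming trend is linear over the whole series.
#'
#' @param config a [weather_gen_config()].
#' @return A [daily_weather()] with provenance `source = "observed"`.
#' @examples
#' cfg <- weather_gen_config(grid_spec(40, -8), 2000, 2002, noise_sd = 0)
#' obs <- generate_baseline(cfg)
#' range(obs$tmax - obs$tmin)  # == diurnal_range exactly (no noise)
#' @export
generate_baseline <- function(config) {
  validate_weather_gen_config(config)
  dates <- seq(as.Date(sprintf("%d-01-01", config$year_start)),
               as.Date(sprintf("%d-12-31", config$year_end)), by = "day")
  w <- gen_daily_series(config, dates,
                        function(ty) config$warming_trend * ty)
  daily_weather(config$grid, dates, w$tmin, w$tmax,
                provenance = list(source = "observed"))
}

#' Generate a set of scenario-like daily weather series
#'
#' Each series spans the historical segment (the config years, matching the
#' baseline climate) plus a future segment through `future_end`. All model
#' pairs within a scenario share one synthetic truth; each model then gets a
#' distinct known bias `scale * T + offset`, with per-model offsets drawn
#' deterministically from the seed around `config$bias_offset`
#' (sd `config$bias_jitter`). Scenario warming starts the year after the
#' historical segment ends, so the historical overlap is unwarmed and a
#' quantile map can be fitted against the baseline.
#'
#' The true imposed bias of each series is recorded in `meta$true_bias`.
#'
#' @param config a [weather_gen_config()]; its years define the historical
#'   segment and its `bias_offset`/`bias_scale` the central model bias.
#' @param n_models number of mock GCM-RCM model pairs (>= 1).
#' @param scenarios named numeric vector of warming trends in degC/yr, one
#'   per scenario (e.g. `c(rcp45 = 0.02, rcp85 = 0.045)`); a bare character
#'   vector of labels reuses `config$warming_trend` for every scenario.
#' @param future_end last calendar year of the future segment.
#' @return A list of [daily_weather()] objects, one per model x scenario,
#'   each with provenance `source = "model"`, `model`, `scenario`.
#' @export
generate_scenario_set <- function(config, n_models, scenarios,
                                  future_end = 2080) {
  validate_weather_gen_config(config)
  if (n_models < 1) stop("n_models must be >= 1")
  if (length(scenarios) == 0) stop("scenario list is empty")
  if (is.character(scenarios)) {
    trends <- rep(config$warming_trend, length(scenarios))
    names(trends) <- scenarios
  } else {
    trends <- scenarios
    if (is.null(names(trends)) || any(names(trends) == ""))
      stop("numeric `scenarios` must be a named vector of degC/yr trends")
  }
  if (future_end < config$year_end) stop("future_end precedes historical end")

  dates <- seq(as.Date(sprintf("%d-01-01", config$year_start)),
               as.Date(sprintf("%d-12-31", future_end)), by = "day")
  pivot_ty <- as.numeric(as.Date(sprintf("%d-01-01", config$year_end + 1)) -
                           dates[1]) / 365.25

  # per-model bias perturbations, deterministic in the seed
  set.seed(substream_seed(config$seed, 0L, 9L))
  off_jit <- rnorm(n_models, 0, config$bias_jitter)
  scl_jit <- rnorm(n_models, 0, config$bias_jitter * 0.05)

  out <- list()
  for (sc in names(trends)) {
    tr <- trends[[sc]]
    w <- gen_daily_series(config, dates,
                          function(ty) tr * pmax(0, ty - pivot_ty))
    for (m in seq_len(n_models)) {
      offset <- config$bias_offset + off_jit[m]
      scale  <- config$bias_scale + scl_jit[m]
      lab <- sprintf("model%02d", m)
      out[[paste(lab, sc, sep = ".")]] <- daily_weather(
        config$grid, dates,
        tmin = scale * w$tmin + offset,
        tmax = scale * w$tmax + offset,
        provenance = list(source = "model", model = lab, scenario = sc),
        meta = list(true_bias = list(offset = offset, scale = scale),
                    trend = tr, hist_end = config$year_end))
    }
  }
  out
}

#' Write / read a single-cell daily weather series as CSV
#'
#' Columns `date,tmin,tmax`. The grid must contain exactly one cell for
#' writing; reading creates a one-cell series at the stated coordinates.
#'
#' @param x a one-cell [daily_weather()].
#' @param path CSV path.
#' @export
write_weather_csv <- function(x, path) {
  stopifnot(inherits(x, "daily_weather"))
  if (n_cells(x$grid) != 1)
    stop("CSV export is per-site; supply a one-cell series")
  write.csv(data.frame(date = format(x$dates), tmin = x$tmin[, 1],
                       tmax = x$tmax[, 1]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @param lat,lon site coordinates, degrees.
#' @export
read_weather_csv <- function(path, lat, lon) {
  d <- read.csv(path)
  stopifnot(all(c("date", "tmin", "tmax") %in% names(d)))
  daily_weather(grid_spec(lat, lon), as.Date(d$date),
                matrix(d$tmin, ncol = 1), matrix(d$tmax, ncol = 1))
}

#' Optional NetCDF export of a daily weather series
#'
#' Writes CF-style `tasmin`/`tasmax` (degC) on dimensions
#' (`lon`, `lat`, `time`). Requires the ncdf4 package.
#'
#' @param x a [daily_weather()].
#' @param path output `.nc` path.
#' @export
write_weather_netcdf <- function(x, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("ncdf4 is not installed; use write_weather_csv() instead")
  stopifnot(inherits(x, "daily_weather"))
  g <- x$grid
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dim_t <- ncdf4::ncdim_def("time",
                            sprintf("days since %s", format(x$dates[1])),
                            as.numeric(x$dates - x$dates[1]),
                            unlim = TRUE)
  v_min <- ncdf4::ncvar_def("tasmin", "degC", list(dim_lon, dim_lat, dim_t))
  v_max <- ncdf4::ncvar_def("tasmax", "degC", list(dim_lon, dim_lat, dim_t))
  nc <- ncdf4::nc_create(path, list(v_min, v_max))
  on.exit(ncdf4::nc_close(nc))
  arr <- function(m) aperm(array(t(m), dim = c(length(g$lon), length(g$lat),
                                               length(x$dates))), c(1, 2, 3))
  ncdf4::ncvar_put(nc, v_min, arr(x$tmin))
  ncdf4::ncvar_put(nc, v_max, arr(x$tmax))
  invisible(path)
}
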