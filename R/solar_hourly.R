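#' Sunrise, sunset and daylength from latitude and day of year
#'
#' Standard day-angle formulation: solar declination
#' \eqn{\delta = 23.45 \sin(2\pi (284 + doy) / 365)} degrees, hour angle at
#' sunrise from \eqn{\cos H_0 = -\tan(lat)\tan(\delta)}, daylength
#' \eqn{2 H_0 \cdot 24 / 360} hours. The day is symmetric about solar noon
#' fixed at 12:00 local solar time (`sunrise = 12 - daylength/2`). Polar
#' day/night cases are clamped to daylength 24 or 0 with a warning;
#' latitudes beyond 66.5 degrees are outside the intended temperate use.
#'
#' @param latitude degrees north.
#' @param day_of_year integer 1-366.
#' @return list with `sunrise`, `sunset` (hours, local solar time) and
#'   `daylength` (hours); vectorized over `day_of_year`.
#' @examples
#' solar_times(40, 172)$daylength  # near-solstice, about 15 h
#' @export
solar_times <- function(latitude, day_of_year) {
  stopifnot(length(latitude) == 1, is.finite(latitude), abs(latitude) < 90)
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("day_of_year must be in 1..366")
  if (abs(latitude) > 66.5)
    warning("latitude beyond 66.5 degrees: polar day/night clamped")
  decl <- 23.45 * sin(2 * pi * (284 + day_of_year) / 365) * pi / 180
  cosh0 <- -tan(latitude * pi / 180) * tan(decl)
  clamped <- abs(cosh0) > 1
  if (any(clamped) && abs(latitude) <= 66.5)
    warning("polar day/night encountered; daylength clamped to [0, 24]")
  cosh0 <- pmin(1, pmax(-1, cosh0))
  daylength <- 2 * acos(cosh0) * 24 / (2 * pi)
  list(sunrise = 12 - daylength / 2,
       sunset = 12 + daylength / 2,
       daylength = daylength)
}

# integer-hour anchors of the diurnal curve for a vector of days:
# sunrise/sunset rounded to whole hours; temperature peak at sunset - 3 h
# (kept at least one hour after sunrise)
diurnal_anchors <- function(latitude, doy) {
  st <- solar_times(latitude, doy)
  srh <- round(st$sunrise)
  ssh <- round(st$sunset)
  peak <- pmax(srh + 1, ssh - 3)
  list(srh = srh, ssh = ssh, peak = peak)
}

#' Reconstruct hourly temperatures from daily extremes
#'
#' Idealized diurnal curve: during daytime the temperature follows a sine
#' from `tmin` at sunrise up to `tmax` at the daily peak (the sunset - 3 h
#' convention) and back down until sunset; from sunset the temperature
#' decays logarithmically toward the next day's `tmin` at the next sunrise.
#' Sunrise, sunset and the peak are rounded to whole hours so that the 24
#' sampled values of each day attain `tmin` and `tmax` exactly. The curve is
#' continuous across day boundaries. At the series edges the first day
#' stands in for its missing predecessor and the last for its missing
#' successor (self-padding).
#'
#' @param daily a [daily_weather()] (at least 3 consecutive days).
#' @param cell cell index into the grid (default 1; sites are one-cell
#'   grids).
#' @return data.frame of class `hourly_temps` with columns `date`, `hour`
#'   (0-23) and `temp` (degC), `n_days * 24` rows, and attributes
#'   `latitude` and `cell`.
#' @examples
#' cfg <- weather_gen_config(grid_spec(40, -8), 2000, 2000, noise_sd = 0)
#' h <- interpolate_hourly(generate_baseline(cfg))
#' head(h)
#' @export
interpolate_hourly <- function(daily, cell = 1) {
  stopifnot(inherits(daily, "daily_weather"),
            cell >= 1, cell <= n_cells(daily$grid))
  n <- length(daily$dates)
  if (n < 3) stop("need at least 3 consecutive days")
  lat <- cell_coords(daily$grid)$lat[cell]
  tmin <- daily$tmin[, cell]
  tmax <- daily$tmax[, cell]
  if (any(!is.finite(tmin)) || any(!is.finite(tmax)))
    stop("non-finite daily temperatures")

  doy <- as.POSIXlt(daily$dates)$yday + 1
  an <- diurnal_anchors(lat, doy)
  srh <- an$srh; ssh <- an$ssh; peak <- an$peak

  # temperature of the daytime sine at integer hour h of day d
  day_curve <- function(h, d) {
    s <- sin(pi * (h - srh[d]) / (2 * (peak[d] - srh[d])))
    tmin[d] + (tmax[d] - tmin[d]) * pmax(0, s)
  }
  t_sunset <- day_curve(ssh, seq_len(n))

  # neighbours, self-padded at the edges
  prev <- c(1, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], n)
  tss_prev <- t_sunset[prev]
  ssh_prev <- ssh[prev]
  tmin_next <- tmin[nxt]
  srh_next <- srh[nxt]

  hours <- matrix(rep(0:23, n), nrow = 24)
  D <- matrix(rep(seq_len(n), each = 24), nrow = 24)
  H <- hours

  pre <- H < srh[D]        # before sunrise: tail of last night's decay
  day <- H >= srh[D] & H <= ssh[D]
  post <- H > ssh[D]       # after sunset: tonight's decay

  temp <- matrix(NA_real_, 24, n)
  # night decay reaches tmin of the morning day exactly at its sunrise
  temp[pre] <- tss_prev[D[pre]] -
    (tss_prev[D[pre]] - tmin[D[pre]]) *
    log1p(H[pre] + 24 - ssh_prev[D[pre]]) /
    log1p(srh[D[pre]] + 24 - ssh_prev[D[pre]])
  temp[day] <- tmin[D[day]] + (tmax[D[day]] - tmin[D[day]]) *
    pmax(0, sin(pi * (H[day] - srh[D[day]]) / (2 * (peak[D[day]] - srh[D[day]]))))
  temp[post] <- t_sunset[D[post]] -
    (t_sunset[D[post]] - tmin_next[D[post]]) *
    log1p(H[post] - ssh[D[post]]) /
    log1p(srh_next[D[post]] + 24 - ssh[D[post]])

  out <- data.frame(date = rep(daily$dates, each = 24),
                    hour = rep(0:23, n),
                    temp = as.vector(temp))
  attr(out, "latitude") <- lat
  attr(out, "cell") <- cell
  class(out) <- c("hourly_temps", "data.frame")
  out
}

#' Export an hourly series to CSV
#'
#' @param hourly an `hourly_temps` data.frame from [interpolate_hourly()].
#' @param path CSV path; columns `timestamp,temp_C`.
#' @export
write_hourly_csv <- function(hourly, path) {
  stopifnot(inherits(hourly, "hourly_temps"))
  write.csv(data.frame(timestamp = sprintf("%s %02d:00",
                                           format(hourly$date), hourly$hour),
                       temp_C = hourly$temp),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
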