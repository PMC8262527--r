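#' Parameters of the Dynamic chill model
#'
#' The canonical published parameter set of the two-step kinetic model of
#' chill accumulation (temperatures in Kelvin inside the recursion). Chill
#' is effective roughly between -16 and 24 degC with an optimum around
#' 4 degC; high temperatures negate previously accumulated intermediate.
#'
#' @param slp slope of the sigmoidal conversion function (unitless).
#' @param tetmlt transition temperature of the conversion sigmoid (K).
#' @param a0,a1 rate prefactors (1/h); `a1 > a0`.
#' @param e0,e1 activation energies (K).
#' @return list of class `dynamic_model_params`.
#' @export
dynamic_model_params <- function(slp = 1.6, tetmlt = 277,
                                 a0 = 1.395e5, a1 = 2.567e18,
                                 e0 = 4153.5, e1 = 12888.8) {
  p <- list(slp = slp, tetmlt = tetmlt, a0 = a0, a1 = a1, e0 = e0, e1 = e1)
  if (any(unlist(p) <= 0)) stop("Dynamic model parameters must be positive")
  if (a1 <= a0) stop("a1 must exceed a0")
  structure(p, class = "dynamic_model_params")
}

#' Parameters of the Growing Degree Hours model
#'
#' Cosine thermal response between a base, an optimum and a critical
#' temperature; zero contribution outside (Tb, Tc).
#'
#' @param Tb base temperature, degC.
#' @param Tu optimum temperature, degC.
#' @param Tc critical temperature, degC.
#' @param F stress factor in (0, 1]; 1 = unstressed.
#' @return list of class `gdh_params`. Defaults Tb=4, Tu=25, Tc=36, F=1.
#' @export
gdh_params <- function(Tb = 4, Tu = 25, Tc = 36, F = 1) {
  if (!(Tb < Tu && Tu < Tc)) stop("need Tb < Tu < Tc")
  if (!(F > 0 && F <= 1)) stop("F must be in (0, 1]")
  structure(list(Tb = Tb, Tu = Tu, Tc = Tc, F = F), class = "gdh_params")
}

#' Growing degree hours contributed by one hour at temperature T
#'
#' Piecewise cosine response, continuous on the whole real line:
#' zero at or below `Tb` and at or above `Tc`; on `[Tb, Tu]` the ramp
#' `F (Tu-Tb)/2 (1 + cos(pi + pi (T-Tb)/(Tu-Tb)))`; on `(Tu, Tc)` the
#' decline `F (Tu-Tb) (1 + cos(pi/2 + pi/2 (T-Tu)/(Tc-Tu)))`. Maximal at
#' `Tu`, where both branches equal `F (Tu - Tb)`.
#'
#' @param T temperature(s), degC; vectorized.
#' @param params a [gdh_params()].
#' @return degree-hours per hour (numeric, same length as `T`).
#' @examples
#' gdh_hour(25)  # 21 at the default optimum
#' @export
gdh_hour <- function(T, params = gdh_params()) {
  stopifnot(all(is.finite(T)))
  Tb <- params$Tb; Tu <- params$Tu; Tc <- params$Tc; F <- params$F
  out <- numeric(length(T))
  ramp <- T > Tb & T <= Tu
  decl <- T > Tu & T < Tc
  out[ramp] <- F * (Tu - Tb) / 2 *
    (1 + cos(pi + pi * (T[ramp] - Tb) / (Tu - Tb)))
  out[decl] <- F * (Tu - Tb) *
    (1 + cos(pi / 2 + pi / 2 * (T[decl] - Tu) / (Tc - Tu)))
  out
}

#' Chill portions of an hourly temperature series
#'
#' Runs the Dynamic model recursion hour by hour (see
#' [dynamic_model_params()]); the intermediate is initialized to zero at the
#' start of the series, so pass one chill season at a time (or subset with
#' `window`). The cumulative series is non-decreasing.
#'
#' @param hourly an `hourly_temps` data.frame from [interpolate_hourly()],
#'   or a bare numeric vector of hourly temperatures (degC).
#' @param params a [dynamic_model_params()].
#' @param window optional [season_windows()] row (list with `start`, `end`
#'   Dates) to subset the hourly series before accumulating.
#' @return list with `cumulative` (chill portions after each hour) and
#'   `total` (the seasonal total, last cumulative value).
#' @export
chill_portions <- function(hourly, params = dynamic_model_params(),
                           window = NULL) {
  temps <- hourly_vector(hourly, window)
  if (length(temps) == 0) stop("empty hourly window")
  if (any(!is.finite(temps))) stop("non-finite hourly temperatures")
  cum <- cp_dynamic_cpp(temps, params$slp, params$tetmlt,
                        params$a0, params$a1, params$e0, params$e1)
  list(cumulative = cum, total = cum[length(cum)])
}

#' Accumulate growing degree hours over a forcing window
#'
#' @param hourly an `hourly_temps` data.frame or numeric vector (degC).
#' @param window optional forcing-season window (list with `start`, `end`)
#'   to subset by date; `kind`, if present, must be `"forcing"`.
#' @param params a [gdh_params()].
#' @return list with `total` (degree-hours) and `total_k` (same in units of
#'   10^3 degree-hours, the usual reporting convention).
#' @export
gdh_accumulate <- function(hourly, window = NULL, params = gdh_params()) {
  if (!is.null(window) && !is.null(window$kind) && window$kind != "forcing")
    stop("gdh_accumulate expects a forcing window")
  temps <- hourly_vector(hourly, window)
  if (length(temps) == 0) stop("empty hourly window")
  tot <- sum(gdh_hour(temps, params))
  list(total = tot, total_k = tot / 1000)
}

hourly_vector <- function(hourly, window = NULL) {
  if (is.numeric(hourly)) {
    if (!is.null(window)) stop("window subsetting needs a dated hourly series")
    return(as.numeric(hourly))
  }
  stopifnot(inherits(hourly, "hourly_temps"))
  if (is.null(window)) return(hourly$temp)
  sel <- hourly$date >= window$start & hourly$date <= window$end
  covered <- unique(hourly$date[sel])
  expected <- seq(window$start, window$end, by = "day")
  if (!all(expected %in% covered))
    stop(sprintf("hourly series does not cover window %s..%s",
                 format(window$start), format(window$end)))
  hourly$temp[sel]
}

#' Seasonal accumulation windows
#'
#' A chill season labeled by year Y runs from 1 October of Y-1 through the
#' end of February of Y (29 February in leap years); a forcing season
#' labeled Y runs from 1 February through 31 October of Y. The chill label
#' follows the year containing January-February, matching how safe-chill
#' years are counted against harvest years.
#'
#' @param years integer vector of season-year labels.
#' @param kind `"chill"` or `"forcing"`.
#' @return data.frame with columns `season_year`, `kind`, `start`, `end`.
#' @examples
#' season_windows(1992, "chill")  # 1991-10-01 .. 1992-02-29
#' @export
season_windows <- function(years, kind = c("chill", "forcing")) {
  kind <- match.arg(kind)
  years <- as.integer(years)
  if (kind == "chill") {
    start <- as.Date(sprintf("%d-10-01", years - 1))
    feb1 <- as.Date(sprintf("%d-02-01", years))
    end <- seq_feb_end(years)
  } else {
    start <- as.Date(sprintf("%d-02-01", years))
    end <- as.Date(sprintf("%d-10-31", years))
  }
  data.frame(season_year = years, kind = kind, start = start, end = end)
}

seq_feb_end <- function(years) {
  leap <- (years %% 4 == 0 & years %% 100 != 0) | years %% 400 == 0
  as.Date(sprintf("%d-02-%02d", years, ifelse(leap, 29, 28)))
}

#' Seasonal CP or GDH totals for every cell of a daily series
#'
#' Interpolates each cell to hourly resolution and accumulates chill
#' portions or growing degree hours over every season window fully covered
#' by the data; seasons with incomplete coverage (typically the first chill
#' season, which needs the preceding autumn) are omitted with a warning.
#'
#' @param daily a [daily_weather()].
#' @param kind `"chill"` (CP) or `"forcing"` (GDH).
#' @param cp_params a [dynamic_model_params()].
#' @param gdh_params a [gdh_params()].
#' @param years optional integer vector restricting the season-year labels.
#' @return data.frame of class `seasonal_totals`: columns `cell`, `lat`,
#'   `lon`, `season_year`, `variable` ("CP" or "GDH") and `value`.
#' @export
seasonal_totals <- function(daily, kind = c("chill", "forcing"),
                            cp_params = dynamic_model_params(),
                            gdh_params = chillforce::gdh_params(),
                            years = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(daily, "daily_weather"))
  if (any(daily$grid$lat < 0))
    stop("southern-hemisphere latitudes are not supported: ",
         "accumulation windows are northern-hemisphere")
  d0 <- min(daily$dates); d1 <- max(daily$dates)
  yr <- as.integer(format(daily$dates, "%Y"))
  cand <- if (is.null(years)) seq(min(yr), max(yr)) else as.integer(years)
  win <- season_windows(cand, kind)
  ok <- win$start >= d0 & win$end <= d1
  if (any(!ok))
    warning(sprintf("%d %s season(s) without full coverage omitted (%s)",
                    sum(!ok), kind,
                    paste(win$season_year[!ok], collapse = ", ")))
  win <- win[ok, , drop = FALSE]
  if (nrow(win) == 0) stop("no fully covered season in the series")

  coords <- cell_coords(daily$grid)
  res <- vector("list", nrow(coords))
  varname <- if (kind == "chill") "CP" else "GDH"
  # hourly rows of each window by index (the hourly frame is regular:
  # 24 rows per day, days contiguous from d0)
  row_start <- as.numeric(win$start - d0) * 24 + 1
  row_end <- (as.numeric(win$end - d0) + 1) * 24
  for (cell in seq_len(nrow(coords))) {
    temps <- interpolate_hourly(daily, cell)$temp
    vals <- numeric(nrow(win))
    for (i in seq_len(nrow(win))) {
      tw <- temps[row_start[i]:row_end[i]]
      vals[i] <- if (kind == "chill")
        chill_portions(tw, cp_params)$total
      else
        gdh_accumulate(tw, params = gdh_params)$total
    }
    res[[cell]] <- data.frame(cell = cell, lat = coords$lat[cell],
                              lon = coords$lon[cell],
                              season_year = win$season_year,
                              variable = varname, value = vals)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("seasonal_totals", "data.frame")
  out
}
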