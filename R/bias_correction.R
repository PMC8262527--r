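#' Bilinearly regrid a daily weather series onto a target grid
#'
#' Per-day bilinear interpolation of `tmin` and `tmax` in latitude and
#' longitude; exact for fields linear in both coordinates. Target centers
#' outside the source span are clamped to the source edge
#' (nearest-edge extrapolation) and a warning reports how many.
#'
#' @param field a [daily_weather()] on the source grid.
#' @param target a [grid_spec()].
#' @return A [daily_weather()] on `target`, same dates and provenance.
#' @export
regrid_bilinear <- function(field, target) {
  stopifnot(inherits(field, "daily_weather"), inherits(target, "grid_spec"))
  src <- field$grid
  if (max(target$lon) < min(src$lon) || min(target$lon) > max(src$lon) ||
      max(target$lat) < min(src$lat) || min(target$lat) > max(src$lat))
    stop("source and target grids are disjoint")
  out_lon <- pmin(pmax(target$lon, min(src$lon)), max(src$lon))
  out_lat <- pmin(pmax(target$lat, min(src$lat)), max(src$lat))
  n_clamp <- sum(out_lon != target$lon) + sum(out_lat != target$lat)
  if (n_clamp > 0)
    warning(sprintf("%d target coordinate(s) outside source span: nearest-edge extrapolation", n_clamp))

  W <- bilinear_weights(src, out_lat, out_lon)
  new_field <- daily_weather(target, field$dates,
                             tmin = field$tmin %*% W,
                             tmax = pmax(field$tmin %*% W, field$tmax %*% W),
                             provenance = field$provenance,
                             meta = field$meta)
  new_field
}

# n_src_cells x n_target_cells weight matrix; source/target cells ordered
# lon-fastest (see cell_coords)
bilinear_weights <- function(src, t_lat, t_lon) {
  nlon <- length(src$lon); nlat <- length(src$lat)
  tg <- expand.grid(lon = t_lon, lat = t_lat)  # lon fastest
  W <- matrix(0, nlon * nlat, nrow(tg))
  ix <- bracket(src$lon, tg$lon)
  iy <- bracket(src$lat, tg$lat)
  for (k in seq_len(nrow(tg))) {
    i0 <- ix$lo[k]; i1 <- ix$hi[k]; fx <- ix$frac[k]
    j0 <- iy$lo[k]; j1 <- iy$hi[k]; fy <- iy$frac[k]
    W[(j0 - 1) * nlon + i0, k] <- (1 - fx) * (1 - fy)
    W[(j0 - 1) * nlon + i1, k] <- W[(j0 - 1) * nlon + i1, k] + fx * (1 - fy)
    W[(j1 - 1) * nlon + i0, k] <- W[(j1 - 1) * nlon + i0, k] + (1 - fx) * fy
    W[(j1 - 1) * nlon + i1, k] <- W[(j1 - 1) * nlon + i1, k] + fx * fy
  }
  W
}

bracket <- function(coords, x) {
  n <- length(coords)
  lo <- findInterval(x, coords, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1), max(n - 1, 1))
  hi <- pmin(lo + 1, n)
  frac <- ifelse(hi == lo, 0, (x - coords[lo]) / (coords[hi] - coords[lo]))
  list(lo = lo, hi = hi, frac = pmin(pmax(frac, 0), 1))
}

#' Fit an empirical quantile map from simulated to observed temperatures
#'
#' For every cell, calendar month and variable (`tmin`, `tmax`), the
#' empirical quantiles of the observed and the simulated-historical pools
#' are computed at fixed probability levels (default percentiles 1-99),
#' pooling all years of the overlapping fitting period. The paired quantile
#' vectors define the correction transform used by [apply_eqm()].
#'
#' @param obs observed [daily_weather()].
#' @param sim_hist simulated [daily_weather()] on the same grid, overlapping
#'   the observed period (typically a scenario series whose historical
#'   segment overlaps the baseline years).
#' @param n_quantiles number of probability levels (`k/(n+1)`, k=1..n);
#'   default 99.
#' @return object of class `quantile_map`: arrays
#'   `obs_q`/`sim_q[n_quantiles, 12, n_cells, 2]` (vars tmin, tmax), the
#'   grid, probability levels and fitting metadata.
#' @export
fit_eqm <- function(obs, sim_hist, n_quantiles = 99) {
  stopifnot(inherits(obs, "daily_weather"), inherits(sim_hist, "daily_weather"))
  if (!same_grid(obs$grid, sim_hist$grid))
    stop("obs and sim_hist must be on the same grid")
  if (n_quantiles < 2) stop("n_quantiles must be >= 2")
  common <- as.Date(intersect(obs$dates, sim_hist$dates), origin = "1970-01-01")
  if (length(common) == 0) stop("no overlapping period to fit on")
  io <- match(common, obs$dates)
  is <- match(common, sim_hist$dates)
  mon <- as.POSIXlt(common)$mon + 1
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  nc <- n_cells(obs$grid)

  obs_q <- sim_q <- array(NA_real_, c(n_quantiles, 12, nc, 2),
                          dimnames = list(NULL, NULL, NULL, c("tmin", "tmax")))
  for (v in 1:2) {
    O <- if (v == 1) obs$tmin[io, , drop = FALSE] else obs$tmax[io, , drop = FALSE]
    S <- if (v == 1) sim_hist$tmin[is, , drop = FALSE] else sim_hist$tmax[is, , drop = FALSE]
    for (m in 1:12) {
      rows <- mon == m
      if (sum(rows) < 30)
        stop(sprintf("fewer than 30 days in month %d pool (var %s)",
                     m, c("tmin", "tmax")[v]))
      obs_q[, m, , v] <- apply(O[rows, , drop = FALSE], 2, quantile,
                               probs = probs, type = 7, names = FALSE)
      sim_q[, m, , v] <- apply(S[rows, , drop = FALSE], 2, quantile,
                               probs = probs, type = 7, names = FALSE)
    }
  }
  structure(list(grid = obs$grid, probs = probs, obs_q = obs_q, sim_q = sim_q,
                 meta = list(period = range(common), n_days = length(common),
                             n_quantiles = n_quantiles)),
            class = "quantile_map")
}

#' @export
print.quantile_map <- function(x, ...) {
  cat(sprintf("<quantile_map> %d levels x 12 months x %d cells x 2 vars; fitted on %s..%s (%d days)\n",
              length(x$probs), dim(x$obs_q)[3],
              format(x$meta$period[1]), format(x$meta$period[2]),
              x$meta$n_days))
  invisible(x)
}

#' Apply an empirical quantile map to a simulated series
#'
#' Every value is transformed by piecewise-linear interpolation between the
#' matched (simulated, observed) quantile pairs of its cell, calendar month
#' and variable. Values beyond the fitted range are shifted by the constant
#' offset at the outermost quantile (not clamped). The transform is monotone
#' non-decreasing; should a corrected `tmin`/`tmax` pair invert, it is
#' repaired by swapping and the count is reported via a message.
#'
#' @param map a `quantile_map` from [fit_eqm()].
#' @param sim_future a [daily_weather()] on the map's grid.
#' @return A bias-corrected [daily_weather()].
#' @export
apply_eqm <- function(map, sim_future) {
  stopifnot(inherits(map, "quantile_map"), inherits(sim_future, "daily_weather"))
  if (!same_grid(map$grid, sim_future$grid))
    stop("quantile map and series are on different grids")
  mon <- as.POSIXlt(sim_future$dates)$mon + 1
  nc <- n_cells(map$grid)
  tmin <- sim_future$tmin
  tmax <- sim_future$tmax
  for (cell in seq_len(nc)) {
    for (m in sort(unique(mon))) {
      rows <- mon == m
      tmin[rows, cell] <- eqm_transform(sim_future$tmin[rows, cell],
                                        map$sim_q[, m, cell, "tmin"],
                                        map$obs_q[, m, cell, "tmin"])
      tmax[rows, cell] <- eqm_transform(sim_future$tmax[rows, cell],
                                        map$sim_q[, m, cell, "tmax"],
                                        map$obs_q[, m, cell, "tmax"])
    }
  }
  inv <- tmin > tmax
  if (any(inv)) {
    message(sprintf("apply_eqm: %d corrected tmin/tmax pair(s) inverted; swapped", sum(inv)))
    tmp <- tmin[inv]; tmin[inv] <- tmax[inv]; tmax[inv] <- tmp
  }
  daily_weather(sim_future$grid, sim_future$dates, tmin, tmax,
                provenance = c(sim_future$provenance, list(corrected = TRUE)),
                meta = sim_future$meta)
}

# one cell/month/variable transform: piecewise linear inside the fitted
# quantile range, constant tail shift outside
eqm_transform <- function(x, sim_q, obs_q) {
  k <- length(sim_q)
  # collapse ties in the simulated quantiles (flat distributions)
  ux <- !duplicated(sim_q)
  sq <- sim_q[ux]
  oq <- vapply(split(obs_q, cumsum(ux)), mean, 0)
  if (length(sq) < 2) return(x + (mean(obs_q) - mean(sim_q)))
  out <- x
  lo <- x < sq[1]
  hi <- x > sq[length(sq)]
  mid <- !lo & !hi
  out[mid] <- approx(sq, oq, xout = x[mid], ties = "ordered")$y
  out[lo] <- x[lo] + (obs_q[1] - sim_q[1])
  out[hi] <- x[hi] + (obs_q[k] - sim_q[k])
  out
}
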