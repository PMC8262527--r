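#' Safe chill / safe forcing percentile index
#'
#' The safe index of a period is the 10th empirical percentile of the
#' annual seasonal totals within that period: the amount of chill (Safe
#' Winter Chill, from CP) or forcing (Safe Heat Forcing, from GDH) exceeded
#' in 90% of years. Percentiles use linear interpolation between order
#' statistics with plotting position `h = (n - 1) p + 1` (R's default
#' type 7). Cells with fewer than `min_seasons` seasons in the period are
#' returned as `NA` with a warning.
#'
#' @param totals a [seasonal_totals()] data.frame.
#' @param period integer length-2 vector `c(first, last)` of season-year
#'   labels (inclusive), or a single year vector.
#' @param level percentile level, default 0.1.
#' @param min_seasons minimum seasons per cell, default 5.
#' @return data.frame of class `safe_index`: `cell`, `lat`, `lon`, `value`,
#'   with attributes `variable`, `period` and `level`.
#' @examples
#' tot <- data.frame(cell = 1, lat = 40, lon = -8,
#'                   season_year = 1989:2005, variable = "CP",
#'                   value = 10:26)
#' safe_index(tot, c(1989, 2005))$value  # 11.6
#' @export
safe_index <- function(totals, period, level = 0.1, min_seasons = 5) {
  stopifnot(is.data.frame(totals),
            all(c("cell", "season_year", "value") %in% names(totals)))
  yrs <- if (length(period) == 2) seq(period[1], period[2]) else period
  sub <- totals[totals$season_year %in% yrs, , drop = FALSE]
  cells <- sort(unique(totals$cell))
  coords <- unique(totals[c("cell", "lat", "lon")])
  val <- rep(NA_real_, length(cells))
  short <- 0L
  for (i in seq_along(cells)) {
    v <- sub$value[sub$cell == cells[i]]
    v <- v[!is.na(v)]
    if (length(v) < min_seasons) { short <- short + 1L; next }
    val[i] <- quantile(v, level, type = 7, names = FALSE)
  }
  if (short > 0)
    warning(sprintf("%d cell(s) with fewer than %d seasons marked missing",
                    short, min_seasons))
  out <- merge(data.frame(cell = cells, value = val), coords, by = "cell")
  out <- out[order(out$cell), c("cell", "lat", "lon", "value")]
  rownames(out) <- NULL
  attr(out, "variable") <- if ("variable" %in% names(totals))
    unique(totals$variable)[1] else NA_character_
  attr(out, "period") <- range(yrs)
  attr(out, "level") <- level
  class(out) <- c("safe_index", "data.frame")
  out
}

#' Ensemble mean and spread across model members
#'
#' Arithmetic mean and population standard deviation (divide by n — the
#' members enumerate the ensemble) across model pairs, element-wise.
#'
#' @param members list of `safe_index` data.frames on identical geometry,
#'   or a numeric matrix with one column per member.
#' @return For fields: data.frame `cell`, `lat`, `lon`, `mean`, `sd`.
#'   For a matrix: list with `mean` and `sd` vectors.
#' @export
ensemble_stats <- function(members) {
  if (is.matrix(members)) {
    if (ncol(members) < 2) stop("need >= 2 ensemble members")
    return(list(mean = rowMeans(members), sd = row_sd_pop(members)))
  }
  stopifnot(is.list(members), length(members) >= 2)
  ref <- members[[1]]
  for (m in members[-1]) {
    if (nrow(m) != nrow(ref) || any(m$cell != ref$cell) ||
        any(abs(m$lat - ref$lat) > 1e-8) || any(abs(m$lon - ref$lon) > 1e-8))
      stop("ensemble members have mismatched geometry")
  }
  M <- do.call(cbind, lapply(members, function(m) m$value))
  data.frame(cell = ref$cell, lat = ref$lat, lon = ref$lon,
             mean = rowMeans(M), sd = row_sd_pop(M))
}

row_sd_pop <- function(M) {
  mu <- rowMeans(M)
  sqrt(rowMeans((M - mu)^2))
}

#' Ordinary-least-squares linear trend of regional annual series
#'
#' Fits `value ~ year` by OLS for each region in a tidy annual series
#' (typically the regional ensemble-mean index), returning the slope in
#' index units per year with fit diagnostics.
#'
#' @param annual data.frame with columns `region`, `year`, `value` (and
#'   optionally `scenario`, carried through).
#' @param years optional year range `c(first, last)` to restrict the fit.
#' @return data.frame: `region` (and `scenario`), `slope`, `intercept`,
#'   `slope_se`, `ci_lo`, `ci_hi` (95%), `n`, `resid_sd`.
#' @export
linear_trend <- function(annual, years = NULL) {
  stopifnot(all(c("region", "year", "value") %in% names(annual)))
  if (!is.null(years))
    annual <- annual[annual$year >= years[1] & annual$year <= years[2], ]
  keys <- unique(annual[intersect(c("region", "scenario"), names(annual))])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- annual$region == keys$region[i]
    if ("scenario" %in% names(keys))
      sel <- sel & annual$scenario == keys$scenario[i]
    d <- annual[sel & !is.na(annual$value), ]
    if (nrow(d) < 3) stop(sprintf("region %s: fewer than 3 non-missing years",
                                  keys$region[i]))
    fit <- lm(value ~ year, data = d)
    ci <- confint(fit)["year", ]
    cbind(keys[i, , drop = FALSE],
          data.frame(slope = unname(coef(fit)["year"]),
                     intercept = unname(coef(fit)["(Intercept)"]),
                     slope_se = summary(fit)$coefficients["year", "Std. Error"],
                     ci_lo = ci[1], ci_hi = ci[2],
                     n = nrow(d), resid_sd = summary(fit)$sigma))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cellwise change of an index field relative to baseline
#'
#' @param future,baseline `safe_index` data.frames on the same geometry.
#' @return data.frame `cell`, `lat`, `lon`, `delta` (future - baseline).
#' @export
change_map <- function(future, baseline) {
  if (nrow(future) != nrow(baseline) || any(future$cell != baseline$cell) ||
      any(abs(future$lat - baseline$lat) > 1e-8))
    stop("future and baseline fields have mismatched geometry")
  data.frame(cell = future$cell, lat = future$lat, lon = future$lon,
             delta = future$value - baseline$value)
}

#' The three future subperiods
#'
#' Short term 2021-2040, medium term 2041-2060, long term 2061-2080:
#' contiguous, disjoint 20-year ranges covering 2021-2080.
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
subperiods <- function() {
  data.frame(label = c("2021-2040", "2041-2060", "2061-2080"),
             start = c(2021L, 2041L, 2061L),
             end = c(2040L, 2060L, 2080L))
}
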