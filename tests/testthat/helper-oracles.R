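# Independent brute-force oracles: scalar step-by-step evaluations of the
# published model definitions, written separately from the package's
# vectorized/compiled paths. They intentionally share no code with R/.

oracle_cp <- function(temps, slp = 1.6, tetmlt = 277, a0 = 1.395e5,
                      a1 = 2.567e18, e0 = 4153.5, e1 = 12888.8) {
  x <- 0; portions <- 0
  cum <- numeric(length(temps))
  for (i in seq_along(temps)) {
    tk <- temps[i] + 273
    sr <- exp(slp * tetmlt * (tk - tetmlt) / tk)
    xi <- sr / (1 + sr)
    xs <- (a0 / a1) * exp((e1 - e0) / tk)
    ak1 <- a1 * exp(-e1 / tk)
    x <- xs - (xs - x) * exp(-ak1)
    if (x >= 1) {
      portions <- portions + xi * x
      x <- x * (1 - xi)
    }
    cum[i] <- portions
  }
  cum
}

oracle_gdh_hour <- function(T, Tb = 4, Tu = 25, Tc = 36, F = 1) {
  vapply(T, function(t) {
    if (t <= Tb || t >= Tc) return(0)
    if (t <= Tu)
      F * (Tu - Tb) / 2 * (1 + cos(pi + pi * (t - Tb) / (Tu - Tb)))
    else
      F * (Tu - Tb) * (1 + cos(pi / 2 + pi / 2 * (t - Tu) / (Tc - Tu)))
  }, 0)
}

oracle_gdh_sum <- function(temps, ...) sum(oracle_gdh_hour(temps, ...))

# scalar evaluation of the diurnal curve convention: sine from tmin at
# (rounded) sunrise to tmax at sunset - 3 h, logarithmic night decay to the
# next sunrise's tmin; self-padded series edges
oracle_hourly <- function(tmin, tmax, lat, doy) {
  n <- length(tmin)
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  dl <- 2 * acos(pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(decl)))) * 24 / (2 * pi)
  srh <- round(12 - dl / 2); ssh <- round(12 + dl / 2)
  peak <- pmax(srh + 1, ssh - 3)
  dayT <- function(d, h) {
    s <- sin(pi * (h - srh[d]) / (2 * (peak[d] - srh[d])))
    tmin[d] + (tmax[d] - tmin[d]) * max(0, s)
  }
  out <- numeric(n * 24)
  k <- 0
  for (d in seq_len(n)) {
    dp <- if (d == 1) 1 else d - 1
    dn <- if (d == n) n else d + 1
    for (h in 0:23) {
      k <- k + 1
      if (h < srh[d]) {
        tss <- dayT(dp, ssh[dp])
        out[k] <- tss - (tss - tmin[d]) *
          log(1 + h + 24 - ssh[dp]) / log(1 + srh[d] + 24 - ssh[dp])
      } else if (h <= ssh[d]) {
        out[k] <- dayT(d, h)
      } else {
        tss <- dayT(d, ssh[d])
        out[k] <- tss - (tss - tmin[dn]) *
          log(1 + h - ssh[d]) / log(1 + srh[dn] + 24 - ssh[d])
      }
    }
  }
  out
}
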