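# Independent oracles. Each reimplements a quantity by a different
# route than the package (different algorithm, brute force, or closed
# form) so that agreement is informative.

# --- Solar elevation, Michalsky (1988) Astronomical-Almanac algorithm.
# Entirely different series than the NOAA equations used by the package.
oracle_solar_elevation <- function(lat, lon, t) {
  delta <- as.numeric(t) / 86400 + 2440587.5 - 2451545
  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * pi / 180
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %%
               360) * pi / 180
  oblqec <- (23.439 - 0.0000004 * delta) * pi / 180
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  dec <- asin(sin(oblqec) * sin(eclong))
  hour_utc <- (as.numeric(t) %% 86400) / 3600
  delta0 <- delta - hour_utc / 24          # days since J2000 at 0h UT
  gmst <- (6.697375 + 0.0657098242 * delta0 + 1.00273790935 * hour_utc) %% 24
  lmst <- (gmst + lon / 15) * 15 * pi / 180
  ha <- lmst - ra
  el <- asin(sin(dec) * sin(lat * pi / 180) +
               cos(dec) * cos(lat * pi / 180) * cos(ha))
  el * 180 / pi
}

# Sunrise/sunset by minute scan + bisection on the -0.833 deg crossing.
oracle_sun_events <- function(lat, lon, date) {
  noon_utc <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - lon / 15 * 3600
  ts <- noon_utc + seq(-12 * 3600, 12 * 3600, by = 60)
  el <- oracle_solar_elevation(lat, lon, ts) + 0.833
  sgn <- sign(el)
  up <- which(diff(sgn) > 0)   # rising crossing
  dn <- which(diff(sgn) < 0)   # setting crossing
  stopifnot(length(up) >= 1, length(dn) >= 1)
  refine <- function(i) {
    a <- ts[i]; b <- ts[i + 1]
    for (k in 1:25) {
      m <- a + as.numeric(b - a, units = "secs") / 2
      if (sign(oracle_solar_elevation(lat, lon, m) + 0.833) ==
            sign(oracle_solar_elevation(lat, lon, a) + 0.833)) a <- m
      else b <- m
    }
    a + as.numeric(b - a, units = "secs") / 2
  }
  list(sunrise = refine(up[1]), sunset = refine(dn[1]))
}

# --- Dimensional-analysis flux oracle: ppm -> mole fraction, ideal-gas
# molar volume, headspace height, explicit unit factors.
oracle_flux <- function(dC_ppm, dt_h, vol_m3, area_m2, t_k, p_pa) {
  mol_per_m3_air <- p_pa / (8.314 * t_k)          # mol m-3
  mol_ch4 <- dC_ppm * 1e-6 * mol_per_m3_air * vol_m3   # mol
  mol_ch4 / area_m2 / dt_h * 1e6                  # umol m-2 h-1
}

# --- Exact two-sample rank-sum: enumerate all C(m+n, m) group
# assignments of the pooled ranks; one-sided P(W_day >= observed).
oracle_ranksum_p <- function(day, night) {
  pooled <- c(day, night)
  rk <- rank(pooled)
  m <- length(day)
  w_obs <- sum(rk[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  w_all <- apply(combs, 2, function(ix) sum(rk[ix]))
  mean(w_all >= w_obs - 1e-9)
}

# --- Exact one-sample signed-rank vs mu: enumerate all 2^n sign
# patterns; one-sided P(V >= observed).
oracle_signedrank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(as.matrix(signs), 1, function(s) sum(rk[s]))
  mean(v_all >= v_obs - 1e-9)
}

# --- Brute-force moving-window OLS slopes over all runs of `win`
# consecutive points; returns all slopes (hPa per hour).
oracle_window_slopes <- function(y, win = 4) {
  n <- length(y)
  if (n < win) return(numeric())
  vapply(seq_len(n - win + 1), function(i) {
    x <- 0:(win - 1)
    yy <- y[i:(i + win - 1)]
    sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  }, numeric(1))
}
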