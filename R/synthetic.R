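## Synthetic-data generator: a stated world with known ground truth.
##
## The generator emulates (a) a multiplicative diel flux pattern with a
## configurable day:night ratio, (b) lognormal AR(1) flux noise,
## (c) episodic ebullition as a marked Poisson process, (d) diel
## wind/PAR/pressure/temperature forcing with realistic magnitudes, and
## (e) the automated flux chamber (AFC) measurement process: closure
## cycles with minute-resolution sampling, 20-min flushing, and a raw
## sensor signal that is the inverse of the calibration model, so that
## calibration is exercised end to end. Manual chambers emit start/end
## grab samples over multi-hour deployments.

.R_GAS <- 8.314  # J mol-1 K-1

#' Chamber geometry and deployment mode
#'
#' @param chamber_id Character identifier.
#' @param depth_m Water depth at the mooring (m, > 0).
#' @param volume_m3,area_m2 Headspace volume (m3) and footprint area (m2);
#'   the ratio `volume_m3/area_m2` is the effective headspace height used
#'   in the ideal-gas flux conversion. Defaults give V/A = 0.1 m, typical
#'   of small floating chambers.
#' @param kind `"automated"` (minute-resolution sensor, closure cycles of
#'   roughly 0.4--3.1 h separated by 20-min flushes) or `"manual"` (grab
#'   samples at 2.9--8.9 h intervals).
#' @param closure_hours Length of one closed accumulation period (h).
#' @param flush_minutes Open flushing time between automated closures.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(chamber_id, depth_m, volume_m3 = 0.0075,
                         area_m2 = 0.075, kind = c("automated", "manual"),
                         closure_hours = NULL, flush_minutes = 20) {
  kind <- match.arg(kind)
  if (is.null(closure_hours))
    closure_hours <- if (kind == "automated") 1.5 else 6
  stopifnot(is.character(chamber_id), length(chamber_id) == 1,
            depth_m > 0, volume_m3 > 0, area_m2 > 0,
            closure_hours > 0, flush_minutes >= 0)
  structure(list(chamber_id = chamber_id, depth_m = depth_m,
                 volume_m3 = volume_m3, area_m2 = area_m2, kind = kind,
                 closure_hours = closure_hours,
                 flush_minutes = flush_minutes),
            class = "chamber_spec")
}

#' Lake location, season and chamber set
#'
#' @param lake_id Character identifier.
#' @param latitude,longitude Decimal degrees (lat in [-90, 90], lon in
#'   [-180, 180]); [sun_events()] additionally requires |lat| < 66.5.
#' @param utc_offset Local clock offset from UTC in hours.
#' @param season_label `"stratified"` or `"mixing"`.
#' @param chambers List of [chamber_spec()] objects (at least one).
#' @return An object of class `lake_config`.
#' @export
lake_config <- function(lake_id, latitude, longitude, utc_offset = 0,
                        season_label = c("stratified", "mixing"),
                        chambers = list()) {
  season_label <- match.arg(season_label)
  stopifnot(is.character(lake_id), length(lake_id) == 1,
            latitude >= -90, latitude <= 90,
            longitude >= -180, longitude <= 180,
            length(chambers) >= 1,
            all(vapply(chambers, inherits, logical(1), "chamber_spec")))
  ids <- vapply(chambers, `[[`, character(1), "chamber_id")
  if (anyDuplicated(ids)) stop("duplicate chamber_id within lake ", lake_id)
  structure(list(lake_id = lake_id, latitude = latitude,
                 longitude = longitude, utc_offset = utc_offset,
                 season_label = season_label, chambers = chambers),
            class = "lake_config")
}

.met_defaults <- function() {
  list(wind_mean = 3, wind_amp = 1.5, wind_peak_h = 14,
       wind_phi = 0.7, wind_ar_sd = 0.8,
       par_max = 1200, cloud_range = c(0.4, 1),
       press_mean = 1013, press_step_sd = 0.3,
       n_fronts = 0, front_slope = -1, front_duration_h = 6,
       airt_mean = 15, airt_amp = 4, airt_peak_h = 15, airt_ar_sd = 0.3,
       watert_mean = 16, watert_amp = 0.05, watert_peak_h = 16)
}

#' Simulation scenario: the stated world for all downstream stages
#'
#' Collects every generative parameter. The diffusive flux truth is
#' `F(t) = base_flux * m(t) * exp(sigma * Z(t))`, where `m(t)` equals
#' `r_true` inside the sun-up window and 1 at night (optionally smoothed
#' by half-sine ramps of width `ramp_width_h` around sunrise/sunset), and
#' `Z(t)` is a stationary unit-variance AR(1) process on the log scale.
#' Ebullition events arrive as a Poisson process per chamber with
#' exponentially distributed sizes and are superimposed as step releases.
#'
#' @param lakes List of [lake_config()] objects.
#' @param n_days Number of simulated days (>= 1).
#' @param r_true True day:night flux ratio (> 0).
#' @param base_flux Night-time diffusive flux level, umol m-2 h-1 (> 0).
#' @param flux_noise_sigma Log-scale SD of the multiplicative flux noise.
#' @param ar1_phi Lag-1-hour autocorrelation of the log-noise process.
#' @param ebullition_rate Events per chamber per day (>= 0).
#' @param ebullition_mean_size Mean event size, umol m-2 (> 0).
#' @param ambient_ch4 Mean background CH4 mole fraction, ppm.
#' @param rng_seed Integer seed; all generator stages derive their
#'   streams from it, so outputs are reproducible bit for bit.
#' @param start_date UTC date on which the simulation span begins.
#' @param ramp_width_h Width of the half-sine sunrise/sunset ramp on
#'   `m(t)`; 0 (default) keeps the square wave, for which the day:night
#'   ratio of the diffusive component is exactly `r_true`.
#' @param truth_dt_min Target width of truth intervals (minutes). The
#'   grid is re-fitted within each day and night window so that truth
#'   intervals never straddle a sunrise or sunset.
#' @param sensor_noise_sd SD of the additive white noise on the raw
#'   sensor signal (raw units).
#' @param cal_truth Named list `beta0` (ppm), `beta1` (ppm per raw unit),
#'   `beta2` (ppm per g m-3 absolute humidity): the true calibration of
#'   every simulated sensor; the emitted raw signal is its inverse.
#' @param ambient_diel_amp,ambient_ar_sd Diel amplitude (ppm) and AR(1)
#'   noise SD of the background CH4 series; the variation makes the
#'   3-parameter calibration regression identifiable.
#' @param met Named list of meteorology parameters overriding the
#'   defaults (see the package vignette for the full set and units).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(lakes, n_days = 30, r_true = 2.5, base_flux = 10,
                         flux_noise_sigma = 0.3, ar1_phi = 0.6,
                         ebullition_rate = 0.5, ebullition_mean_size = 50,
                         ambient_ch4 = 1.9, rng_seed = 1,
                         start_date = "2018-08-01", ramp_width_h = 0,
                         truth_dt_min = 5, sensor_noise_sd = 0.5,
                         cal_truth = list(beta0 = 0.2, beta1 = 0.01,
                                          beta2 = 0.02),
                         ambient_diel_amp = 0.1, ambient_ar_sd = 0.03,
                         met = list()) {
  if (inherits(lakes, "lake_config")) lakes <- list(lakes)
  stopifnot(length(lakes) >= 1,
            all(vapply(lakes, inherits, logical(1), "lake_config")))
  if (!is.numeric(r_true) || r_true <= 0) stop("r_true must be > 0")
  if (!is.numeric(base_flux) || base_flux <= 0) stop("base_flux must be > 0")
  if (n_days < 1) stop("n_days must be >= 1")
  if (flux_noise_sigma < 0 || ebullition_rate < 0)
    stop("rates and noise SDs must be non-negative")
  if (ebullition_mean_size <= 0) stop("ebullition_mean_size must be > 0")
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)")
  stopifnot(all(c("beta0", "beta1", "beta2") %in% names(cal_truth)),
            cal_truth$beta1 > 0)
  met_par <- utils::modifyList(.met_defaults(), met)
  structure(list(lakes = lakes, n_days = as.integer(n_days),
                 r_true = r_true, base_flux = base_flux,
                 flux_noise_sigma = flux_noise_sigma, ar1_phi = ar1_phi,
                 ebullition_rate = ebullition_rate,
                 ebullition_mean_size = ebullition_mean_size,
                 ambient_ch4 = ambient_ch4,
                 rng_seed = as.integer(rng_seed),
                 start_date = as.Date(start_date),
                 ramp_width_h = ramp_width_h,
                 truth_dt_min = truth_dt_min,
                 sensor_noise_sd = sensor_noise_sd,
                 cal_truth = cal_truth,
                 ambient_diel_amp = ambient_diel_amp,
                 ambient_ar_sd = ambient_ar_sd,
                 met = met_par),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  n_ch <- sum(vapply(x$lakes, function(l) length(l$chambers), integer(1)))
  cat("<sim_scenario> ", length(x$lakes), " lake(s), ", n_ch,
      " chamber(s), ", x$n_days, " days from ", format(x$start_date),
      "\n  r_true = ", x$r_true, ", base_flux = ", x$base_flux,
      " umol m-2 h-1, sigma = ", x$flux_noise_sigma,
      ", ebullition ", x$ebullition_rate, "/d x ",
      x$ebullition_mean_size, " umol m-2, seed = ", x$rng_seed, "\n",
      sep = "")
  invisible(x)
}

#' Reference two-lake, five-chamber scenario
#'
#' Two boreal/north-temperate lakes (58 and 64 degrees N) carrying five
#' automated chambers at depths spanning all four depth bins, 30 days in
#' late summer, day:night ratio 2.5, lognormal noise sigma 0.3 and
#' moderate ebullition. This is the configuration used by the package's
#' parameter-recovery acceptance checks.
#'
#' @param rng_seed Integer seed.
#' @param n_days Number of simulated days.
#' @param ... Further arguments passed to [sim_scenario()].
#' @return A [sim_scenario()] object.
#' @export
default_scenario <- function(rng_seed = 42, n_days = 30, ...) {
  south <- lake_config(
    "LKS", latitude = 58.0, longitude = 14.5, utc_offset = 2,
    season_label = "stratified",
    chambers = list(
      chamber_spec("LKS-C1", depth_m = 0.4, closure_hours = 1.5),
      chamber_spec("LKS-C2", depth_m = 0.9, closure_hours = 2.5),
      chamber_spec("LKS-C3", depth_m = 2.0, closure_hours = 1.0)))
  north <- lake_config(
    "LKN", latitude = 64.0, longitude = 19.0, utc_offset = 2,
    season_label = "mixing",
    chambers = list(
      chamber_spec("LKN-C1", depth_m = 1.2, closure_hours = 2.0),
      chamber_spec("LKN-C2", depth_m = 1.6, closure_hours = 0.8)))
  sim_scenario(list(south, north), n_days = n_days, rng_seed = rng_seed, ...)
}

#' Diel cycles for every lake of a scenario
#'
#' @param scenario A [sim_scenario()] object.
#' @return One [build_cycles()] table covering `n_days + 1` calendar days
#'   from `start_date`, stacked over lakes (so the span contains `n_days`
#'   complete sunrise-to-sunrise cycles per lake).
#' @export
scenario_cycles <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  t0 <- as.POSIXct(paste(scenario$start_date, "00:00:00"), tz = "UTC")
  t1 <- t0 + (scenario$n_days + 1) * 86400
  do.call(rbind, lapply(scenario$lakes, build_cycles, t0 = t0, t1 = t1))
}

## Truth grid for one lake: day and night windows subdivided into
## near-equal intervals of ~dt_min, with edges exactly at sunrise and
## sunset so no interval straddles a transition.
.truth_grid <- function(cycles_lake, dt_min) {
  pieces <- lapply(seq_len(nrow(cycles_lake)), function(i) {
    cy <- cycles_lake[i, ]
    seg <- function(a, b, day) {
      len_h <- as.numeric(b, units = "secs") / 3600 -
        as.numeric(a, units = "secs") / 3600
      k <- max(1L, round(len_h * 60 / dt_min))
      edges <- a + as.numeric(b - a, units = "secs") * (0:k) / k
      data.frame(t_start = edges[-(k + 1)], t_end = edges[-1],
                 is_day = day, cycle_index = cy$cycle_index)
    }
    rbind(seg(cy$sunrise, cy$sunset, TRUE),
          seg(cy$sunset, cy$next_sunrise, FALSE))
  })
  do.call(rbind, pieces)
}

## Diel modulation m(t) at interval midpoints; optional half-sine ramps.
.diel_modulation <- function(mid, is_day, cycles_lake, r, ramp_w) {
  m <- ifelse(is_day, r, 1)
  if (ramp_w <= 0) return(m)
  events <- sort(c(as.numeric(cycles_lake$sunrise),
                   as.numeric(cycles_lake$sunset),
                   as.numeric(cycles_lake$next_sunrise)))
  is_rise <- events %in% as.numeric(c(cycles_lake$sunrise,
                                      cycles_lake$next_sunrise))
  tm <- as.numeric(mid)
  idx <- findInterval(tm, events - ramp_w * 1800)
  near <- idx >= 1 & idx <= length(events) &
    tm < events[pmax(idx, 1)] + ramp_w * 1800
  if (any(near)) {
    ev <- events[idx[near]]
    rise <- is_rise[idx[near]]
    f <- 0.5 + 0.5 * sin(pi * (tm[near] - ev) / (ramp_w * 3600))
    f[!rise] <- 1 - f[!rise]
    m[near] <- 1 + (r - 1) * f
  }
  m
}

## Stationary unit-variance AR(1) sampled on an irregular grid: the
## step correlation is phi^(dt in hours).
.ar1_path <- function(dt_h, phi) {
  n <- length(dt_h)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    rho <- phi^dt_h[-n]
    eps <- stats::rnorm(n - 1)
    for (i in 2:n) z[i] <- rho[i - 1] * z[i - 1] +
        sqrt(1 - rho[i - 1]^2) * eps[i - 1]
  }
  z
}

#' Simulate the true flux series for every chamber
#'
#' Generates the diffusive truth `base_flux * m(t) * exp(sigma * Z(t))`
#' on a grid aligned to the day/night windows of `cycles`, draws
#' ebullition events from a Poisson process with exponential sizes, and
#' attributes each event to the truth interval containing it (as an
#' additional flux of `size / interval_h`). By construction the
#' duration-weighted day:night ratio of the diffusive component is
#' exactly `r_true` when `flux_noise_sigma = 0` and `ramp_width_h = 0`.
#'
#' @param scenario A [sim_scenario()].
#' @param cycles Cycle table from [scenario_cycles()] (or
#'   [build_cycles()]) covering the simulated span for every lake.
#' @return An object of class `truth_table`: a list with `flux` (one row
#'   per chamber per truth interval: `lake_id`, `chamber_id`,
#'   `cycle_index`, `t_start`, `t_end`, `is_day`, `diffusive_flux`,
#'   `ebullitive_flux`, `true_flux`, all fluxes in umol m-2 h-1) and
#'   `events` (`lake_id`, `chamber_id`, `time`, `size_umol_m2`). The
#'   cycle table is attached as attribute `"cycles"`.
#' @export
simulate_flux_truth <- function(scenario, cycles) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$r_true <= 0 || scenario$base_flux <= 0)
    stop("r_true and base_flux must be positive")
  if (!nrow(cycles)) stop("cycles must cover the simulated span")
  set.seed(scenario$rng_seed + 11L)
  flux_rows <- list(); event_rows <- list()
  for (lake in scenario$lakes) {
    cyl <- cycles[cycles$lake_id == lake$lake_id, ]
    if (!nrow(cyl)) stop("no cycles supplied for lake ", lake$lake_id)
    grid <- .truth_grid(cyl, scenario$truth_dt_min)
    dt_h <- as.numeric(grid$t_end - grid$t_start, units = "hours")
    mid <- grid$t_start + (grid$t_end - grid$t_start) / 2
    m <- .diel_modulation(mid, grid$is_day, cyl, scenario$r_true,
                          scenario$ramp_width_h)
    span_h <- as.numeric(cyl$next_sunrise[nrow(cyl)] - cyl$sunrise[1],
                         units = "hours")
    for (ch in lake$chambers) {
      z <- if (scenario$flux_noise_sigma > 0)
        .ar1_path(dt_h, scenario$ar1_phi) else numeric(nrow(grid))
      diff_flux <- scenario$base_flux * m *
        exp(scenario$flux_noise_sigma * z)
      eb_flux <- numeric(nrow(grid))
      n_ev <- stats::rpois(1, scenario$ebullition_rate * span_h / 24)
      if (n_ev > 0) {
        ev_t <- cyl$sunrise[1] + sort(stats::runif(n_ev)) * span_h * 3600
        ev_s <- stats::rexp(n_ev, rate = 1 / scenario$ebullition_mean_size)
        slot <- findInterval(as.numeric(ev_t), as.numeric(grid$t_start))
        ok <- slot >= 1 & slot <= nrow(grid)
        for (j in which(ok))
          eb_flux[slot[j]] <- eb_flux[slot[j]] + ev_s[j] / dt_h[slot[j]]
        event_rows[[length(event_rows) + 1]] <- data.frame(
          lake_id = lake$lake_id, chamber_id = ch$chamber_id,
          time = ev_t[ok], size_umol_m2 = ev_s[ok])
      }
      flux_rows[[length(flux_rows) + 1]] <- data.frame(
        lake_id = lake$lake_id, chamber_id = ch$chamber_id,
        cycle_index = grid$cycle_index, t_start = grid$t_start,
        t_end = grid$t_end, is_day = grid$is_day,
        diffusive_flux = diff_flux, ebullitive_flux = eb_flux,
        true_flux = diff_flux + eb_flux)
    }
  }
  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(lake_id = character(), chamber_id = character(),
               time = as.POSIXct(character(), tz = "UTC"),
               size_umol_m2 = numeric())
  structure(list(flux = do.call(rbind, flux_rows), events = events),
            class = "truth_table", cycles = cycles)
}

#' Simulate hourly meteorological forcing per lake
#'
#' Wind is a diel sinusoid peaking in the early afternoon plus AR(1)
#' noise, floored at zero; PAR is a clear-sky half-sine over the daylight
#' window scaled by a per-day cloud factor and exactly zero at night;
#' pressure is a slow random walk around its mean with optional frontal
#' drop events; air temperature is a diel sinusoid with small AR(1)
#' noise; water temperature is a near-constant diel sinusoid whose
#' day:night ratio stays within roughly 0.997--1.006.
#'
#' @inheritParams simulate_flux_truth
#' @return Hourly `data.frame`: `lake_id`, `timestamp` (UTC),
#'   `air_temp_c`, `pressure_hpa`, `wind10_ms`, `par_umol_m2_s`,
#'   `water_temp_c`.
#' @export
simulate_met <- function(scenario, cycles) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$rng_seed + 22L)
  p <- scenario$met
  out <- list()
  for (lake in scenario$lakes) {
    cyl <- cycles[cycles$lake_id == lake$lake_id, ]
    t0 <- as.POSIXct(trunc(cyl$sunrise[1] - 3600, units = "hours"), tz = "UTC")
    t1 <- as.POSIXct(trunc(cyl$next_sunrise[nrow(cyl)] + 7200,
                           units = "hours"), tz = "UTC")
    ts <- seq(t0, t1, by = 3600)
    n <- length(ts)
    h_loc <- (as.numeric(ts) / 3600 + lake$utc_offset) %% 24
    wind <- pmax(0, p$wind_mean +
                   p$wind_amp * cos(2 * pi * (h_loc - p$wind_peak_h) / 24) +
                   p$wind_ar_sd * .ar1_path(rep(1, n), p$wind_phi))
    ## PAR: locate each hour stamp within its diel cycle
    idx <- findInterval(as.numeric(ts), as.numeric(cyl$sunrise))
    par <- numeric(n)
    cloud_day <- stats::runif(length(unique(as.Date(ts))),
                              p$cloud_range[1], p$cloud_range[2])
    names(cloud_day) <- as.character(unique(as.Date(ts)))
    inside <- idx >= 1 & idx <= nrow(cyl)
    ii <- which(inside)
    lit <- ii[ts[ii] < cyl$sunset[idx[ii]]]
    if (length(lit)) {
      frac <- as.numeric(ts[lit] - cyl$sunrise[idx[lit]], units = "hours") /
        cyl$light_period_h[idx[lit]]
      par[lit] <- p$par_max * sin(pi * frac) *
        cloud_day[as.character(as.Date(ts[lit]))]
    }
    press <- p$press_mean + cumsum(stats::rnorm(n, 0, p$press_step_sd))
    if (p$n_fronts > 0) {
      starts <- sort(stats::runif(p$n_fronts, 0, n - p$front_duration_h))
      for (s in starts) {
        drop <- p$front_slope * pmin(pmax(seq_len(n) - s, 0),
                                     p$front_duration_h)
        press <- press + drop
      }
    }
    airt <- p$airt_mean + p$airt_amp * cos(2 * pi * (h_loc - p$airt_peak_h) / 24) +
      p$airt_ar_sd * .ar1_path(rep(1, n), 0.8)
    watert <- p$watert_mean +
      p$watert_amp * cos(2 * pi * (h_loc - p$watert_peak_h) / 24)
    out[[lake$lake_id]] <- data.frame(
      lake_id = lake$lake_id, timestamp = ts, air_temp_c = airt,
      pressure_hpa = press, wind10_ms = wind, par_umol_m2_s = par,
      water_temp_c = watert)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Absolute humidity from relative humidity and temperature
#'
#' Uses the Magnus saturation-vapour-pressure formula
#' `e_s = 6.112 exp(17.62 T / (243.12 + T))` hPa and the ideal-gas
#' density of water vapour.
#'
#' @param rh_pct Relative humidity, percent.
#' @param temp_c Air temperature, degrees Celsius.
#' @return Absolute humidity in g m-3.
#' @export
absolute_humidity <- function(rh_pct, temp_c) {
  es <- 6.112 * exp(17.62 * temp_c / (243.12 + temp_c))  # hPa
  216.68 * (rh_pct / 100) * es / (temp_c + 273.15)
}

## Background CH4 series (ppm) on an hourly grid for one lake; slight
## diel cycle plus AR(1) noise makes the calibration fit identifiable.
.ambient_series <- function(scenario, lake, ts) {
  h_loc <- (as.numeric(ts) / 3600 + lake$utc_offset) %% 24
  scenario$ambient_ch4 +
    scenario$ambient_diel_amp * 0.5 * cos(2 * pi * (h_loc - 5) / 24) +
    scenario$ambient_ar_sd * .ar1_path(rep(1, length(ts)), 0.8)
}

#' Render chamber sensor records from the flux truth
#'
#' Turns the true flux series into per-chamber measurement records.
#' Within each closed period the headspace concentration grows at
#' `slope [ppm/h] = F * R * T / (P * (V/A))` (ideal gas, R = 8.314,
#' T headspace temperature in K, P ambient pressure in Pa, V/A the
#' chamber height in m); ebullition events appear as instantaneous
#' concentration steps `dC = size * R * T / (P * (V/A))` when the
#' chamber is closed (bubbles reaching an open chamber escape). During
#' flushing the concentration relaxes exponentially to the background
#' series. The emitted raw signal is the inverse of the true calibration
#' model plus white noise, so calibration is exercised end to end.
#' Manual chambers emit only start/end grab samples per deployment.
#'
#' @param truth A `truth_table` from [simulate_flux_truth()].
#' @param scenario The [sim_scenario()] that generated it.
#' @param met Hourly meteorology from [simulate_met()] (supplies
#'   headspace temperature and ambient pressure).
#' @param flush_tau_min Time constant (minutes) of the flushing
#'   relaxation.
#' @return A list with `sensors` (named list of per-chamber data frames
#'   with columns `lake_id`, `chamber_id`, `timestamp`, `raw_signal`,
#'   `ch4_ppm_true`, `rh_pct`, `temp_c`, `state`, each carrying its
#'   `chamber_spec` as attribute `"chamber"`) and `ambient` (per-lake
#'   hourly background CH4, ppm).
#' @export
render_sensor_records <- function(truth, scenario, met,
                                  flush_tau_min = 1.5) {
  stopifnot(inherits(truth, "truth_table"),
            inherits(scenario, "sim_scenario"))
  cycles <- attr(truth, "cycles")
  set.seed(scenario$rng_seed + 33L)
  cal <- scenario$cal_truth
  sensors <- list(); ambient <- list()
  for (lake in scenario$lakes) {
    cyl <- cycles[cycles$lake_id == lake$lake_id, ]
    ml <- met[met$lake_id == lake$lake_id, ]
    t0 <- as.POSIXct(ceiling(as.numeric(cyl$sunrise[1]) / 60) * 60,
                     tz = "UTC", origin = "1970-01-01")
    t1 <- as.POSIXct(floor(as.numeric(cyl$next_sunrise[nrow(cyl)]) / 60) * 60,
                     tz = "UTC", origin = "1970-01-01")
    amb_h <- .ambient_series(scenario, lake, ml$timestamp)
    ambient[[lake$lake_id]] <- data.frame(
      lake_id = lake$lake_id, timestamp = ml$timestamp, ch4_ppm = amb_h)
    for (ci in seq_along(lake$chambers)) {
      ch <- lake$chambers[[ci]]
      tf <- truth$flux[truth$flux$chamber_id == ch$chamber_id, ]
      ev <- truth$events[truth$events$chamber_id == ch$chamber_id, ]
      voa <- ch$volume_m3 / ch$area_m2
      if (ch$kind == "automated") {
        ts <- seq(t0, t1, by = 60)
        n <- length(ts)
        tn <- as.numeric(ts)
        amb <- stats::approx(as.numeric(ml$timestamp), amb_h, tn,
                             rule = 2)$y
        temp_c <- stats::approx(as.numeric(ml$timestamp), ml$air_temp_c,
                                tn, rule = 2)$y
        p_pa <- stats::approx(as.numeric(ml$timestamp), ml$pressure_hpa,
                              tn, rule = 2)$y * 100
        h_loc <- (tn / 3600 + lake$utc_offset) %% 24
        rh <- pmin(100, pmax(30, 80 + 10 * cos(2 * pi * (h_loc - 5) / 24) +
                               stats::rnorm(n, 0, 2)))
        slot <- findInterval(tn, as.numeric(tf$t_start))
        slot <- pmin(pmax(slot, 1L), nrow(tf))
        slope <- tf$diffusive_flux[slot] * .R_GAS * (temp_c + 273.15) /
          (p_pa * voa)                                  # ppm per hour
        period_min <- ch$closure_hours * 60 + ch$flush_minutes
        phase <- ((tn - tn[1]) / 60 + (ci - 1) * 7) %% period_min
        closed <- phase < ch$closure_hours * 60
        step <- numeric(n)
        if (nrow(ev)) {
          ei <- findInterval(as.numeric(ev$time), tn) + 1L
          ok <- ei >= 1 & ei <= n
          dC <- ev$size_umol_m2 * .R_GAS * (temp_c[pmin(ei, n)] + 273.15) /
            (p_pa[pmin(ei, n)] * voa)
          for (j in which(ok)) if (closed[ei[j]])
            step[ei[j]] <- step[ei[j]] + dC[j]
        }
        conc <- numeric(n)
        runs <- rle(closed)
        ends <- cumsum(runs$lengths)
        starts <- c(1L, utils::head(ends, -1) + 1L)
        c_prev <- amb[1]
        for (k in seq_along(runs$lengths)) {
          i0 <- starts[k]; i1 <- ends[k]
          if (runs$values[k]) {          # closed: accumulate
            inc <- if (i1 > i0)
              c(0, cumsum(slope[i0:(i1 - 1)] / 60)) else 0
            stp <- if (i1 > i0)
              cumsum(c(0, step[(i0 + 1):i1])) else 0
            conc[i0:i1] <- c_prev + inc + stp
          } else {                       # open: relax to ambient
            decay <- exp(-(seq_len(i1 - i0 + 1)) / flush_tau_min)
            conc[i0:i1] <- amb[i0:i1] + (c_prev - amb[i0:i1]) * decay
          }
          c_prev <- conc[i1]
        }
        ah <- absolute_humidity(rh, temp_c)
        raw <- (conc - cal$beta0 - cal$beta2 * ah) / cal$beta1 +
          stats::rnorm(n, 0, scenario$sensor_noise_sd)
        df <- data.frame(lake_id = lake$lake_id, chamber_id = ch$chamber_id,
                         timestamp = ts, raw_signal = raw,
                         ch4_ppm_true = conc, rh_pct = rh, temp_c = temp_c,
                         state = ifelse(closed, "closed", "open"))
      } else {                           # manual chamber: grab samples
        dep0 <- seq(t0, t1 - ch$closure_hours * 3600,
                    by = (ch$closure_hours + 1 / 6) * 3600)
        rows <- list()
        for (d0 in dep0) {
          d0 <- as.POSIXct(d0, tz = "UTC", origin = "1970-01-01")
          d1 <- d0 + ch$closure_hours * 3600
          ov <- .overlap_h(tf$t_start, tf$t_end, d0, d1)
          midn <- as.numeric(tf$t_start) +
            as.numeric(tf$t_end - tf$t_start, units = "secs") / 2
          tmid <- stats::approx(as.numeric(ml$timestamp), ml$air_temp_c,
                                midn, rule = 2)$y + 273.15
          pmid <- stats::approx(as.numeric(ml$timestamp), ml$pressure_hpa,
                                midn, rule = 2)$y * 100
          dC <- sum(tf$diffusive_flux * ov * .R_GAS * tmid / (pmid * voa))
          if (nrow(ev)) {
            ine <- ev$time > d0 & ev$time <= d1
            if (any(ine)) {
              te <- stats::approx(as.numeric(ml$timestamp), ml$air_temp_c,
                                  as.numeric(ev$time[ine]), rule = 2)$y + 273.15
              pe <- stats::approx(as.numeric(ml$timestamp), ml$pressure_hpa,
                                  as.numeric(ev$time[ine]), rule = 2)$y * 100
              dC <- dC + sum(ev$size_umol_m2[ine] * .R_GAS * te / (pe * voa))
            }
          }
          c0 <- stats::approx(as.numeric(ml$timestamp), amb_h,
                              as.numeric(d0), rule = 2)$y
          tc <- stats::approx(as.numeric(ml$timestamp), ml$air_temp_c,
                              as.numeric(c(d0, d1)), rule = 2)$y
          rows[[length(rows) + 1]] <- data.frame(
            lake_id = lake$lake_id, chamber_id = ch$chamber_id,
            timestamp = c(d0, d1), raw_signal = NA_real_,
            ch4_ppm_true = c(c0, c0 + dC),
            rh_pct = 80, temp_c = tc, state = "closed")
        }
        df <- do.call(rbind, rows)
      }
      attr(df, "chamber") <- ch
      sensors[[ch$chamber_id]] <- df
    }
  }
  list(sensors = sensors,
       ambient = do.call(rbind, c(ambient, list(make.row.names = FALSE))))
}
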