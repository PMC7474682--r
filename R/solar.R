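## Solar geometry and diel-cycle segmentation.
##
## Sunrise/sunset are computed from the NOAA solar-position equations
## (solar declination, equation of time, hour angle at -0.833 deg solar
## elevation, i.e. standard refraction plus the solar radius). All
## timestamps are UTC POSIXct; UTC offsets are only used when reporting
## local clock hours.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## Julian day number for a UTC POSIXct (fractional).
.julian_day <- function(t) {
  as.numeric(t, units = "secs") / 86400 + 2440587.5
}

#' Sunrise and sunset times from the NOAA solar equations
#'
#' Computes sunrise and sunset (solar elevation crossing -0.833 degrees)
#' for one or more calendar dates at a single location, using the NOAA
#' solar-position equations (geometric mean longitude/anomaly of the sun,
#' equation of centre, apparent longitude, corrected obliquity, solar
#' declination and the equation of time), evaluated at local solar noon.
#' Accuracy is within about one minute of reference ephemerides for
#' latitudes below the polar circles.
#'
#' @param latitude Latitude in decimal degrees, positive north. Must lie
#'   strictly within (-66.5, 66.5): polar day/night is unsupported.
#' @param longitude Longitude in decimal degrees, positive east.
#' @param date `Date` vector (or coercible) of UTC calendar dates.
#' @param utc_offset Hours added to UTC to obtain local clock time. Only
#'   stored for downstream reporting; the returned times are UTC.
#'
#' @return A `data.frame` with one row per date: `date`, `sunrise`,
#'   `sunset` (POSIXct, UTC), `light_period_h` (hours) and `utc_offset`.
#'
#' @examples
#' sun_events(0, 0, as.Date("2019-03-21"))   # equinox at the equator
#' sun_events(58, 14.5, as.Date("2018-08-01"), utc_offset = 2)
#' @export
sun_events <- function(latitude, longitude, date, utc_offset = 0) {
  stopifnot(length(latitude) == 1, length(longitude) == 1)
  if (!is.finite(latitude) || abs(latitude) >= 66.5)
    stop("unsupported latitude ", latitude,
         ": polar day/night can occur at |latitude| >= 66.5 degrees")
  if (!is.finite(longitude) || abs(longitude) > 180)
    stop("longitude out of range [-180, 180]")
  date <- as.Date(date)

  ## evaluate solar parameters at the approximate local solar noon
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  t_noon <- midnight + (720 - 4 * longitude) * 60
  jc <- (.julian_day(t_noon) - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(.deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(.deg2rad(3 * gma)) * 0.000289
  true_long <- gml + ctr
  app_long <- true_long - 0.00569 - 0.00478 * sin(.deg2rad(125.04 - 1934.136 * jc))
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(.deg2rad(125.04 - 1934.136 * jc))
  decl <- asin(sin(.deg2rad(obliq)) * sin(.deg2rad(app_long)))

  vary <- tan(.deg2rad(obliq / 2))^2
  eqtime <- 4 * .rad2deg(
    vary * sin(2 * .deg2rad(gml)) -
      2 * ecc * sin(.deg2rad(gma)) +
      4 * ecc * vary * sin(.deg2rad(gma)) * cos(2 * .deg2rad(gml)) -
      0.5 * vary^2 * sin(4 * .deg2rad(gml)) -
      1.25 * ecc^2 * sin(2 * .deg2rad(gma)))     # minutes

  lat_r <- .deg2rad(latitude)
  cos_ha <- cos(.deg2rad(90.833)) / (cos(lat_r) * cos(decl)) -
    tan(lat_r) * tan(decl)
  if (any(abs(cos_ha) > 1))
    stop("polar day or night on ", paste(format(date[abs(cos_ha) > 1]),
                                         collapse = ", "),
         " at latitude ", latitude, " degrees: unsupported")
  ha_min <- 4 * .rad2deg(acos(cos_ha))           # half day length, minutes
  noon_min <- 720 - 4 * longitude - eqtime       # solar noon, minutes UTC

  sunrise <- midnight + (noon_min - ha_min) * 60
  sunset <- midnight + (noon_min + ha_min) * 60
  data.frame(date = date, sunrise = sunrise, sunset = sunset,
             light_period_h = as.numeric(sunset - sunrise, units = "hours"),
             utc_offset = utc_offset)
}

#' Segment a time span into sunrise-to-sunrise diel cycles
#'
#' Each diel cycle starts at one sunrise and ends at the next day's
#' sunrise, so its day window is `[sunrise, sunset]` and its night window
#' `[sunset, next_sunrise]`. Consecutive cycles tile the timeline with no
#' gap or overlap, and the light-period length varies with the lake's
#' latitude and the season, as it does in the field.
#'
#' @param lake A [lake_config()] object (uses `latitude`, `longitude`,
#'   `utc_offset`, `lake_id`).
#' @param t0,t1 POSIXct (UTC) bounds of the span to cover. Cycles run from
#'   the first sunrise at or after `t0` to the last sunrise at or before
#'   `t1`.
#'
#' @return A `data.frame` with columns `lake_id`, `cycle_index`,
#'   `sunrise`, `sunset`, `next_sunrise` (POSIXct UTC), `light_period_h`
#'   and `utc_offset`; zero rows (with a warning) if the span is shorter
#'   than one full cycle.
#' @export
build_cycles <- function(lake, t0, t1) {
  stopifnot(inherits(lake, "lake_config"))
  t0 <- as.POSIXct(t0, tz = "UTC"); t1 <- as.POSIXct(t1, tz = "UTC")
  if (t1 <= t0) stop("t1 must be after t0")
  dates <- seq(as.Date(t0) - 1, as.Date(t1) + 1, by = "day")
  ev <- sun_events(lake$latitude, lake$longitude, dates, lake$utc_offset)
  ev <- ev[order(ev$sunrise), ]
  keep <- ev$sunrise >= t0 & ev$sunrise <= t1
  idx <- which(keep)
  if (length(idx) < 2) {
    warning("span [", format(t0), ", ", format(t1),
            "] contains fewer than one full diel cycle")
    return(data.frame(lake_id = character(), cycle_index = integer(),
                      sunrise = as.POSIXct(character(), tz = "UTC"),
                      sunset = as.POSIXct(character(), tz = "UTC"),
                      next_sunrise = as.POSIXct(character(), tz = "UTC"),
                      light_period_h = numeric(), utc_offset = numeric()))
  }
  n <- length(idx) - 1
  out <- data.frame(
    lake_id = rep(lake$lake_id, n),
    cycle_index = seq_len(n),
    sunrise = ev$sunrise[idx[seq_len(n)]],
    sunset = ev$sunset[idx[seq_len(n)]],
    next_sunrise = ev$sunrise[idx[seq_len(n) + 1]],
    light_period_h = ev$light_period_h[idx[seq_len(n)]],
    utc_offset = rep(lake$utc_offset, n))
  stopifnot(all(out$sunrise < out$sunset),
            all(out$sunset < out$next_sunrise))
  out
}

## Overlap in hours between intervals [a0,a1] and [b0,b1] (vectorised).
.overlap_h <- function(a0, a1, b0, b1) {
  pmax(0, as.numeric(pmin(as.numeric(a1), as.numeric(b1)) -
                       pmax(as.numeric(a0), as.numeric(b0))) / 3600)
}

#' Split flux intervals into day and night overlap hours
#'
#' Attributes each measurement interval `[t_start, t_end]` to the day
#' window `[sunrise, sunset]` and night window `[sunset, next_sunrise]`
#' of every diel cycle it overlaps, proportionally by overlap duration.
#' Proportional splitting conserves total flux-time: for an interval
#' wholly inside one cycle, `day_overlap_h + night_overlap_h` equals its
#' duration.
#'
#' @param fluxes `data.frame` with POSIXct columns `t_start`, `t_end`
#'   (e.g. the output of [compute_afc_flux()]).
#' @param cycles Diel cycle table from [build_cycles()].
#'
#' @return A `data.frame` with one row per (flux, overlapping cycle)
#'   pair: all columns of `fluxes` plus `cycle_index`, `day_overlap_h`,
#'   `night_overlap_h` and `light_period_h`.
#' @export
assign_day_night <- function(fluxes, cycles) {
  stopifnot(all(c("t_start", "t_end") %in% names(fluxes)))
  pieces <- lapply(seq_len(nrow(cycles)), function(i) {
    cy <- cycles[i, ]
    d <- .overlap_h(fluxes$t_start, fluxes$t_end, cy$sunrise, cy$sunset)
    n <- .overlap_h(fluxes$t_start, fluxes$t_end, cy$sunset, cy$next_sunrise)
    hit <- d + n > 0
    if (!any(hit)) return(NULL)
    out <- fluxes[hit, , drop = FALSE]
    out$cycle_index <- cy$cycle_index
    out$day_overlap_h <- d[hit]
    out$night_overlap_h <- n[hit]
    out$light_period_h <- cy$light_period_h
    out
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    out <- fluxes[0, , drop = FALSE]
    out$cycle_index <- integer()
    out$day_overlap_h <- numeric()
    out$night_overlap_h <- numeric()
    out$light_period_h <- numeric()
    return(out)
  }
  do.call(rbind, pieces)
}
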