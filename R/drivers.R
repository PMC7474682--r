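## Candidate-driver diagnostics: day:night ratios of wind, water
## temperature, water-air temperature difference and PAR; maximum
## atmospheric pressure drops from moving 4-h regressions; and the
## concordance of diel wind and flux patterns. Correlations are Spearman
## by default: flux ratios are heavy-tailed because of ebullition, and
## rank correlation is robust to those outliers.

## Duration-weighted mean of an hourly series over a window [a, b].
## Each hourly value represents the hour starting at its timestamp.
.window_mean <- function(ts, x, a, b) {
  w <- .overlap_h(ts, ts + 3600, a, b)
  keep <- w > 0 & !is.na(x)
  if (!any(keep)) return(c(mean = NA_real_, hours = 0))
  c(mean = sum(x[keep] * w[keep]) / sum(w[keep]), hours = sum(w[keep]))
}

#' Maximum pressure drop from moving 4-h regressions
#'
#' Fits an ordinary least-squares slope to every run of
#' `window_h` consecutive hourly pressure points (moving step 1 h) and
#' returns the most negative slope, or `NA` if no window slope is
#' negative (or fewer than `window_h` points are available).
#'
#' @param pressure `data.frame` with `timestamp` (hourly POSIXct) and
#'   `pressure_hpa`.
#' @param window_h Window length in hours (and points), default 4.
#' @return Slope in hPa per hour (<= 0), or `NA_real_` with attribute
#'   `"flag"` set to `"no_negative_slope"` or `"too_few_points"`.
#' @export
max_pressure_drop <- function(pressure, window_h = 4) {
  n <- nrow(pressure)
  if (is.null(n) || n < window_h)
    return(structure(NA_real_, flag = "too_few_points"))
  o <- order(pressure$timestamp)
  y <- pressure$pressure_hpa[o]
  th <- as.numeric(pressure$timestamp[o]) / 3600
  slopes <- vapply(seq_len(n - window_h + 1), function(i) {
    idx <- i:(i + window_h - 1)
    ## require a contiguous hourly run
    if (th[idx[window_h]] - th[idx[1]] > window_h - 1 + 1e-6)
      return(NA_real_)
    x <- th[idx]
    stats::cov(x, y[idx]) / stats::var(x)
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes))
    return(structure(NA_real_, flag = "too_few_points"))
  m <- min(slopes)
  if (m >= 0) return(structure(NA_real_, flag = "no_negative_slope"))
  m
}

#' Day/night driver summaries per diel cycle
#'
#' For every diel cycle, computes duration-weighted day and night means
#' of wind speed, water temperature, the water-air temperature
#' difference (dT = water - air, positive when the water is warmer,
#' i.e. convection-favourable) and PAR, plus the maximum 4-h pressure
#' drop within each window. Ratios are day/night; the PAR ratio is left
#' undefined (night PAR is zero) and the day mean reported instead.
#'
#' @param met Hourly meteorology table ([simulate_met()] schema).
#' @param cycles Diel-cycle table from [build_cycles()].
#' @param min_coverage Minimum fraction of a window that must be covered
#'   by met hours; below it the summary is flagged incomplete.
#' @return `data.frame` per lake and cycle: wind/water-temperature day
#'   and night means and ratios, `deltaT_day`, `deltaT_night`,
#'   `par_day_mean`, `pressure_drop_day`, `pressure_drop_night`,
#'   `pressure_drop_ratio` (day/night, both drops negative), `complete`.
#' @export
driver_day_night_ratios <- function(met, cycles, min_coverage = 0.5) {
  rows <- list()
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    ml <- met[met$lake_id == cy$lake_id, ]
    ts <- ml$timestamp
    win <- function(x, a, b) .window_mean(ts, x, a, b)
    d <- list(wind = win(ml$wind10_ms, cy$sunrise, cy$sunset),
              wt = win(ml$water_temp_c, cy$sunrise, cy$sunset),
              at = win(ml$air_temp_c, cy$sunrise, cy$sunset),
              par = win(ml$par_umol_m2_s, cy$sunrise, cy$sunset))
    n <- list(wind = win(ml$wind10_ms, cy$sunset, cy$next_sunrise),
              wt = win(ml$water_temp_c, cy$sunset, cy$next_sunrise),
              at = win(ml$air_temp_c, cy$sunset, cy$next_sunrise))
    day_h <- cy$light_period_h
    night_h <- as.numeric(cy$next_sunrise - cy$sunset, units = "hours")
    complete <- d$wind["hours"] >= min_coverage * day_h &&
      n$wind["hours"] >= min_coverage * night_h
    pday <- max_pressure_drop(
      ml[ml$timestamp >= cy$sunrise - 3600 & ml$timestamp < cy$sunset,
         c("timestamp", "pressure_hpa")])
    pnight <- max_pressure_drop(
      ml[ml$timestamp >= cy$sunset - 3600 & ml$timestamp < cy$next_sunrise,
         c("timestamp", "pressure_hpa")])
    rows[[i]] <- data.frame(
      lake_id = cy$lake_id, cycle_index = cy$cycle_index,
      light_period_h = cy$light_period_h,
      wind_day = d$wind["mean"], wind_night = n$wind["mean"],
      wind_ratio = d$wind["mean"] / n$wind["mean"],
      watertemp_ratio = d$wt["mean"] / n$wt["mean"],
      deltaT_day = d$wt["mean"] - d$at["mean"],
      deltaT_night = n$wt["mean"] - n$at["mean"],
      par_day_mean = d$par["mean"],
      pressure_drop_day = as.numeric(pday),
      pressure_drop_night = as.numeric(pnight),
      pressure_drop_ratio = if (is.finite(pday) && is.finite(pnight))
        pday / pnight else NA_real_,
      complete = complete)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

## Mean FL_R per lake and cycle (across units), used to pair driver
## summaries (one per cycle) with flux ratios (one per unit and cycle).
.flr_by_cycle <- function(flr) {
  agg <- stats::aggregate(FL_R ~ lake_id + cycle_index,
                          data = flr[is.finite(flr$FL_R), ], FUN = mean)
  names(agg)[names(agg) == "FL_R"] <- "FL_R_mean"
  agg
}

#' Pressure-drop vs FL_R on wind-neutral cycles
#'
#' Isolates the pressure signal from the wind signal: keeps cycles with
#' a negative 4-h pressure drop in both the day and the night window
#' AND a day:night wind ratio inside `wind_band` (similar wind in both
#' periods), then correlates the day:night pressure-drop ratio with the
#' cycle-mean FL_R (Spearman by default).
#'
#' @param summaries Output of [driver_day_night_ratios()].
#' @param flr FL_R table from [compute_flr()].
#' @param wind_band Inclusive day:night wind-ratio band, default
#'   `c(0.7, 1.3)`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `table` (the filtered, paired cycles), `n`, `rho`,
#'   `p_value` (`NA` when the subset is empty or degenerate).
#' @export
pressure_ratio_subset <- function(summaries, flr,
                                  wind_band = c(0.7, 1.3),
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- is.finite(summaries$pressure_drop_day) &
    is.finite(summaries$pressure_drop_night) &
    summaries$pressure_drop_day < 0 & summaries$pressure_drop_night < 0 &
    is.finite(summaries$wind_ratio) &
    summaries$wind_ratio >= wind_band[1] &
    summaries$wind_ratio <= wind_band[2]
  tab <- merge(summaries[keep, ], .flr_by_cycle(flr),
               by = c("lake_id", "cycle_index"))
  if (nrow(tab) < 3 || stats::sd(tab$pressure_drop_ratio) == 0 ||
      stats::sd(tab$FL_R_mean) == 0)
    return(list(table = tab, n = nrow(tab), rho = NA_real_,
                p_value = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(tab$pressure_drop_ratio, tab$FL_R_mean,
                    method = method))
  list(table = tab, n = nrow(tab), rho = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Concordance of diel wind and diel flux patterns
#'
#' Reports (i) among unit-cycles with `FL_R > 1`, the fraction whose
#' cycle had a higher daytime than nighttime wind speed, and (ii) among
#' cycles with `wind_ratio > 1`, the fraction whose FL_R did NOT exceed
#' 1 (windy days without elevated daytime flux).
#'
#' @param flr FL_R table from [compute_flr()].
#' @param summaries Output of [driver_day_night_ratios()].
#' @return List with `frac_flr_with_wind`, `n_flr_above_1`,
#'   `frac_wind_without_flux`, `n_wind_above_1`. Fractions are `NA`
#'   when their denominator category is empty.
#' @export
wind_flux_concordance <- function(flr, summaries) {
  tab <- merge(flr[is.finite(flr$FL_R), ],
               summaries[, c("lake_id", "cycle_index", "wind_ratio")],
               by = c("lake_id", "cycle_index"))
  up <- tab$FL_R > 1
  windy <- is.finite(tab$wind_ratio) & tab$wind_ratio > 1
  list(
    frac_flr_with_wind = if (any(up)) mean(windy[up]) else NA_real_,
    n_flr_above_1 = sum(up),
    frac_wind_without_flux = if (any(windy)) mean(!up[windy]) else NA_real_,
    n_wind_above_1 = sum(windy))
}

#' FL_R versus length of the light period
#'
#' Pairs each FL_R with the light-period length of its diel cycle and
#' reports the Spearman rank correlation; a flat relationship indicates
#' that the diel flux asymmetry is not a simple function of photoperiod
#' (hence not of latitude or season).
#'
#' @param flr FL_R table from [compute_flr()].
#' @param min_n Minimum number of pairs, default 5.
#' @return List: `table` (`light_period_h`, `FL_R` pairs), `n`, `rho`,
#'   `p_value`. A constant FL_R gives `rho = 0` with flag
#'   `"degenerate"`.
#' @export
flr_vs_light <- function(flr, min_n = 5) {
  tab <- flr[is.finite(flr$FL_R),
             c("lake_id", "unit_id", "cycle_index", "light_period_h",
               "FL_R")]
  if (nrow(tab) < min_n)
    return(list(table = tab, n = nrow(tab), rho = NA_real_,
                p_value = NA_real_, flag = "too_few"))
  if (stats::sd(tab$FL_R) == 0 || stats::sd(tab$light_period_h) == 0)
    return(list(table = tab, n = nrow(tab), rho = 0, p_value = 1,
                flag = "degenerate"))
  ct <- suppressWarnings(
    stats::cor.test(tab$light_period_h, tab$FL_R, method = "spearman"))
  list(table = tab, n = nrow(tab), rho = unname(ct$estimate),
       p_value = ct$p.value, flag = "")
}
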