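## Chamber flux computation: sensor calibration, gap imputation, QC
## screening and the ideal-gas conversion from headspace concentration
## change to areal CH4 flux.
##
## Fluxes use endpoint differencing (mean of the last k records minus
## mean of the first k) rather than a regression slope: a regression
## would damp the instantaneous concentration steps left by ebullition
## events, and the method is meant to capture diffusion and ebullition
## together.

#' Fit the three-parameter sensor calibration
#'
#' Calibrates a raw CH4 sensor signal against known background air
#' concentrations using open-chamber records collected under well-mixed
#' atmospheric conditions (wind speed above `wind_threshold`). The model
#' is `ppm = beta0 + beta1 * raw + beta2 * AH`, with absolute humidity AH
#' (g m-3) computed from relative humidity and temperature via the
#' Magnus formula. Records from the first `settle_minutes` of each open
#' period are discarded so that residual chamber air from the previous
#' closure does not contaminate the reference.
#'
#' @param series A chamber record `data.frame` (see
#'   [render_sensor_records()]): columns `timestamp`, `raw_signal`,
#'   `rh_pct`, `temp_c`, `state`.
#' @param ambient_ppm Reference background concentration: either a
#'   single number or a `data.frame` with columns `timestamp`,
#'   `ch4_ppm`, matched to records by nearest time.
#' @param wind Hourly wind: `data.frame` with `timestamp`, `wind10_ms`.
#' @param wind_threshold Minimum wind speed (m s-1) for a record to
#'   qualify as well mixed.
#' @param settle_minutes Open-period settling time to discard.
#' @param min_records Minimum number of qualifying records (default 10).
#'
#' @return An object of class `calibration_model`: list with `beta0`,
#'   `beta1`, `beta2`, `n`, `rmse`, `ok` (logical) and `flags`
#'   (character vector; e.g. `"too_few_records"`,
#'   `"nonphysical_gain"`).
#' @export
fit_calibration <- function(series, ambient_ppm, wind, wind_threshold = 2,
                            settle_minutes = 10, min_records = 10) {
  stopifnot(all(c("timestamp", "raw_signal", "rh_pct", "temp_c", "state")
                %in% names(series)))
  fail <- function(flag) structure(
    list(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
         n = 0L, rmse = NA_real_, ok = FALSE, flags = flag),
    class = "calibration_model")

  open <- series$state == "open" & !is.na(series$raw_signal)
  if (!any(open)) return(fail("no_open_records"))
  ## drop the settling head of each open run
  r <- rle(series$state == "open")
  run_id <- rep(seq_along(r$lengths), r$lengths)
  run_start <- stats::ave(as.numeric(series$timestamp), run_id,
                          FUN = function(x) x[1])
  settled <- as.numeric(series$timestamp) - run_start >= settle_minutes * 60
  keep <- open & settled
  ## wind screen (nearest hourly value)
  w <- stats::approx(as.numeric(wind$timestamp), wind$wind10_ms,
                     as.numeric(series$timestamp), method = "constant",
                     rule = 2)$y
  keep <- keep & w > wind_threshold
  if (sum(keep) < min_records) return(fail("too_few_records"))

  ref <- if (is.data.frame(ambient_ppm)) {
    stats::approx(as.numeric(ambient_ppm$timestamp), ambient_ppm$ch4_ppm,
                  as.numeric(series$timestamp[keep]), rule = 2)$y
  } else rep(ambient_ppm, sum(keep))
  ah <- absolute_humidity(series$rh_pct[keep], series$temp_c[keep])
  fit <- stats::lm(ref ~ series$raw_signal[keep] + ah)
  beta <- unname(stats::coef(fit))
  flags <- character()
  ok <- TRUE
  if (!is.finite(beta[2]) || beta[2] <= 0) {
    flags <- c(flags, "nonphysical_gain"); ok <- FALSE
  }
  structure(list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3],
                 n = sum(keep),
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 ok = ok, flags = flags),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ppm = ", signif(x$beta0, 4), " + ",
      signif(x$beta1, 4), " * raw + ", signif(x$beta2, 4),
      " * AH; n = ", x$n, ", RMSE = ", signif(x$rmse, 3), " ppm",
      if (!x$ok) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Apply a fitted calibration to a record series
#'
#' @param series Chamber records with `raw_signal`, `rh_pct`, `temp_c`.
#' @param cal A `calibration_model` from [fit_calibration()].
#' @return `series` with an added `ch4_ppm` column.
#' @export
apply_calibration <- function(series, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (!isTRUE(cal$ok)) stop("cannot apply a failed calibration (",
                            paste(cal$flags, collapse = ","), ")")
  ah <- absolute_humidity(series$rh_pct, series$temp_c)
  series$ch4_ppm <- cal$beta0 + cal$beta1 * series$raw_signal +
    cal$beta2 * ah
  series
}

#' Impute missing RH/temperature from the nearest donor chamber
#'
#' Fills missing `rh_pct`/`temp_c` values in each chamber series with
#' the value of the donor chamber (on the same lake) that is closest in
#' deployment depth, taking the donor record nearest in time. Depth
#' proximity stands in for spatial proximity, which the chamber metadata
#' does not carry. Imputed records are flagged; records for which no
#' donor has data within `max_gap_h` are dropped with a QC count.
#'
#' @param all_series Named list of chamber record data frames (each with
#'   attribute `"chamber"`).
#' @param max_gap_h Maximum donor time gap (hours).
#' @return A list like `all_series` with filled values and logical
#'   columns `imputed_rh`, `imputed_temp`; attribute `"qc"` holds
#'   per-chamber counts of imputed and dropped records.
#' @export
impute_rh_temp <- function(all_series, max_gap_h = 3) {
  depths <- vapply(all_series, function(s) attr(s, "chamber")$depth_m,
                   numeric(1))
  lakes <- vapply(all_series, function(s) s$lake_id[1], character(1))
  qc <- data.frame(chamber_id = names(all_series), imputed = 0L,
                   dropped = 0L)
  for (i in seq_along(all_series)) {
    s <- all_series[[i]]
    s$imputed_rh <- FALSE; s$imputed_temp <- FALSE
    for (col in c("rh_pct", "temp_c")) {
      miss <- which(is.na(s[[col]]))
      if (!length(miss)) next
      donors <- setdiff(which(lakes == lakes[i]), i)
      donors <- donors[order(abs(depths[donors] - depths[i]))]
      for (m in miss) {
        tm <- as.numeric(s$timestamp[m])
        for (d in donors) {
          ds <- all_series[[d]]
          okrec <- !is.na(ds[[col]])
          if (!any(okrec)) next
          j <- which.min(abs(as.numeric(ds$timestamp[okrec]) - tm))
          gap <- abs(as.numeric(ds$timestamp[okrec][j]) - tm)
          if (gap <= max_gap_h * 3600) {
            s[[col]][m] <- ds[[col]][okrec][j]
            s[[if (col == "rh_pct") "imputed_rh" else "imputed_temp"]][m] <- TRUE
            qc$imputed[i] <- qc$imputed[i] + 1L
            break
          }
        }
      }
    }
    drop <- is.na(s$rh_pct) | is.na(s$temp_c)
    qc$dropped[i] <- sum(drop)
    keep <- s[!drop, , drop = FALSE]
    attr(keep, "chamber") <- attr(all_series[[i]], "chamber")
    all_series[[i]] <- keep
  }
  attr(all_series, "qc") <- qc
  all_series
}

## ppm change per hour -> umol m-2 h-1 (ideal gas). dC in ppm
## (umol mol-1), P in Pa, T in K, voa = V/A in m. The 1e-6 (ppm -> mole
## fraction) and 1e6 (mol -> umol) factors cancel.
.flux_from_slope <- function(dC_per_h, p_pa, t_k, voa) {
  dC_per_h * p_pa / (.R_GAS * t_k) * voa
}

#' Compute fluxes from automated-chamber closures
#'
#' Splits the record series into closed accumulation periods, screens
#' them (at least `min_records` samples, duration at least
#' `min_duration_h`), and converts each surviving closure's
#' concentration change to a flux. The change is measured by endpoint
#' differencing: `dC` is the mean of the last `k` records minus the mean
#' of the first `k`, and `dt` the time between those window centres, so
#' ebullition steps inside the closure are retained in the flux.
#' The conversion is `flux = (dC/dt) * P / (R * T) * (V/A)` in
#' umol m-2 h-1, with T and P averaged over the closure.
#'
#' @param series Chamber records carrying a `chamber_spec` as attribute
#'   `"chamber"` (or pass `geometry`). Must contain `ch4_ppm` (else
#'   calibrated from `raw_signal` via `cal`; with `cal = NULL` the
#'   noise-free `ch4_ppm_true` column is used when present).
#' @param cal Optional `calibration_model` applied to `raw_signal`.
#' @param pressure Ambient pressure: single value (hPa) or `data.frame`
#'   with `timestamp`, `pressure_hpa`.
#' @param geometry Optional `chamber_spec` overriding the attribute.
#' @param k Endpoint window length in records (default 3).
#' @param min_records,min_duration_h QC thresholds per closure.
#'
#' @return A `data.frame` of flux records: `lake_id`, `chamber_id`,
#'   `t_start`, `t_end`, `duration_h`, `flux` (umol m-2 h-1),
#'   `method = "afc_endpoints"`, `qc`. Closures failing QC are counted
#'   in attribute `"qc_excluded"`.
#' @export
compute_afc_flux <- function(series, cal = NULL, pressure = 1013,
                             geometry = NULL, k = 3, min_records = 5,
                             min_duration_h = 0.2) {
  geom <- if (!is.null(geometry)) geometry else attr(series, "chamber")
  if (is.null(geom)) stop("chamber geometry not supplied")
  voa <- geom$volume_m3 / geom$area_m2
  if (!"ch4_ppm" %in% names(series)) {
    if (!is.null(cal)) series <- apply_calibration(series, cal)
    else if ("ch4_ppm_true" %in% names(series))
      series$ch4_ppm <- series$ch4_ppm_true
    else stop("series has neither ch4_ppm nor ch4_ppm_true")
  }
  stopifnot(!is.unsorted(as.numeric(series$timestamp)))
  r <- rle(series$state == "closed")
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  rows <- list(); excluded <- 0L
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    tt <- as.numeric(series$timestamp[idx])
    dur_h <- (tt[length(tt)] - tt[1]) / 3600
    if (length(idx) < min_records || dur_h < min_duration_h) {
      excluded <- excluded + 1L
      next
    }
    cc <- series$ch4_ppm[idx]
    kk <- min(k, floor(length(idx) / 2))
    head_i <- seq_len(kk); tail_i <- seq(length(idx) - kk + 1, length(idx))
    dC <- mean(cc[tail_i]) - mean(cc[head_i])
    dt_h <- (mean(tt[tail_i]) - mean(tt[head_i])) / 3600
    t_k <- mean(series$temp_c[idx]) + 273.15
    p_hpa <- if (is.data.frame(pressure)) {
      mean(stats::approx(as.numeric(pressure$timestamp),
                         pressure$pressure_hpa, tt, rule = 2)$y)
    } else pressure
    rows[[length(rows) + 1]] <- data.frame(
      lake_id = if ("lake_id" %in% names(series)) series$lake_id[idx[1]]
                else NA_character_,
      chamber_id = geom$chamber_id,
      t_start = series$timestamp[idx[1]],
      t_end = series$timestamp[idx[length(idx)]],
      duration_h = dur_h,
      flux = .flux_from_slope(dC / dt_h, p_hpa * 100, t_k, voa),
      method = "afc_endpoints", qc = "ok")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lake_id = character(), chamber_id = character(),
               t_start = as.POSIXct(character(), tz = "UTC"),
               t_end = as.POSIXct(character(), tz = "UTC"),
               duration_h = numeric(), flux = numeric(),
               method = character(), qc = character())
  attr(out, "qc_excluded") <- excluded
  out
}

#' Compute a flux from manual grab samples
#'
#' Two-point version of the same ideal-gas conversion used by
#' [compute_afc_flux()]: the concentration difference between the first
#' and last grab sample of a deployment divided by the elapsed time.
#'
#' @param samples `data.frame` with `timestamp` and `ch4_ppm` (at least
#'   two rows per deployment; a single sample yields no record).
#' @param geometry A `chamber_spec`.
#' @param t_c Mean headspace temperature over the deployment (deg C).
#' @param p_hpa Mean ambient pressure (hPa).
#' @return A one-row flux `data.frame` (`method = "manual_two_point"`),
#'   or a zero-row frame with attribute `"qc_excluded" = 1` if fewer
#'   than two samples were supplied.
#' @export
compute_manual_flux <- function(samples, geometry, t_c = 15,
                                p_hpa = 1013) {
  empty <- data.frame(lake_id = character(), chamber_id = character(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      duration_h = numeric(), flux = numeric(),
                      method = character(), qc = character())
  if (nrow(samples) < 2) {
    attr(empty, "qc_excluded") <- 1L
    return(empty)
  }
  samples <- samples[order(samples$timestamp), ]
  n <- nrow(samples)
  dt_h <- as.numeric(samples$timestamp[n] - samples$timestamp[1],
                     units = "hours")
  if (dt_h <= 0) {
    attr(empty, "qc_excluded") <- 1L
    return(empty)
  }
  dC <- samples$ch4_ppm[n] - samples$ch4_ppm[1]
  voa <- geometry$volume_m3 / geometry$area_m2
  out <- data.frame(
    lake_id = if ("lake_id" %in% names(samples)) samples$lake_id[1]
              else NA_character_,
    chamber_id = geometry$chamber_id,
    t_start = samples$timestamp[1], t_end = samples$timestamp[n],
    duration_h = dt_h,
    flux = .flux_from_slope(dC / dt_h, p_hpa * 100, t_c + 273.15, voa),
    method = "manual_two_point", qc = "ok")
  attr(out, "qc_excluded") <- 0L
  out
}

#' Fluxes for every chamber of a rendered scenario
#'
#' Convenience wrapper running calibration (for automated chambers) and
#' flux computation over the full sensor-record set of one rendered
#' scenario. Manual chambers are processed deployment by deployment with
#' the two-point method.
#'
#' @param rendered Output of [render_sensor_records()].
#' @param met Hourly meteorology from [simulate_met()].
#' @param use_true_ppm If `TRUE`, bypass calibration and use the
#'   noise-free `ch4_ppm_true` column (the generator's oracle path).
#' @param ... Passed to [compute_afc_flux()].
#' @return A flux `data.frame` (rows from all chambers); attribute
#'   `"calibrations"` holds the per-chamber `calibration_model`s and
#'   `"qc_excluded"` the total excluded-closure count.
#' @export
scenario_fluxes <- function(rendered, met, use_true_ppm = FALSE, ...) {
  out <- list(); cals <- list(); excl <- 0L
  for (nm in names(rendered$sensors)) {
    s <- rendered$sensors[[nm]]
    geom <- attr(s, "chamber")
    lake <- s$lake_id[1]
    ml <- met[met$lake_id == lake, c("timestamp", "pressure_hpa")]
    if (geom$kind == "automated") {
      cal <- NULL
      if (!use_true_ppm) {
        amb <- rendered$ambient[rendered$ambient$lake_id == lake, ]
        wind <- met[met$lake_id == lake, c("timestamp", "wind10_ms")]
        cal <- fit_calibration(s, amb, wind)
        if (!cal$ok) {
          warning("calibration failed for ", nm, "; using true ppm")
          cal <- NULL
        }
      }
      if (use_true_ppm || is.null(cal)) s$ch4_ppm <- s$ch4_ppm_true
      fx <- compute_afc_flux(s, cal = cal, pressure = ml, ...)
      cals[[nm]] <- cal
    } else {
      ## manual series: rows come in start/end pairs per deployment
      s$ch4_ppm <- s$ch4_ppm_true
      rows <- lapply(split(s, rep(seq_len(nrow(s) / 2), each = 2)),
                     function(dep) {
        tmid <- mean(as.numeric(dep$timestamp))
        p <- stats::approx(as.numeric(ml$timestamp), ml$pressure_hpa,
                           tmid, rule = 2)$y
        compute_manual_flux(dep, geom, t_c = mean(dep$temp_c), p_hpa = p)
      })
      fx <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
    excl <- excl + (attr(fx, "qc_excluded") %||% 0L)
    out[[nm]] <- fx
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "calibrations") <- cals
  attr(res, "qc_excluded") <- excl
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
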