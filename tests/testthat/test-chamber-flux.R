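make_open_series <- function(n = 60, beta = c(0.2, 0.01, 0.02),
                             seed = 1, noise_sd = 0) {
  set.seed(seed)
  ts <- as.POSIXct("2018-08-01 00:00:00", tz = "UTC") + (0:(n - 1)) * 60
  rh <- runif(n, 40, 95)
  temp <- runif(n, 8, 24)
  ppm <- 1.9 + 0.15 * sin(seq(0, 3 * pi, length.out = n)) +
    rnorm(n, 0, 0.01)
  ah <- absolute_humidity(rh, temp)
  raw <- (ppm - beta[1] - beta[3] * ah) / beta[2] + rnorm(n, 0, noise_sd)
  list(series = data.frame(lake_id = "L1", chamber_id = "C1",
                           timestamp = ts, raw_signal = raw,
                           ch4_ppm_true = ppm, rh_pct = rh, temp_c = temp,
                           state = "open"),
       ambient = data.frame(timestamp = ts, ch4_ppm = ppm),
       beta = beta)
}

steady_wind <- function(ts, speed = 5)
  data.frame(timestamp = ts, wind10_ms = speed)

test_that("calibration recovers a noiseless inverse model exactly", {
  fx <- make_open_series()
  cal <- fit_calibration(fx$series, fx$ambient, steady_wind(fx$series$timestamp),
                         settle_minutes = 0)
  expect_true(cal$ok)
  expect_equal(cal$beta0, fx$beta[1], tolerance = 1e-9)
  expect_equal(cal$beta1, fx$beta[2], tolerance = 1e-9)
  expect_equal(cal$beta2, fx$beta[3], tolerance = 1e-9)
  expect_lt(cal$rmse, 1e-10)
})

test_that("a humidity-free sensor yields beta2 near zero", {
  fx <- make_open_series(n = 400, beta = c(0.2, 0.01, 0), noise_sd = 0.5)
  cal <- fit_calibration(fx$series, fx$ambient,
                         steady_wind(fx$series$timestamp),
                         settle_minutes = 0)
  expect_true(cal$ok)
  # beta2 should be indistinguishable from zero at this noise level
  expect_lt(abs(cal$beta2), 0.005)
})

test_that("calibration fails cleanly without qualifying records", {
  fx <- make_open_series()
  calm <- steady_wind(fx$series$timestamp, speed = 0.5)  # never > 2 m/s
  cal <- fit_calibration(fx$series, fx$ambient, calm, settle_minutes = 0)
  expect_false(cal$ok)
  expect_true("too_few_records" %in% cal$flags)
  expect_error(apply_calibration(fx$series, cal), "failed calibration")
})

test_that("RH/temperature imputation fills from the depth-nearest donor", {
  ts <- as.POSIXct("2018-08-01 10:00:00", tz = "UTC") + (0:2) * 3600
  mk <- function(id, depth, rh, temp) {
    s <- data.frame(lake_id = "L1", chamber_id = id, timestamp = ts,
                    raw_signal = 1, ch4_ppm_true = 2, rh_pct = rh,
                    temp_c = temp, state = "closed")
    attr(s, "chamber") <- chamber_spec(id, depth_m = depth)
    s
  }
  a <- mk("A", 1.0, c(80, NA, 82), c(15, 15, 15))
  b <- mk("B", 1.1, c(70, 71, 72), c(14, 14, 14))
  c3 <- mk("C", 3.0, c(60, 61, 62), c(13, 13, 13))
  out <- impute_rh_temp(list(A = a, B = b, C = c3))
  expect_equal(out$A$rh_pct[2], 71)           # donor B (closest depth)
  expect_true(out$A$imputed_rh[2])
  qc <- attr(out, "qc")
  expect_equal(qc$imputed[qc$chamber_id == "A"], 1L)
  # untouched series pass through identically
  expect_equal(out$B$rh_pct, b$rh_pct)

  # all chambers missing at one time -> record dropped
  a2 <- mk("A", 1.0, c(80, NA, 82), c(15, 15, 15))
  b2 <- mk("B", 1.1, c(70, NA, 72), c(14, 14, 14))
  out2 <- impute_rh_temp(list(A = a2, B = b2), max_gap_h = 0.25)
  expect_equal(nrow(out2$A), 2)
  expect_equal(attr(out2, "qc")$dropped, c(1L, 1L))
})

make_closure <- function(slope_ppm_h = 1, n_min = 61, t_c = 20,
                         c0 = 1.9, step_at = NULL, step_ppm = 0) {
  ts <- as.POSIXct("2018-08-01 10:00:00", tz = "UTC") + (0:(n_min - 1)) * 60
  ppm <- c0 + slope_ppm_h * (0:(n_min - 1)) / 60
  if (!is.null(step_at)) ppm[step_at:n_min] <- ppm[step_at:n_min] + step_ppm
  s <- data.frame(lake_id = "L1", chamber_id = "C1", timestamp = ts,
                  raw_signal = NA, ch4_ppm_true = ppm, rh_pct = 80,
                  temp_c = t_c, state = "closed")
  attr(s, "chamber") <- chamber_spec("C1", depth_m = 1)  # V/A = 0.1 m
  s
}

test_that("the unit conversion reproduces the ideal-gas hand value", {
  s <- make_closure(slope_ppm_h = 1, t_c = 20)
  fx <- compute_afc_flux(s, pressure = 1013.25)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$flux, 4.157, tolerance = 1e-3)
  # flat concentration -> zero flux
  s0 <- make_closure(slope_ppm_h = 0)
  expect_equal(compute_afc_flux(s0, pressure = 1013.25)$flux, 0)
})

test_that("flux matches the dimensional-analysis oracle on random draws", {
  set.seed(2)
  for (i in 1:200) {
    slope <- runif(1, -2, 8)
    t_c <- runif(1, -5, 30)
    p <- runif(1, 950, 1050)
    vol <- runif(1, 0.002, 0.02)
    area <- runif(1, 0.03, 0.2)
    s <- make_closure(slope, t_c = t_c)
    attr(s, "chamber") <- chamber_spec("C1", 1, volume_m3 = vol,
                                       area_m2 = area)
    got <- compute_afc_flux(s, pressure = p)$flux
    # endpoint differencing on a linear series recovers the slope exactly
    want <- oracle_flux(slope, 1, vol, area, t_c + 273.15, p * 100)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("flux is monotone in dC, 1/dt and V/A", {
  base <- compute_afc_flux(make_closure(1), pressure = 1013)$flux
  expect_gt(compute_afc_flux(make_closure(2), pressure = 1013)$flux, base)
  s <- make_closure(1)
  attr(s, "chamber") <- chamber_spec("C1", 1, volume_m3 = 0.015,
                                     area_m2 = 0.075)   # V/A doubled
  expect_gt(compute_afc_flux(s, pressure = 1013)$flux, base)
})

test_that("an in-closure ebullition step adds size/duration to the flux", {
  # 10 umol m-2 step: dC = 10 * R*T/(P * V/A)
  t_k <- 293.15; p <- 101325; voa <- 0.1
  dC <- 10 * 8.314 * t_k / (p * voa)
  s <- make_closure(slope_ppm_h = 1, n_min = 61, step_at = 31,
                    step_ppm = dC)
  fx <- compute_afc_flux(s, pressure = 1013.25)
  base <- compute_afc_flux(make_closure(1), pressure = 1013.25)
  # the step sits between the endpoint windows; dt is 58 min here
  expect_equal(fx$flux - base$flux,
               oracle_flux(dC, 58 / 60, 0.0075, 0.075, t_k, 101325),
               tolerance = 1e-6)
})

test_that("QC screening drops short or sparse closures", {
  s <- make_closure(n_min = 4)                      # < 5 records
  fx <- compute_afc_flux(s, pressure = 1013)
  expect_equal(nrow(fx), 0)
  expect_equal(attr(fx, "qc_excluded"), 1L)
  s2 <- make_closure(n_min = 8)                     # 7 min < 0.2 h
  fx2 <- compute_afc_flux(s2, pressure = 1013)
  expect_equal(nrow(fx2), 0)
})

test_that("manual two-point fluxes mirror the AFC conversion", {
  ts <- as.POSIXct("2018-08-01 08:00:00", tz = "UTC") + c(0, 6 * 3600)
  samples <- data.frame(lake_id = "L1", timestamp = ts,
                        ch4_ppm = c(1.9, 7.9))      # 1 ppm/h over 6 h
  geom <- chamber_spec("M1", 1, kind = "manual")
  fx <- compute_manual_flux(samples, geom, t_c = 20, p_hpa = 1013.25)
  expect_equal(fx$flux, 4.157, tolerance = 1e-3)
  expect_equal(fx$duration_h, 6)
  expect_equal(fx$method, "manual_two_point")
  # a single grab sample yields no record
  none <- compute_manual_flux(samples[1, ], geom)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "qc_excluded"), 1L)
})

test_that("noiseless generator round-trip recovers interval-mean truth", {
  sc <- noiseless_scenario(r_true = 1, n_days = 2, base_flux = 12)
  out <- run_sim(sc)
  fx <- scenario_fluxes(out$rn, out$met, use_true_ppm = TRUE)
  expect_gt(nrow(fx), 10)
  expect_equal(fx$flux, rep(12, nrow(fx)), tolerance = 1e-6)

  # full sensor + calibration path: residual errors stay below 1%
  fx2 <- scenario_fluxes(out$rn, out$met)
  expect_lt(max(abs(fx2$flux - 12) / 12), 0.01)
})
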