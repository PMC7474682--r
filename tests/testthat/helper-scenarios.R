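# Shared scenario fixtures, built in code.

one_lake <- function(chambers = list(chamber_spec("C1", depth_m = 1)),
                     lat = 58, lon = 14.5, offset = 2,
                     season = "stratified") {
  lake_config("L1", latitude = lat, longitude = lon, utc_offset = offset,
              season_label = season, chambers = chambers)
}

# Noise-free analytic world: square-wave diel signal, constant air
# temperature and pressure (the flux conversion uses closure means, so
# diel T/P variation would add a ~1e-5 discretisation term).
noiseless_scenario <- function(r_true = 2.5, n_days = 3, rng_seed = 7,
                               base_flux = 10, ...) {
  sim_scenario(one_lake(), n_days = n_days, r_true = r_true,
               base_flux = base_flux, flux_noise_sigma = 0,
               ebullition_rate = 0, sensor_noise_sd = 0,
               rng_seed = rng_seed,
               met = list(airt_amp = 0, airt_ar_sd = 0,
                          press_step_sd = 0), ...)
}

run_sim <- function(sc) {
  cy <- scenario_cycles(sc)
  tr <- simulate_flux_truth(sc, cy)
  met <- simulate_met(sc, cy)
  rn <- render_sensor_records(tr, sc, met)
  list(sc = sc, cy = cy, tr = tr, met = met, rn = rn)
}

# Duration-weighted day and night means of a truth table's flux column.
truth_day_night_means <- function(tr, col = "diffusive_flux") {
  f <- tr$flux
  dt_h <- as.numeric(f$t_end - f$t_start, units = "hours")
  c(day = sum(f[[col]][f$is_day] * dt_h[f$is_day]) / sum(dt_h[f$is_day]),
    night = sum(f[[col]][!f$is_day] * dt_h[!f$is_day]) /
      sum(dt_h[!f$is_day]))
}
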