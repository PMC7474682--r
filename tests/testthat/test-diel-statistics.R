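test_that("weighted geometric mean matches closed forms", {
  expect_equal(weighted_geometric_mean(c(3, 3, 3), c(1, 5, 2)), 3)
  expect_equal(weighted_geometric_mean(c(1, 4), c(1, 1)), 2)
  expect_equal(weighted_geometric_mean(c(1, 4), c(3, 1)), 4^(1 / 4))
  expect_error(weighted_geometric_mean(c(1, -2), c(1, 1)), "positive")
  expect_error(weighted_geometric_mean(c(1, 0), c(1, 1)), "positive")
  empty <- weighted_geometric_mean(numeric())
  expect_true(is.na(empty))
  expect_equal(attr(empty, "flag"), "empty")
})

test_that("weighted geometric mean never exceeds the arithmetic mean", {
  set.seed(4)
  for (i in 1:50) {
    x <- rlnorm(sample(2:20, 1), 1, 1)
    w <- runif(length(x), 0.1, 5)
    expect_lte(weighted_geometric_mean(x, w),
               sum(w * x) / sum(w) + 1e-12)
  }
})

hour_ts <- function(h) as.POSIXct("2018-08-01 00:00:00", tz = "UTC") +
  h * 3600

test_that("hourly profile weights fluxes by hour overlap", {
  # one 2-h flux spanning 10:00-12:00 -> 1 h in hour 10 and hour 11
  fx <- data.frame(t_start = hour_ts(10), t_end = hour_ts(12), flux = 5)
  pr <- hourly_profile(fx)
  expect_equal(pr$hour_of_day, c(10, 11))
  expect_equal(pr$total_weight_h, c(1, 1))
  expect_equal(pr$gw_mean_flux, c(5, 5))

  # constant-flux chamber over several days -> flat 24-point profile
  fx2 <- data.frame(t_start = hour_ts(seq(0, 71, by = 1.5)),
                    t_end = hour_ts(seq(0, 71, by = 1.5) + 1.5),
                    flux = 7)
  pr2 <- hourly_profile(fx2)
  expect_equal(nrow(pr2), 24)
  expect_equal(pr2$gw_mean_flux, rep(7, 24))

  # utc_offset shifts the clock axis
  pr3 <- hourly_profile(fx, utc_offset = 2)
  expect_equal(pr3$hour_of_day, c(12, 13))

  # non-positive fluxes are excluded and counted, not silently used
  fx4 <- rbind(fx, data.frame(t_start = hour_ts(10), t_end = hour_ts(11),
                              flux = -1))
  pr4 <- hourly_profile(fx4)
  expect_equal(pr4$n_excluded[pr4$hour_of_day == 10], 1)
  expect_equal(pr4$gw_mean_flux[pr4$hour_of_day == 10], 5)
})

test_that("square-wave scenario gives the closed-form hourly profile", {
  sc <- noiseless_scenario(r_true = 2.5, n_days = 3)
  out <- run_sim(sc)
  fx <- scenario_fluxes(out$rn, out$met, use_true_ppm = TRUE)
  pr <- hourly_profile(fx, utc_offset = 2)
  # local sunrise ~04:45, sunset ~21:15 at 58 N in early August; hours
  # reachable only by all-day closures (max 1.5 h) sit well inside
  lit <- pr$gw_mean_flux[pr$hour_of_day %in% 10:16]
  dark <- pr$gw_mean_flux[pr$hour_of_day %in% 0:2]
  expect_equal(lit, rep(2.5 * 10, length(lit)), tolerance = 1e-9)
  expect_equal(dark, rep(10, length(dark)), tolerance = 1e-9)
})

test_that("FL_R reproduces hand-computed weighted means", {
  lake <- one_lake()
  t0 <- as.POSIXct("2018-08-10 00:00:00", tz = "UTC")
  cy <- build_cycles(lake, t0, t0 + 2 * 86400)[1, ]
  # day: 2 for 1 h and 4 for 3 h -> F_day = 3.5; night: 1 throughout
  fx <- data.frame(
    lake_id = "L1", chamber_id = "C1",
    t_start = c(cy$sunrise + 3600, cy$sunrise + 2 * 3600,
                cy$sunset + 3600),
    t_end = c(cy$sunrise + 2 * 3600, cy$sunrise + 5 * 3600,
              cy$sunset + 4 * 3600),
    flux = c(2, 4, 1))
  flr <- compute_flr(fx, cy)
  expect_equal(nrow(flr), 1)
  expect_equal(flr$F_day, 3.5)
  expect_equal(flr$F_night, 1)
  expect_equal(flr$FL_R, 3.5)
  expect_equal(flr$day_hours, 4)
  expect_equal(flr$night_hours, 3)
})

test_that("FL_R is 1 for constant flux and scale invariant in general", {
  sc <- noiseless_scenario(r_true = 1, n_days = 3)
  out <- run_sim(sc)
  fx <- scenario_fluxes(out$rn, out$met, use_true_ppm = TRUE)
  flr <- compute_flr(fx, out$cy)
  expect_true(all(abs(flr$FL_R - 1) < 1e-9))

  # scale invariance on a noisy set
  sc2 <- default_scenario(rng_seed = 6, n_days = 4)
  out2 <- run_sim(sc2)
  fx2 <- scenario_fluxes(out2$rn, out2$met, use_true_ppm = TRUE)
  flr_a <- compute_flr(fx2, out2$cy)
  fx2$flux <- fx2$flux * 17.3
  flr_b <- compute_flr(fx2, out2$cy)
  expect_equal(flr_b$FL_R, flr_a$FL_R, tolerance = 1e-12)
})

test_that("truth-interval fluxes give FL_R exactly r_true", {
  sc <- noiseless_scenario(r_true = 2.5, n_days = 3)
  cy <- scenario_cycles(sc)
  tr <- simulate_flux_truth(sc, cy)
  # feed the aligned truth intervals through compute_flr directly
  fx <- data.frame(lake_id = tr$flux$lake_id,
                   chamber_id = tr$flux$chamber_id,
                   t_start = tr$flux$t_start, t_end = tr$flux$t_end,
                   flux = tr$flux$true_flux)
  flr <- compute_flr(fx, cy)
  expect_gt(nrow(flr), 0)
  expect_equal(flr$FL_R, rep(2.5, nrow(flr)), tolerance = 1e-12)
})

test_that("parameter recovery holds across r_true values", {
  for (r in c(1, 1.5, 2.5, 4)) {
    sc <- sim_scenario(one_lake(), n_days = 30, r_true = r,
                       flux_noise_sigma = 0.2, ebullition_rate = 0,
                       rng_seed = 20 + r * 10)
    cy <- scenario_cycles(sc)
    tr <- simulate_flux_truth(sc, cy)
    fx <- data.frame(lake_id = tr$flux$lake_id,
                     chamber_id = tr$flux$chamber_id,
                     t_start = tr$flux$t_start, t_end = tr$flux$t_end,
                     flux = tr$flux$true_flux)
    flr <- compute_flr(fx, cy)
    se <- sd(flr$FL_R) / sqrt(nrow(flr))
    expect_lt(abs(mean(flr$FL_R) - r), 3 * se + 0.05)
  }
})

test_that("depth bins follow the four-category convention", {
  ch <- list(chamber_spec("a", 0.4), chamber_spec("b", 0.5),
             chamber_spec("c", 1.2), chamber_spec("d", 2.0),
             chamber_spec("e", 1.5))
  bins <- bin_by_depth(ch)
  expect_equal(bins$unit_id, c("<0.5", "0.5-1", "1-1.5", ">1.5", ">1.5"))
  nb <- bin_by_depth(data.frame(chamber_id = "x", depth_m = NA_real_))
  expect_true(is.na(nb$unit_id))
  expect_equal(attr(nb, "n_unbinned"), 1L)
})

test_that("rank-sum day/night test matches exact enumeration", {
  # hand case: day {3,4,5} vs night {1,2} -> one-sided p = 1/10
  fx <- data.frame(
    t_start = c(hour_ts(c(11, 12, 13)), hour_ts(c(1, 2))),
    t_end = c(hour_ts(c(11, 12, 13)), hour_ts(c(1, 2))) + 1800,
    flux = c(3, 4, 5, 1, 2))
  res <- wilcoxon_day_night(fx)
  expect_equal(res$p_value, 1 / 10)
  expect_equal(res$p_value, oracle_ranksum_p(c(3, 4, 5), c(1, 2)))

  # identical samples in both windows (no shift) -> p >= 0.5
  fx2 <- data.frame(
    t_start = c(hour_ts(c(11, 12, 13)), hour_ts(c(1, 2, 3))),
    t_end = c(hour_ts(c(11, 12, 13)), hour_ts(c(1, 2, 3))) + 1800,
    flux = c(1, 2, 3, 1, 2, 3))
  expect_gte(wilcoxon_day_night(fx2)$p_value, 0.5)

  # empty window -> flagged, no test
  res3 <- wilcoxon_day_night(fx[1:3, ])
  expect_true(is.na(res3$p_value))
  expect_equal(res3$flag, "empty_window")
})

test_that("rank-sum p equals enumeration for random small samples", {
  set.seed(8)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    vals <- sample(100, m + n)        # unique -> tie-free, exact path
    day <- vals[seq_len(m)]; night <- vals[m + seq_len(n)]
    fx <- data.frame(
      t_start = c(hour_ts(seq(10, 15, length.out = m)),
                  hour_ts(seq(0, 3, length.out = n))),
      t_end = c(hour_ts(seq(10, 15, length.out = m)),
                hour_ts(seq(0, 3, length.out = n))) + 600,
      flux = c(day, night))
    expect_equal(wilcoxon_day_night(fx)$p_value,
                 oracle_ranksum_p(day, night), tolerance = 1e-12)
  }
})

test_that("signed-rank FL_R exceedance matches exact enumeration", {
  mk_flr <- function(r) data.frame(lake_id = "L1", unit_id = "u",
                                   cycle_index = seq_along(r), FL_R = r,
                                   F_day = r, F_night = 1,
                                   day_hours = 12, night_hours = 12,
                                   light_period_h = 12)
  # {2,3,4,5,6} vs 1: all positive -> one-sided exact p = 1/32
  res <- flr_exceedance_test(mk_flr(c(2, 3, 4, 5, 6)))
  row <- res[res$unit_id == "u", ]
  expect_equal(row$p_value, 1 / 32)
  expect_equal(row$p_value, oracle_signedrank_p(c(2, 3, 4, 5, 6), 1))
  expect_equal(row$frac_above_1, 1)

  # all FL_R exactly 1 -> degenerate, no test, fraction still reported
  res2 <- flr_exceedance_test(mk_flr(rep(1, 6)))
  row2 <- res2[res2$unit_id == "u", ]
  expect_true(is.na(row2$p_value))
  expect_equal(row2$frac_above_1, 0)

  # mixed with ties: statistic must match the mid-rank construction
  res3 <- flr_exceedance_test(mk_flr(c(0.5, 2, 2, 2)))
  row3 <- res3[res3$unit_id == "u", ]
  d <- c(0.5, 2, 2, 2) - 1
  rk <- rank(abs(d))
  expect_equal(row3$statistic, sum(rk[d > 0]))
})

test_that("signed-rank p equals enumeration for random small samples", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    # distinct magnitudes with random signs: tie-free |differences|
    r <- 1 + sample(1:10, n) / 7 * sample(c(-1, 1), n, replace = TRUE)
    flr <- data.frame(lake_id = "L1", unit_id = "u",
                      cycle_index = seq_len(n), FL_R = r, F_day = r,
                      F_night = 1, day_hours = 12, night_hours = 12,
                      light_period_h = 12)
    row <- flr_exceedance_test(flr)
    row <- row[row$unit_id == "u", ]
    expect_equal(row$p_value, oracle_signedrank_p(r, 1),
                 tolerance = 1e-12)
  }
})
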