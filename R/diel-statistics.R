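## Headline diel statistics: time-weighted geometric hourly flux
## profiles, day:night flux ratios (FL_R) per measurement unit and diel
## cycle, depth-bin pooling, and the nonparametric day-vs-night tests.
##
## Two deliberate asymmetries, both part of the method being
## implemented: hourly profiles use *geometric* duration-weighted means
## (robust to episodic ebullition spikes), while FL_R uses *arithmetic*
## duration-weighted means of day and night fluxes; and the clock-window
## day/night test uses local clock hours, distinct from the
## sunrise/sunset windows used for FL_R.

#' Time-weighted geometric mean
#'
#' `exp( sum(w * log(x)) / sum(w) )` for positive values `x` and
#' positive weights `w` (hours of measurement time). Non-positive values
#' must be filtered upstream; they make the geometric mean undefined.
#'
#' @param values Positive fluxes.
#' @param weights Positive weights; recycled if scalar.
#' @return The weighted geometric mean, or `NA_real_` (with attribute
#'   `"flag" = "empty"`) for empty input.
#' @examples
#' weighted_geometric_mean(c(1, 4), c(1, 1))   # 2
#' weighted_geometric_mean(c(1, 4), c(3, 1))   # 4^(1/4)
#' @export
weighted_geometric_mean <- function(values, weights = 1) {
  if (!length(values))
    return(structure(NA_real_, flag = "empty"))
  if (length(weights) == 1) weights <- rep(weights, length(values))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("weighted_geometric_mean requires strictly positive values; ",
         "filter non-positive fluxes upstream")
  if (any(weights <= 0)) stop("weights must be positive")
  exp(sum(weights * log(values)) / sum(weights))
}

#' Hourly diel profile of the flux (geometric, time-weighted)
#'
#' Each flux interval contributes to every local clock hour it overlaps,
#' with weight equal to the overlap duration; the profile value for an
#' hour is the weighted geometric mean over all contributing positive
#' fluxes. Hours with no data are absent from the result, not zero.
#'
#' @param fluxes Flux `data.frame` with `t_start`, `t_end`, `flux`.
#' @param utc_offset Hours added to UTC for the local clock axis.
#' @param lake_id,season_label Optional labels copied to the output.
#' @return `data.frame` with `lake_id`, `season_label`, `hour_of_day`
#'   (0--23, local clock), `gw_mean_flux`, `n_obs`, `total_weight_h` and
#'   `n_excluded` (non-positive fluxes dropped from that hour).
#' @export
hourly_profile <- function(fluxes, utc_offset = 0, lake_id = NA,
                           season_label = NA) {
  if (!nrow(fluxes))
    return(data.frame(lake_id = character(), season_label = character(),
                      hour_of_day = integer(), gw_mean_flux = numeric(),
                      n_obs = integer(), total_weight_h = numeric(),
                      n_excluded = integer()))
  t0 <- as.numeric(fluxes$t_start) + utc_offset * 3600
  t1 <- as.numeric(fluxes$t_end) + utc_offset * 3600
  ## expand each interval over the clock hours it spans
  pieces <- lapply(seq_along(t0), function(i) {
    hs <- seq(floor(t0[i] / 3600), ceiling(t1[i] / 3600) - 1)
    w <- pmax(0, pmin(t1[i], (hs + 1) * 3600) - pmax(t0[i], hs * 3600)) / 3600
    keep <- w > 0
    data.frame(hour_of_day = hs[keep] %% 24, flux = fluxes$flux[i],
               w = w[keep])
  })
  long <- do.call(rbind, pieces)
  res <- lapply(sort(unique(long$hour_of_day)), function(h) {
    sub <- long[long$hour_of_day == h, ]
    pos <- sub$flux > 0
    data.frame(lake_id = lake_id, season_label = season_label,
               hour_of_day = h,
               gw_mean_flux = if (any(pos))
                 weighted_geometric_mean(sub$flux[pos], sub$w[pos])
               else NA_real_,
               n_obs = sum(pos), total_weight_h = sum(sub$w[pos]),
               n_excluded = sum(!pos))
  })
  do.call(rbind, res)
}

#' Day:night flux ratio (FL_R) per unit and diel cycle
#'
#' For every measurement unit (chamber, or depth bin via `units`) and
#' every diel cycle, computes the duration-weighted arithmetic mean flux
#' of the day window (`F_day = sum(flux_i * day_overlap_i) /
#' sum(day_overlap_i)`), the analogous mean over the following night,
#' and their ratio `FL_R = F_day / F_night`. Fluxes straddling sunset
#' contribute to both windows in proportion to their overlap.
#'
#' @param fluxes Flux `data.frame` (needs `chamber_id`, `lake_id`,
#'   `t_start`, `t_end`, `flux`).
#' @param cycles Diel-cycle table from [build_cycles()] (stacked over
#'   lakes is fine; rows are matched by `lake_id`).
#' @param units Optional `data.frame` mapping `chamber_id` to `unit_id`
#'   (e.g. from [bin_by_depth()]); defaults to one unit per chamber.
#' @param min_window_h Minimum flux-time (hours) required in each of
#'   the day and night windows; cycles with less coverage are skipped.
#'
#' @return `data.frame` with `lake_id`, `unit_id`, `cycle_index`,
#'   `F_day`, `F_night`, `FL_R`, `day_hours`, `night_hours`,
#'   `light_period_h`. Records with `F_night <= 0` have `FL_R = NA` and
#'   are counted in attribute `"n_undefined"`; skipped unit-cycles are
#'   counted in `"n_skipped"`.
#' @export
compute_flr <- function(fluxes, cycles, units = NULL, min_window_h = 1) {
  if (is.null(units))
    units <- data.frame(chamber_id = unique(fluxes$chamber_id),
                        unit_id = unique(fluxes$chamber_id))
  fluxes$unit_id <- units$unit_id[match(fluxes$chamber_id,
                                        units$chamber_id)]
  rows <- list(); n_undef <- 0L; n_skip <- 0L
  for (lk in unique(fluxes$lake_id)) {
    fl <- fluxes[fluxes$lake_id == lk, ]
    cyl <- cycles[cycles$lake_id == lk, ]
    if (!nrow(cyl)) next
    ov <- assign_day_night(fl, cyl)
    for (u in unique(ov$unit_id)) {
      for (ci in unique(ov$cycle_index[ov$unit_id == u])) {
        sub <- ov[ov$unit_id == u & ov$cycle_index == ci, ]
        dsum <- sum(sub$day_overlap_h); nsum <- sum(sub$night_overlap_h)
        if (dsum < min_window_h || nsum < min_window_h) {
          n_skip <- n_skip + 1L
          next
        }
        f_day <- sum(sub$flux * sub$day_overlap_h) / dsum
        f_night <- sum(sub$flux * sub$night_overlap_h) / nsum
        flr <- if (f_night > 0) f_day / f_night else NA_real_
        if (!is.finite(flr)) n_undef <- n_undef + 1L
        rows[[length(rows) + 1]] <- data.frame(
          lake_id = lk, unit_id = u, cycle_index = ci,
          F_day = f_day, F_night = f_night, FL_R = flr,
          day_hours = dsum, night_hours = nsum,
          light_period_h = sub$light_period_h[1])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lake_id = character(), unit_id = character(),
               cycle_index = integer(), F_day = numeric(),
               F_night = numeric(), FL_R = numeric(),
               day_hours = numeric(), night_hours = numeric(),
               light_period_h = numeric())
  out <- out[order(out$lake_id, out$unit_id, out$cycle_index), ]
  rownames(out) <- NULL
  attr(out, "n_undefined") <- n_undef
  attr(out, "n_skipped") <- n_skip
  out
}

#' Group chambers into depth bins
#'
#' Standard four-category depth binning: `<0.5`, `0.5-1`, `1-1.5` and
#' `>1.5` m, with right-open intervals so that a chamber at exactly
#' 0.5 m falls in `0.5-1`.
#'
#' @param chambers List of `chamber_spec`s, or a `data.frame` with
#'   `chamber_id` and `depth_m`.
#' @param breaks Inner bin boundaries in metres.
#' @return `data.frame` with `chamber_id`, `depth_m`, `unit_id` (the bin
#'   label); chambers with missing depth get `unit_id = NA` and are
#'   counted in attribute `"n_unbinned"`.
#' @export
bin_by_depth <- function(chambers, breaks = c(0.5, 1, 1.5)) {
  df <- if (is.data.frame(chambers)) chambers else
    data.frame(chamber_id = vapply(chambers, `[[`, character(1),
                                   "chamber_id"),
               depth_m = vapply(chambers, `[[`, numeric(1), "depth_m"))
  labels <- c(paste0("<", breaks[1]),
              paste(utils::head(breaks, -1), breaks[-1], sep = "-"),
              paste0(">", breaks[length(breaks)]))
  df$unit_id <- as.character(cut(df$depth_m, c(-Inf, breaks, Inf),
                                 labels = labels, right = FALSE))
  attr(df, "n_unbinned") <- sum(is.na(df$unit_id))
  df
}

## Shared Wilcoxon policy: exact null for small samples without ties,
## normal approximation with continuity correction otherwise.
.wilcox <- function(x, y = NULL, mu = 0, exact_max = 25) {
  n_tot <- length(x) + length(y)
  vals <- if (is.null(y)) abs(x - mu) else c(x, y)
  exact <- n_tot <= exact_max && !anyDuplicated(vals)
  suppressWarnings(
    stats::wilcox.test(x, y, mu = mu, alternative = "greater",
                       exact = exact, correct = TRUE))
}

#' Clock-window day-vs-night flux comparison (rank-sum test)
#'
#' One-sided two-sample Wilcoxon rank-sum test that fluxes whose
#' interval midpoints fall in the daytime clock window exceed those in
#' the night window. Windows are local clock hours (`utc_offset`
#' applied), by default 10:00--16:00 vs 00:00--04:00. The null
#' distribution is exact for combined n <= 25 without ties, otherwise a
#' normal approximation with continuity correction is used.
#'
#' @param fluxes Flux `data.frame` with `t_start`, `t_end`, `flux`.
#' @param utc_offset Hours added to UTC for the clock windows.
#' @param day_window,night_window Numeric `c(start, end)` clock hours;
#'   midpoints with hour in `[start, end)` qualify.
#' @return List with `statistic` (W), `p_value` (one-sided, day >
#'   night), `n_day`, `n_night`, `method`; or a flagged list with
#'   `p_value = NA` if either window is empty.
#' @export
wilcoxon_day_night <- function(fluxes, utc_offset = 0,
                               day_window = c(10, 16),
                               night_window = c(0, 4)) {
  mid_h <- ((as.numeric(fluxes$t_start) + as.numeric(fluxes$t_end)) / 2 /
              3600 + utc_offset) %% 24
  day <- fluxes$flux[mid_h >= day_window[1] & mid_h < day_window[2]]
  night <- fluxes$flux[mid_h >= night_window[1] & mid_h < night_window[2]]
  if (!length(day) || !length(night))
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_day = length(day), n_night = length(night),
                method = NA_character_, flag = "empty_window"))
  ht <- .wilcox(day, night)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_day = length(day), n_night = length(night), method = ht$method)
}

#' Test whether FL_R exceeds 1 (signed-rank), per unit
#'
#' One-sample Wilcoxon signed-rank test of the per-cycle FL_R values
#' against 1 (one-sided, greater), computed separately for each
#' `unit_id` (and pooled under `unit_id = "(all)"`). Zero differences
#' are dropped before testing (Wilcoxon's original treatment; set
#' `zero_method = "pratt"` to keep them in the ranking). The fraction of
#' FL_R above 1 is always reported; the test is skipped for fewer than
#' `min_n` usable differences.
#'
#' @param flr FL_R table from [compute_flr()].
#' @param min_n Minimum number of non-zero differences (default 4).
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @return `data.frame` per unit: `unit_id`, `n`, `frac_above_1`,
#'   `statistic` (V), `p_value`, `flag`.
#' @export
flr_exceedance_test <- function(flr, min_n = 4,
                                zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  groups <- c(split(flr$FL_R, flr$unit_id),
              list("(all)" = flr$FL_R))
  rows <- lapply(names(groups), function(u) {
    r <- groups[[u]]
    r <- r[is.finite(r)]
    frac <- if (length(r)) mean(r > 1) else NA_real_
    d <- r - 1
    if (zero_method == "wilcoxon") {
      d <- d[d != 0]
      if (length(d) < min_n)
        return(data.frame(unit_id = u, n = length(r), frac_above_1 = frac,
                          statistic = NA_real_, p_value = NA_real_,
                          flag = "too_few_or_degenerate"))
      ht <- .wilcox(d, mu = 0)
      stat <- unname(ht$statistic); pv <- ht$p.value
    } else {
      ## Pratt: zeros kept in the ranking, excluded from the statistic;
      ## normal approximation with the zero-adjusted null moments.
      if (sum(d != 0) < min_n)
        return(data.frame(unit_id = u, n = length(r), frac_above_1 = frac,
                          statistic = NA_real_, p_value = NA_real_,
                          flag = "too_few_or_degenerate"))
      rk <- rank(abs(d))
      stat <- sum(rk[d > 0])
      n <- length(d); z <- sum(d == 0)
      mu_v <- (n * (n + 1) - z * (z + 1)) / 4
      var_v <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24
      pv <- stats::pnorm((stat - mu_v - 0.5) / sqrt(var_v),
                         lower.tail = FALSE)
    }
    data.frame(unit_id = u, n = length(r), frac_above_1 = frac,
               statistic = stat, p_value = pv, flag = "")
  })
  do.call(rbind, rows)
}
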