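#' Ectotherm model parameters for the operative-temperature synthesizer
#'
#' The synthesizer stands in for a full biophysical microclimate + ectotherm
#' model: a passive ("dead", non-thermoregulating) cylindrical animal model
#' tracks air temperature plus a daytime radiative gain. Mass and shape are
#' carried as metadata of the emulated animal model (33.5 g cylinder by
#' default); they do not enter the simplified temperature arithmetic.
#'
#' @param mass_g animal model mass, grams.
#' @param shape animal model shape label.
#' @param diurnal logical, diurnal activity assumed.
#' @param radiative_gain degC added to the exposed model during daylight
#'   hours (06:00-20:00).
#' @param diurnal_amplitude degC half-range of the daily temperature cycle.
#' @return list of class `ectotherm_params`.
#' @export
ectotherm_params <- function(mass_g = 33.5, shape = "cylinder",
                             diurnal = TRUE, radiative_gain = 12,
                             diurnal_amplitude = 8) {
  if (mass_g <= 0) vt_stop("invalid_config", "`mass_g` must be > 0")
  if (radiative_gain < 0 || diurnal_amplitude < 0) {
    vt_stop("invalid_config", "amplitudes must be >= 0")
  }
  structure(list(mass_g = mass_g, shape = shape, diurnal = diurnal,
                 radiative_gain = radiative_gain,
                 diurnal_amplitude = diurnal_amplitude),
            class = "ectotherm_params")
}

# Day-of-year midpoints of the 12 months in a 365-day year.
month_midpoints <- function() {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(len) - len / 2
}

#' Synthesize a full year of hourly operative temperature for one cell
#'
#' Daily mean temperature is the linear interpolation of the cell's twelve
#' monthly means across day-of-year at month midpoints (wrapping December to
#' January; 365-day year, no leap day). Each day carries a sinusoidal cycle of
#' half-range `diurnal_amplitude` peaking at 14:00, and the exposed model
#' gains `radiative_gain` degC during daylight hours (06:00-20:00).
#' Deterministic: no randomness enters the synthesizer.
#'
#' @param monthly_mean numeric length-12, monthly mean air temperatures degC.
#' @param params an [ectotherm_params()] object.
#' @return numeric vector of 8760 hourly operative temperatures (365 x 24),
#'   hour 0 to 23 within each day.
#' @export
synthesize_hourly_te <- function(monthly_mean, params = ectotherm_params()) {
  monthly_mean <- as.numeric(monthly_mean)
  if (length(monthly_mean) != 12L || anyNA(monthly_mean)) {
    vt_stop("missing_scenario",
            "need 12 non-missing monthly means for the scenario")
  }
  mid <- month_midpoints()
  # wrap the cycle so days before mid-January and after mid-December interpolate
  x <- c(mid[12] - 365, mid, mid[1] + 365)
  y <- c(monthly_mean[12], monthly_mean, monthly_mean[1])
  day <- seq_len(365)
  daily_mean <- stats::approx(x, y, xout = day - 0.5)$y
  hour <- 0:23
  cycle <- params$diurnal_amplitude * sin(2 * pi * (hour - 8) / 24)
  gain <- ifelse(hour >= 6 & hour < 20, params$radiative_gain, 0)
  as.numeric(outer(cycle + gain, daily_mean, `+`))  # 24 x 365, day-major
}

#' Annual restriction time h_r
#'
#' Number of hours in the year when operative temperature strictly exceeds
#' the upper set-point bound, i.e. hours too hot for surface activity.
#'
#' @param hourly_te numeric vector of length 8760.
#' @param t_set_upper upper set-point bound, degC.
#' @return integer count of hours, 0..8760.
#' @export
restriction_hours <- function(hourly_te, t_set_upper) {
  if (length(hourly_te) != 8760L) {
    vt_stop("malformed_series", "hourly series must have 8760 values")
  }
  sum(hourly_te > t_set_upper)
}

#' Per-cell, per-scenario restriction times and scenario summaries
#'
#' Runs the hourly synthesizer and [restriction_hours()] for every occurrence
#' cell under every scenario. Future pathways are averaged over their climate
#' models (equal weights) per cell before differencing against the current
#' scenario, and each scenario gets a cross-cell mean and standard error.
#'
#' @param climate climate data.frame (`cell_id`, `latitude`, `scenario_id`,
#'   `gcm_id`, `m01`..`m12`).
#' @param t_set_upper single upper bound degC, or a data.frame
#'   (`cell_id`, `t_set_upper`) for per-cell bounds.
#' @param params an [ectotherm_params()] object.
#' @return list of class `restriction_summary` with `cells` (per cell x
#'   scenario x GCM h_r), `per_cell` (GCM-averaged h_r + delta vs current) and
#'   `per_scenario` (mean, SE, delta of the GCM-averaged values).
#' @export
scenario_change_summary <- function(climate, t_set_upper,
                                    params = ectotherm_params()) {
  if (!"current" %in% climate$scenario_id) {
    vt_stop("invalid_config", "climate table must include the current scenario")
  }
  upper_of <- function(cell) {
    if (is.data.frame(t_set_upper)) {
      u <- t_set_upper$t_set_upper[match(cell, t_set_upper$cell_id)]
      if (anyNA(u)) vt_stop("invalid_config",
                            paste0("no t_set_upper for cell ", cell))
      u
    } else t_set_upper
  }
  cells <- climate[, c("cell_id", "latitude", "scenario_id", "gcm_id")]
  cells$h_r <- vapply(seq_len(nrow(climate)), function(i) {
    te <- synthesize_hourly_te(as.numeric(climate[i, month_cols]), params)
    as.numeric(restriction_hours(te, upper_of(climate$cell_id[i])))
  }, numeric(1))

  # equal-weight mean over GCMs within each cell x scenario
  agg <- stats::aggregate(h_r ~ cell_id + latitude + scenario_id, data = cells,
                          FUN = mean)
  cur <- agg[agg$scenario_id == "current", c("cell_id", "h_r")]
  names(cur)[2] <- "h_r_current"
  per_cell <- merge(agg, cur, by = "cell_id", sort = FALSE)
  per_cell$delta_vs_current <- per_cell$h_r - per_cell$h_r_current
  per_cell <- per_cell[order(per_cell$scenario_id, per_cell$cell_id), ]
  rownames(per_cell) <- NULL

  per_scenario <- do.call(rbind, lapply(split(per_cell, per_cell$scenario_id),
    function(d) {
      data.frame(scenario_id = d$scenario_id[1],
                 mean_h_r = mean(d$h_r),
                 se_h_r = stats::sd(d$h_r) / sqrt(nrow(d)),
                 mean_delta = mean(d$delta_vs_current),
                 n_cells = nrow(d), stringsAsFactors = FALSE)
    }))
  rownames(per_scenario) <- NULL
  structure(list(cells = cells, per_cell = per_cell,
                 per_scenario = per_scenario),
            class = "restriction_summary")
}

#' @export
print.restriction_summary <- function(x, ...) {
  cat("Annual activity-restriction time (h/year) by scenario\n")
  y <- x$per_scenario
  y$mean_h_r <- round(y$mean_h_r, 1)
  y$se_h_r <- round(y$se_h_r, 1)
  y$mean_delta <- round(y$mean_delta, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Compare per-cell restriction times between two scenarios
#'
#' Two-sample Wilcoxon rank-sum test (delegating to [wilcoxon_ranksum()]).
#'
#' @param h_r_a,h_r_b numeric vectors of per-cell h_r.
#' @return list with `W` and `p_value`.
#' @export
compare_scenarios <- function(h_r_a, h_r_b) wilcoxon_ranksum(h_r_a, h_r_b)

#' Latitude trend of restriction time
#'
#' Ordinary least-squares fit of per-cell h_r on latitude (delegating to
#' [ols_fit()]).
#'
#' @param h_r per-cell restriction hours.
#' @param latitude per-cell latitudes, degrees.
#' @return a `fit_result` (see [ols_fit()]).
#' @export
latitude_trend <- function(h_r, latitude) ols_fit(latitude, h_r)
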