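#' Deviation of a temperature from a set-point range
#'
#' Standard Hertz convention: zero inside the range, distance to the nearest
#' bound outside it; never negative.
#'
#' @param t temperature(s), degC.
#' @param lower,upper set-point bounds, degC, `lower <= upper`.
#' @return non-negative deviation(s), degC.
#' @export
deviation <- function(t, lower, upper) {
  if (any(lower > upper)) {
    vt_stop("invalid_bounds", "`lower` must not exceed `upper`")
  }
  pmax(lower - t, t - upper, 0)
}

# Percentile bootstrap CI of a mean, seed-deterministic.
bootstrap_mean_ci <- function(x, n_boot = 10000, seed = 1, conf = 0.95) {
  n <- length(x)
  means <- with_stage_seed(seed, "bootstrap", {
    vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
}

#' Accuracy of thermoregulation d_b
#'
#' Mean deviation of field body temperatures from the set-point range, with a
#' percentile-bootstrap confidence interval over records. Values near 0 mean
#' the animals hold their body temperature inside the preferred range.
#'
#' @param spots data.frame of spot records (column `t_b`; `individual_id`
#'   needed when `per_individual = TRUE`).
#' @param tset a `tset_estimate` (or list with `t_set_lower`, `t_set_upper`).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed bootstrap seed.
#' @param per_individual average deviations within individuals before pooling.
#' @return list with `mean`, `ci` (length 2), `n`.
#' @export
accuracy_db <- function(spots, tset, n_boot = 10000, seed = 1,
                        per_individual = FALSE) {
  if (is.null(spots) || nrow(spots) == 0L) {
    vt_stop("insufficient_data", "no body-temperature records")
  }
  devs <- deviation(spots$t_b, tset$t_set_lower, tset$t_set_upper)
  if (per_individual) {
    devs <- as.numeric(tapply(devs, spots$individual_id, mean))
  }
  list(mean = mean(devs),
       ci = bootstrap_mean_ci(devs, n_boot = n_boot, seed = seed),
       n = length(devs))
}

#' Thermal quality of the habitat d_e
#'
#' Mean deviation of operative temperatures from the set-point range over the
#' diurnal activity window (default 06:00 inclusive to 20:00 exclusive),
#' pooling all logger series of the population, with a percentile-bootstrap
#' confidence interval. Values near 0 mean a thermally ideal habitat.
#'
#' @param otm data.frame of operative-temperature readings (columns
#'   `datetime`, `t_e`).
#' @param tset a `tset_estimate`.
#' @param window numeric length-2 clock hours, `[start, end)`.
#' @param n_boot,seed bootstrap settings.
#' @return list with `mean`, `ci`, `n`.
#' @export
habitat_quality_de <- function(otm, tset, window = c(6, 20),
                               n_boot = 10000, seed = 1) {
  h <- hour_of_day(otm$datetime)
  keep <- h >= window[1] & h < window[2]
  if (!any(keep)) {
    vt_stop("insufficient_data", "no operative readings inside the window")
  }
  devs <- deviation(otm$t_e[keep], tset$t_set_lower, tset$t_set_upper)
  list(mean = mean(devs),
       ci = bootstrap_mean_ci(devs, n_boot = n_boot, seed = seed),
       n = length(devs))
}

#' Hertz effectiveness of thermoregulation E = 1 - d_b/d_e
#'
#' Approaches 1 for careful thermoregulators, 0 for thermoconformers; negative
#' values indicate active avoidance of thermally favourable conditions.
#'
#' @param d_b,d_e mean deviations, degC; `d_e` must be positive.
#' @return dimensionless E.
#' @export
effectiveness_hertz <- function(d_b, d_e) {
  if (any(d_e == 0)) {
    vt_stop("undefined_index",
            "E is undefined when d_e = 0 (thermally ideal habitat)")
  }
  1 - d_b / d_e
}

#' Blouin-Demers & Weatherhead effectiveness I = d_e - d_b
#'
#' Zero for thermoconformers, positive for thermoregulators (degC).
#'
#' @param d_b,d_e mean deviations, degC.
#' @return I, degC.
#' @export
effectiveness_bdw <- function(d_b, d_e) d_e - d_b

#' Thermal exploitation E_x
#'
#' Counts spot records whose body temperature lies inside the set-point range
#' and divides by the number of spot records whose time-matched operative
#' temperature overlaps the set-point range. A spot's operative temperature
#' "overlaps" when the nearest-in-time reading (within `match_tolerance`
#' minutes) of at least one of the population's sun/shade series lies inside
#' the range. The ratio is returned unclamped and can exceed 1 (animals inside
#' their preferred range more often than the habitat alone would allow).
#'
#' @param spots spot records of one population (`datetime`, `t_b`).
#' @param otm operative series of the same population (`datetime`,
#'   `microhabitat`, `t_e`).
#' @param tset a `tset_estimate`.
#' @param match_tolerance minutes; default 2.5 (half the 5-min cadence).
#' @return list with `e_x`, `n_tb_in`, `n_te_in`, `n`.
#' @export
exploitation_ex <- function(spots, otm, tset, match_tolerance = 2.5) {
  if (is.null(spots) || nrow(spots) == 0L) {
    vt_stop("insufficient_data", "no body-temperature records")
  }
  lower <- tset$t_set_lower
  upper <- tset$t_set_upper
  spot_s <- as.numeric(spots$datetime)
  te_in <- vapply(seq_len(nrow(spots)), function(i) {
    any(vapply(split(otm, otm$microhabitat), function(series) {
      dt <- abs(as.numeric(series$datetime) - spot_s[i])
      j <- which.min(dt)
      if (dt[j] > match_tolerance * 60) return(NA)
      series$t_e[j] >= lower && series$t_e[j] <= upper
    }, logical(1)), na.rm = TRUE)
  }, logical(1))
  matched <- vapply(seq_len(nrow(spots)), function(i) {
    any(abs(as.numeric(otm$datetime) - spot_s[i]) <= match_tolerance * 60)
  }, logical(1))
  if (!all(matched)) {
    vt_stop("insufficient_data",
            "some spot records have no operative reading within tolerance")
  }
  tb_in <- spots$t_b >= lower & spots$t_b <= upper
  if (sum(te_in) == 0L) {
    vt_stop("undefined_index",
            "E_x undefined: no matched operative temperature inside T_set")
  }
  list(e_x = sum(tb_in) / sum(te_in), n_tb_in = sum(tb_in),
       n_te_in = sum(te_in), n = nrow(spots))
}

#' Assemble the per-population index report
#'
#' One row per population with Tp, the set-point range, d_b and d_e with 95%
#' bootstrap CIs, E, I and E_x. Indices whose inputs are absent (e.g. a
#' population with operative loggers but no captured animals) are reported as
#' `NA`, not zero.
#'
#' @param spots spot-record data.frame (may omit some populations), or NULL.
#' @param otm operative-series data.frame covering every population.
#' @param tset_table population-level rows of [estimate_tset_table()].
#' @param n_boot,seed bootstrap settings.
#' @param window diurnal activity window for d_e.
#' @param per_individual passed to [accuracy_db()].
#' @return data.frame of class `index_report`.
#' @export
build_index_report <- function(spots, otm, tset_table, n_boot = 10000,
                               seed = 1, window = c(6, 20),
                               per_individual = FALSE) {
  pops <- tset_table[tset_table$level == "population", , drop = FALSE]
  if (nrow(pops) == 0L) {
    vt_stop("invalid_config", "tset_table has no population-level rows")
  }
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    p <- pops$population[i]
    ts <- list(t_set_lower = pops$t_set_lower[i],
               t_set_upper = pops$t_set_upper[i])
    sp <- if (!is.null(spots)) spots[spots$population == p, , drop = FALSE]
    ot <- otm[otm$population == p, , drop = FALSE]
    has_tb <- !is.null(sp) && nrow(sp) > 0L
    de <- habitat_quality_de(ot, ts, window = window, n_boot = n_boot,
                             seed = seed)
    if (has_tb) {
      db <- accuracy_db(sp, ts, n_boot = n_boot, seed = seed,
                        per_individual = per_individual)
      # a habitat whose matched T_e never overlaps T_set leaves E_x undefined;
      # the report carries that as NA rather than aborting
      ex <- tryCatch(exploitation_ex(sp, ot, ts),
                     vipertherm_undefined_index = function(e) {
                       list(e_x = NA_real_)
                     })
      e_h <- effectiveness_hertz(db$mean, de$mean)
      i_b <- effectiveness_bdw(db$mean, de$mean)
    } else {
      db <- list(mean = NA_real_, ci = c(NA_real_, NA_real_), n = 0L)
      ex <- list(e_x = NA_real_)
      e_h <- NA_real_
      i_b <- NA_real_
    }
    data.frame(
      population = p, t_p = pops$t_p[i],
      t_set_lower = ts$t_set_lower, t_set_upper = ts$t_set_upper,
      d_b = db$mean, d_b_lo = db$ci[1], d_b_hi = db$ci[2],
      d_e = de$mean, d_e_lo = de$ci[1], d_e_hi = de$ci[2],
      e_hertz = e_h, i_bdw = i_b, e_x = ex$e_x,
      n_tb = db$n, n_te = de$n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_report", "data.frame")
  out
}

#' @export
print.index_report <- function(x, digits = 2, ...) {
  cat("Thermoregulation indices by population\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
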