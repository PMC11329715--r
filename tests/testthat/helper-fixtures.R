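# Shared fixture builders; everything is generated in code, nothing on disk.

small_configs <- function(n = c(4L, 6L), tp_sd_within = 2) {
  data.frame(
    name = c("N1", "S1")[seq_along(n)],
    latitude = c(40.5, 38.8)[seq_along(n)],
    base_tp = c(30, 27.5)[seq_along(n)],
    svl_mean = 270, svl_sd = 30,
    tp_sd_between = 1.2, tp_sd_within = tp_sd_within,
    n_individuals = n, n_otm_days = 2L,
    stringsAsFactors = FALSE
  )
}

# OTM series at 5-min cadence with prescribed values, one microhabitat.
make_otm <- function(t_e, population = "P", microhabitat = "sun",
                     start_day = 1L) {
  n <- length(t_e)
  data.frame(
    population = population, microhabitat = microhabitat,
    datetime = as.POSIXct("2017-08-01", tz = "UTC") +
      (start_day - 1L) * 86400 + (seq_len(n) - 1L) * 300,
    t_e = t_e, stringsAsFactors = FALSE
  )
}

make_spots <- function(t_b, datetime, population = "P") {
  data.frame(
    individual_id = sprintf("ind%02d", seq_along(t_b)),
    population = population, datetime = datetime, t_b = t_b,
    microhabitat = "sun", latitude = 39, svl_mm = 270, sex = "female",
    gravid = FALSE, stringsAsFactors = FALSE
  )
}

tset_fix <- function(lower = 25, upper = 35, t_p = 30) {
  list(t_p = t_p, t_set_lower = lower, t_set_upper = upper)
}

# Explicit-loop recomputation of the full index suite; deliberately written
# with scalar if/else control flow so it is independent of the vectorized path.
brute_force_indices <- function(spots, otm, lower, upper, window = c(6, 20),
                                tol_min = 2.5) {
  dev1 <- function(t) {
    if (t < lower) lower - t else if (t > upper) t - upper else 0
  }
  db_sum <- 0
  for (i in seq_len(nrow(spots))) db_sum <- db_sum + dev1(spots$t_b[i])
  d_b <- db_sum / nrow(spots)

  de_vals <- c()
  for (i in seq_len(nrow(otm))) {
    h <- as.numeric(format(otm$datetime[i], "%H", tz = "UTC")) +
      as.numeric(format(otm$datetime[i], "%M", tz = "UTC")) / 60
    if (h >= window[1] && h < window[2]) de_vals <- c(de_vals, dev1(otm$t_e[i]))
  }
  d_e <- mean(de_vals)

  n_tb_in <- 0
  n_te_in <- 0
  for (i in seq_len(nrow(spots))) {
    if (spots$t_b[i] >= lower && spots$t_b[i] <= upper) {
      n_tb_in <- n_tb_in + 1
    }
    overlap <- FALSE
    for (micro in unique(otm$microhabitat)) {
      ser <- otm[otm$microhabitat == micro, ]
      gaps <- abs(as.numeric(ser$datetime) - as.numeric(spots$datetime[i]))
      j <- which.min(gaps)
      if (gaps[j] <= tol_min * 60 &&
          ser$t_e[j] >= lower && ser$t_e[j] <= upper) {
        overlap <- TRUE
      }
    }
    if (overlap) n_te_in <- n_te_in + 1
  }
  list(d_b = d_b, d_e = d_e, e = 1 - d_b / d_e, i = d_e - d_b,
       e_x = if (n_te_in > 0) n_tb_in / n_te_in else NA_real_)
}
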