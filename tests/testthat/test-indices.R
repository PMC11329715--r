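test_that("deviation follows the zero-inside, distance-outside convention", {
  expect_equal(deviation(30, 25, 35), 0)
  expect_equal(deviation(40, 25, 35), 5)
  expect_equal(deviation(20, 25, 35), 5)
  expect_equal(deviation(c(24, 25, 35, 36), 25, 35), c(1, 0, 0, 1))
  expect_error(deviation(30, 35, 25), class = "vipertherm_invalid_bounds")
})

test_that("d_b is the mean deviation with a percentile-bootstrap CI", {
  ts <- tset_fix(25, 34)
  sp <- make_spots(c(36, 38), as.POSIXct("2017-08-01 10:00:00", tz = "UTC") +
                     c(0, 300))
  db <- accuracy_db(sp, ts, n_boot = 500, seed = 1)
  expect_equal(db$mean, 3)
  ts <- tset_fix(25, 35)

  # all inside the range: zero mean and zero-width CI
  sp0 <- make_spots(c(30, 31, 32), as.POSIXct("2017-08-01 10:00:00",
                                              tz = "UTC") + (0:2) * 300)
  db0 <- accuracy_db(sp0, ts, n_boot = 500, seed = 1)
  expect_equal(db0$mean, 0)
  expect_equal(db0$ci, c(0, 0))

  # CI brackets the point estimate
  set.seed(2)
  spn <- make_spots(runif(40, 20, 40),
                    as.POSIXct("2017-08-01 08:00:00", tz = "UTC") +
                      (0:39) * 300)
  dbn <- accuracy_db(spn, ts, n_boot = 2000, seed = 3)
  expect_true(dbn$ci[1] <= dbn$mean && dbn$mean <= dbn$ci[2])

  expect_error(accuracy_db(sp[0, ], ts), class = "vipertherm_insufficient_data")
})

test_that("d_e uses the [06:00, 20:00) window, inclusive start exclusive end", {
  ts <- tset_fix(25, 35)
  base <- as.POSIXct("2017-08-01", tz = "UTC")
  otm <- data.frame(
    population = "P", microhabitat = "sun",
    datetime = base + c(5 * 3600 + 55 * 60, 6 * 3600, 12 * 3600,
                        19 * 3600 + 55 * 60, 20 * 3600, 20 * 3600 + 300),
    t_e = c(100, 25, 27, 35, 100, 100)  # the 100s sit outside the window
  )
  de <- habitat_quality_de(otm, ts, n_boot = 200, seed = 1)
  expect_equal(de$n, 3L)
  expect_equal(de$mean, 0)

  # hand-enumerated deviations {0, 2, 4} average to 2
  otm2 <- make_otm(c(30, 37, 21), start_day = 1)
  otm2$datetime <- base + (10:12) * 3600
  de2 <- habitat_quality_de(otm2, ts, n_boot = 200, seed = 1)
  expect_equal(de2$mean, 2)

  night <- make_otm(30)
  night$datetime <- base + 2 * 3600
  expect_error(habitat_quality_de(night, ts),
               class = "vipertherm_insufficient_data")
})

test_that("E and I arithmetic, including the published example values", {
  expect_equal(round(effectiveness_hertz(1.42, 5.89), 2), 0.76)
  expect_equal(effectiveness_hertz(0, 5.51), 1)
  expect_equal(effectiveness_hertz(3, 3), 0)
  expect_error(effectiveness_hertz(1, 0), class = "vipertherm_undefined_index")
  expect_equal(effectiveness_bdw(1.42, 5.89), 4.47)
  expect_equal(effectiveness_bdw(0, 5.51), 5.51)
  expect_equal(effectiveness_bdw(3, 3), 0)
})

test_that("both temperature deviations are translation invariant", {
  set.seed(4)
  tb <- runif(30, 18, 42)
  base <- as.POSIXct("2017-08-01 10:00:00", tz = "UTC")
  for (c0 in c(-3, 2.5)) {
    sp1 <- make_spots(tb, base + seq_along(tb) * 300)
    sp2 <- make_spots(tb + c0, base + seq_along(tb) * 300)
    d1 <- accuracy_db(sp1, tset_fix(25, 35), n_boot = 200, seed = 9)
    d2 <- accuracy_db(sp2, tset_fix(25 + c0, 35 + c0), n_boot = 200, seed = 9)
    expect_equal(d1$mean, d2$mean, tolerance = 1e-12)
  }
})

test_that("E_x counts set-point occupancy against matched habitat overlap", {
  # 10 spots at exact logger times; 6 t_b inside T_set, matched T_e inside
  # for exactly 2 of the 10 -> E_x = 6/2 = 3, unclamped above 1
  ts <- tset_fix(25, 35)
  base <- as.POSIXct("2017-08-01 10:00:00", tz = "UTC")
  times <- base + (0:9) * 300
  sun <- make_otm(c(30, 30, rep(40, 8)), microhabitat = "sun")
  sun$datetime <- times
  shade <- make_otm(rep(20, 10), microhabitat = "shade")
  shade$datetime <- times
  otm <- rbind(sun, shade)
  spots <- make_spots(c(rep(30, 6), rep(20, 4)), times)
  ex <- exploitation_ex(spots, otm, ts)
  expect_equal(ex$e_x, 3)
  expect_equal(ex$n_tb_in, 6L)
  expect_equal(ex$n_te_in, 2L)

  # all inside, all overlapping -> 1; none inside -> 0
  sun_in <- sun
  sun_in$t_e <- 30
  expect_equal(exploitation_ex(make_spots(rep(30, 10), times),
                               rbind(sun_in, shade), ts)$e_x, 1)
  expect_equal(exploitation_ex(make_spots(rep(20, 10), times),
                               rbind(sun_in, shade), ts)$e_x, 0)

  # no matched T_e inside T_set at all -> undefined
  sun_out <- sun
  sun_out$t_e <- 45
  expect_error(exploitation_ex(make_spots(rep(30, 3), times[1:3]),
                               rbind(sun_out, shade), ts),
               class = "vipertherm_undefined_index")

  # a spot far from any reading violates the matching precondition
  far <- make_spots(30, base + 86400 * 30)
  expect_error(exploitation_ex(far, otm, ts),
               class = "vipertherm_insufficient_data")
})

test_that("vectorized indices match the explicit-loop oracle exactly", {
  set.seed(11)
  base <- as.POSIXct("2017-08-01", tz = "UTC")
  for (rep in 1:20) {
    n_sp <- sample(3:50, 1)
    n_te <- 60L
    times <- base + 8 * 3600 + (0:(n_te - 1)) * 300
    otm <- rbind(
      {o <- make_otm(runif(n_te, 15, 45)); o$datetime <- times; o},
      {o <- make_otm(runif(n_te, 10, 30), microhabitat = "shade")
       o$datetime <- times; o}
    )
    spots <- make_spots(runif(n_sp, 18, 42),
                        sample(times, n_sp, replace = TRUE))
    lower <- runif(1, 24, 27)
    upper <- lower + runif(1, 4, 9)
    ts <- tset_fix(lower, upper)

    oracle <- brute_force_indices(spots, otm, lower, upper)
    db <- accuracy_db(spots, ts, n_boot = 100, seed = 1)
    de <- habitat_quality_de(otm, ts, n_boot = 100, seed = 1)
    expect_identical(db$mean, oracle$d_b)
    expect_identical(de$mean, oracle$d_e)
    expect_identical(effectiveness_hertz(db$mean, de$mean), oracle$e)
    expect_identical(effectiveness_bdw(db$mean, de$mean), oracle$i)
    if (!is.na(oracle$e_x)) {
      expect_identical(exploitation_ex(spots, otm, ts)$e_x, oracle$e_x)
    }
  }
})

test_that("index report flags missing inputs as NA and stays self-consistent", {
  r <- generate_roster(small_configs(), seed = 31)
  tr <- generate_gradient_trials(r, seed = 31)
  fc <- generate_field_campaign(r, n_days = 2, seed = 31,
                                skip_tb_populations = "S1")
  tab <- estimate_tset_table(tr)
  rep_ <- build_index_report(fc$spots, fc$otm, tab, n_boot = 300, seed = 31)
  expect_equal(nrow(rep_), 2L)
  s1 <- rep_[rep_$population == "S1", ]
  expect_true(is.na(s1$d_b) && is.na(s1$e_hertz) && is.na(s1$i_bdw) &&
                is.na(s1$e_x))
  expect_false(is.na(s1$d_e))
  n1 <- rep_[rep_$population == "N1", ]
  expect_false(any(is.na(n1[c("d_b", "d_e", "e_hertz", "i_bdw", "e_x")])))
  # internal consistency: I = d_e - d_b and E = 1 - d_b/d_e exactly
  expect_identical(n1$i_bdw, n1$d_e - n1$d_b)
  expect_identical(n1$e_hertz, 1 - n1$d_b / n1$d_e)
})
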