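test_that("constant-temperature accumulation matches degree-day arithmetic", {
  # at 18.3 degC the A. mali DD model runs at 10/254.8 per day, so the
  # remaining half generation (0.5 -> 1.0) takes 12.74 days: first daily
  # timestep with D >= 1 is day 13, and G2 (one further full generation,
  # 25.48 days) lands 26 daily steps later
  ts <- constant_series(18.3, days = 60)
  fc <- accumulate_development(amali_model("linear_dd"), ts,
                               start_fraction = 0.5)
  ev <- predict_event_dates(fc, c("G1 adults" = 1, "G2 adults" = 2))
  expect_equal(ev$date[1], as.Date("2018-01-13"))
  expect_equal(as.numeric(ev$date[2] - ev$date[1]), 26)
  # first-crossing convention: D < threshold strictly before the event date
  traj <- fc$trajectory
  expect_lt(max(traj$cum_dev[traj$timestamp < ev$date[1]]), 1)
  expect_gte(traj$cum_dev[traj$timestamp == ev$date[1]], 1)
})

test_that("cold series accrue exactly zero development", {
  ts <- constant_series(4.0, days = 90)
  for (m in list(amali_model(), elanigerum_model(),
                 amali_model("linear_dd"))) {
    fc <- accumulate_development(m, ts, start_fraction = 0.5)
    expect_true(all(fc$trajectory$cum_dev == 0.5))
    ev <- predict_event_dates(fc, c("G1 adults" = 1))
    expect_false(ev$reached)
    expect_true(is.na(ev$date))
  }
})

test_that("trajectories are monotone and clamp contributions to zero", {
  set.seed(11)
  for (rep in 1:5) {
    temps <- runif(200, -10, 45)
    ts <- temperature_series(
      seq(as.Date("2018-01-01"), by = "day", length.out = 200), temps)
    m <- if (rep %% 2) amali_model() else elanigerum_model()
    fc <- accumulate_development(m, ts)
    expect_true(all(diff(fc$trajectory$cum_dev) >= 0))
    inc <- c(fc$trajectory$cum_dev[1], diff(fc$trajectory$cum_dev))
    cutoff <- resolve_upper_cutoff(m)
    dead <- temps <= m$lower_threshold | temps >= cutoff
    expect_true(all(inc[dead] == 0))
  }
})

test_that("hourly and daily resolutions give consistent event dates", {
  # a smooth series: seasonal cycle only. A diurnal cycle makes the two
  # resolutions genuinely diverge (rate clamping and curvature act on the
  # within-day extremes), which is a documented modelling choice, not a bug.
  cl <- climate_params(noise_sd = 0, diurnal_amplitude = 0)
  hourly <- generate_temperature_series(cl, seed = 1)
  dates <- as.Date(hourly$timestamp, tz = "UTC")
  daily_mean <- tapply(hourly$temperature_c, dates, mean)
  daily <- temperature_series(as.Date(names(daily_mean)),
                              as.numeric(daily_mean))
  for (m in list(amali_model(), elanigerum_model())) {
    eh <- predict_event_dates(
      accumulate_development(m, hourly, 0.5), c(ev = 1))
    ed <- predict_event_dates(
      accumulate_development(m, daily, 0.5), c(ev = 1))
    expect_lte(abs(as.numeric(eh$date - ed$date)), 1)
  }
})

test_that("series validation flags gaps, order and window problems", {
  ts <- seq(as.POSIXct("2018-01-01 00:00", tz = "UTC"), by = 3600,
            length.out = 48)
  # 4-hour gap: filled by interpolation
  keep <- -(10:12)
  filled <- temperature_series(ts[keep], seq(0, 9.4, by = 0.2)[keep])
  expect_equal(nrow(filled), 48)
  expect_equal(filled$temperature_c, seq(0, 9.4, by = 0.2))
  # 10-hour gap: refused
  expect_error(temperature_series(ts[-(10:18)], rnorm(39, 5)),
               "fill window")
  expect_error(temperature_series(rev(ts), rnorm(48, 5)), "increasing")
  expect_error(temperature_series(ts, rep(99, 48)), "-40..55")
  late <- constant_series(15, days = 30)
  late$timestamp <- late$timestamp + 40
  expect_error(accumulate_development(amali_model(), late),
               "1 January")
})

test_that("cohort simulation degenerates to the deterministic forecast at sd = 0", {
  ts <- constant_series(16, days = 120)
  events <- c("G1 adults" = 1, "G2 adults" = 2)
  coh <- simulate_individuals(amali_model(), ts, n = 10, sd = 0, seed = 3,
                              start_fraction = 0.5, events = events)
  det <- predict_event_dates(
    accumulate_development(amali_model(), ts, 0.5), events)
  for (j in seq_along(events)) {
    expect_identical(unique(coh$individual_dates[[j]]), det$date[j])
  }
  expect_identical(coh$events$first, det$date)
  expect_identical(coh$events$median, det$date)
})

test_that("stochastic cohort brackets the deterministic date", {
  cl <- climate_params(year = 2018)
  series <- generate_temperature_series(cl, seed = 8)
  coh <- simulate_individuals(amali_model(), series, n = 50, sd = 0.015,
                              seed = 99, start_fraction = 0.5,
                              events = c("G1 adults" = 1))
  det <- coh$deterministic$date[1]
  expect_lte(coh$events$first[1], det)
  expect_lte(abs(as.numeric(coh$events$median[1] - det)), 2)
  expect_lte(coh$events$q10[1], coh$events$median[1])
  expect_lte(coh$events$median[1], coh$events$q90[1])
  # reproducibility
  coh2 <- simulate_individuals(amali_model(), series, n = 50, sd = 0.015,
                               seed = 99, start_fraction = 0.5,
                               events = c("G1 adults" = 1))
  expect_identical(coh$individual_dates, coh2$individual_dates)
})

test_that("cohort-first date is stochastically earlier for larger cohorts", {
  # extreme-value monotonicity: over replicates, the mean first-crossing
  # date of n = 40 cohorts is no later than that of n = 10 cohorts
  ts <- constant_series(14, days = 150)
  first_of <- function(n, seed) {
    coh <- simulate_individuals(amali_model("linear_dd"), ts, n = n,
                                sd = 0.015, seed = seed,
                                start_fraction = 0.5, events = c(ev = 1))
    as.numeric(coh$events$first[1])
  }
  f10 <- vapply(1:200, function(s) first_of(10, s), 0)
  f40 <- vapply(1:200, function(s) first_of(40, 10000 + s), 0)
  expect_lte(mean(f40), mean(f10))
})

test_that("stage-ratio initialization fractions are exact", {
  ratio <- c(egg = 1, larva = 4, pupa = 5)
  expect_identical(stage_fraction_from_ratio(ratio, c("egg", "larva")), 0.5)
  expect_identical(stage_fraction_from_ratio(ratio, character()), 0)
  expect_identical(stage_fraction_from_ratio(ratio, "egg"), 0.1)
  expect_error(stage_fraction_from_ratio(ratio, c("egg", "imago")),
               "unknown stage")
  expect_error(stage_fraction_from_ratio(ratio, c("larva")), "prefix")
  expect_error(stage_fraction_from_ratio(c(1, 4, 5), "egg"), "named")
})

test_that("simulation inputs are validated", {
  ts <- constant_series(15, days = 10)
  expect_error(simulate_individuals(amali_model(), ts, n = 0, seed = 1,
                                    events = c(ev = 1)), "n")
  expect_error(simulate_individuals(amali_model(), ts, n = 5,
                                    events = c(ev = 1)), "seed")
  fc <- accumulate_development(amali_model(), ts)
  expect_error(predict_event_dates(fc, c(a = 2, b = 1)), "increasing")
  expect_error(accumulate_development(amali_model(), ts,
                                      start_fraction = 1.2), "\\[0, 1\\)")
})
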