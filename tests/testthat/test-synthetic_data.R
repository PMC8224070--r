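test_that("degenerate parameters give a constant series", {
  cl <- climate_params(annual_mean = 15, seasonal_amplitude = 0,
                       diurnal_amplitude = 0, noise_sd = 0)
  s <- generate_temperature_series(cl, seed = 1)
  expect_true(all(s$temperature_c == 15))
  expect_equal(nrow(s), 8760)
  expect_identical(attr(s, "resolution"), "hourly")
})

test_that("seeded generation is reproducible and seasonal structure is right", {
  cl <- climate_params()
  s1 <- generate_temperature_series(cl, seed = 42)
  s2 <- generate_temperature_series(cl, seed = 42)
  expect_identical(s1, s2)
  # April monthly mean across seeds sits in the temperate-spring band
  april_means <- vapply(1:25, function(s) {
    series <- generate_temperature_series(cl, seed = s)
    mo <- format(series$timestamp, "%m")
    mean(series$temperature_c[mo == "04"])
  }, 0)
  expect_true(all(april_means > 8 & april_means < 12))
  # January is the coldest month in expectation
  mo <- format(s1$timestamp, "%m")
  mm <- tapply(s1$temperature_c, mo, mean)
  expect_identical(names(which.min(mm)), "01")
})

test_that("ar_coef = 0 leaves no lag-1 autocorrelation", {
  cl <- climate_params(seasonal_amplitude = 0, diurnal_amplitude = 0,
                       ar_coef = 0, noise_sd = 1)
  s <- generate_temperature_series(cl, seed = 9)
  resid <- s$temperature_c - mean(s$temperature_c)
  rho <- stats::cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(rho), 0.05)
})

test_that("trap censoring brackets the true date with the expected error", {
  true <- as.Date("2018-04-25")
  daily <- trap_protocol(interval_days = 1)
  o <- generate_trap_observations(true, daily, seed = 1)
  expect_identical(o$observed, true)
  expect_identical(o$first_positive, true)

  weekly <- trap_protocol(interval_days = 7)
  for (s in 1:20) {
    o <- generate_trap_observations(true, weekly, seed = s)
    expect_true(o$last_negative < true)
    expect_true(o$first_positive >= true)
    expect_true(o$observed >= o$last_negative &
                  o$observed <= o$first_positive)
    expect_lte(as.numeric(o$first_positive - o$last_negative), 7)
  }

  # mean |observed - true| over many seeds approximates interval / 4
  errs <- vapply(1:500, function(s) {
    truth <- as.Date("2018-04-10") + (s %% 40)
    abs(as.numeric(generate_trap_observations(
      truth, trap_protocol(c(3, 7)), seed = s)$observed - truth))
  }, 0)
  expect_gt(mean(errs), 0.7)   # average interval 5 -> about 1.25
  expect_lt(mean(errs), 1.9)
  expect_error(generate_trap_observations(as.Date("2018-03-01"),
                                          weekly, seed = 1), "season")
})

test_that("noise-free daily-check campaigns validate perfectly", {
  cl <- climate_params(resolution = "daily")
  sc <- end_to_end_scenario(climate = cl,
                            protocol = trap_protocol(interval_days = 1),
                            n_years = 6, seed = 4, start_year = 2014)
  for (tab in sc) {
    expect_true(all(tab$observed == tab$predicted))
    r <- regress_observed_on_predicted(tab)
    expect_equal(r$r_squared, 1, tolerance = 1e-9)
    expect_equal(r$slope, 1, tolerance = 1e-9)
    expect_identical(r$mae, 0)
  }
})

test_that("validation error grows with the trap-check interval", {
  cl <- climate_params(resolution = "daily")
  mean_mae <- function(interval) {
    maes <- vapply(1:4, function(s) {
      sc <- end_to_end_scenario(climate = cl,
                                protocol = trap_protocol(interval),
                                n_years = 8, seed = 100 * s,
                                start_year = 2010)
      mean(vapply(sc, function(tab) error_metrics(tab)$mae, 0))
    }, 0)
    mean(maes)
  }
  m1 <- mean_mae(1); m4 <- mean_mae(4); m7 <- mean_mae(7)
  expect_identical(m1, 0)
  expect_lt(m1, m4)
  expect_lt(m4, m7)
})

test_that("a 3-7 day campaign stays inside the censoring error budget", {
  sc <- end_to_end_scenario(climate = climate_params(resolution = "daily"),
                            protocol = trap_protocol(c(3, 7)),
                            n_years = 11, seed = 77, start_year = 2010)
  # pooled over the three events (33 event-years) so the budget check is
  # not dominated by the luck of a single 11-year table
  errs <- unlist(lapply(sc, function(tab) {
    ok <- !is.na(tab$observed) & !is.na(tab$predicted)
    abs(as.numeric(tab$observed[ok] - tab$predicted[ok]))
  }))
  expect_gte(mean(errs), 1)
  expect_lte(mean(errs), 4)
  expect_true(all(errs <= 3.5 + 0.5))  # midpoint censoring bound + rounding
})

test_that("uniform warming strictly advances every event date", {
  cl <- climate_params(resolution = "daily")
  warm <- climate_params(annual_mean = cl$annual_mean + 2,
                         resolution = "daily")
  base <- end_to_end_scenario(climate = cl, n_years = 5, seed = 31,
                              protocol = trap_protocol(1))
  warmer <- end_to_end_scenario(climate = warm, n_years = 5, seed = 31,
                                protocol = trap_protocol(1))
  for (nm in names(base)) {
    d0 <- base[[nm]]$predicted
    d1 <- warmer[[nm]]$predicted
    ok <- !is.na(d0) & !is.na(d1)
    expect_true(all(d1[ok] < d0[ok]))
  }
})
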