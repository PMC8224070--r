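#' Synthetic orchard climate parameters
#'
#' Describes the statistical structure of a temperate-orchard temperature
#' series: an annual mean, a seasonal sine (minimum in mid-January by
#' default), a diurnal sine (hourly resolution only, warmest at 14:00), and
#' stationary AR(1) noise capturing multi-day weather systems. Defaults
#' target the Haspengouw fruit region of eastern Belgium, where a typical
#' year has an annual mean near 10.5 degrees Celsius, winter/summer monthly
#' means near 3 and 18, and a diurnal range of roughly 8 degrees.
#'
#' @param annual_mean annual mean temperature, degrees Celsius.
#' @param seasonal_amplitude half-range of the seasonal cycle, degrees.
#' @param seasonal_phase_day day of year of the seasonal minimum.
#' @param diurnal_amplitude half-range of the diurnal cycle, degrees
#'   (ignored at daily resolution).
#' @param ar_coef AR(1) coefficient of the noise, `|ar_coef| < 1`; default
#'   0.95 hourly (decorrelation time about half a day), 0.7 daily.
#' @param noise_sd innovation standard deviation of the AR(1) noise,
#'   degrees; default 0.5 hourly, 1.5 daily (stationary sd about 1.6 and
#'   2.1).
#' @param year calendar year the series covers.
#' @param resolution `"hourly"` or `"daily"`.
#' @return a list of class `climate_params`.
#' @export
climate_params <- function(annual_mean = 10.5, seasonal_amplitude = 7.5,
                           seasonal_phase_day = 15, diurnal_amplitude = 4,
                           ar_coef = NULL, noise_sd = NULL, year = 2018,
                           resolution = c("hourly", "daily")) {
  resolution <- match.arg(resolution)
  if (is.null(ar_coef)) ar_coef <- if (resolution == "hourly") 0.95 else 0.7
  if (is.null(noise_sd)) noise_sd <- if (resolution == "hourly") 0.5 else 1.5
  if (seasonal_amplitude < 0 || diurnal_amplitude < 0 || noise_sd < 0) {
    stop("amplitudes and noise sd must be >= 0", call. = FALSE)
  }
  if (abs(ar_coef) >= 1) stop("|ar_coef| must be < 1", call. = FALSE)
  structure(
    list(annual_mean = annual_mean, seasonal_amplitude = seasonal_amplitude,
         seasonal_phase_day = seasonal_phase_day,
         diurnal_amplitude = diurnal_amplitude, ar_coef = ar_coef,
         noise_sd = noise_sd, year = as.integer(year),
         resolution = resolution),
    class = "climate_params"
  )
}

#' Generate a synthetic temperature series
#'
#' Produces one calendar year of hourly or daily temperatures:
#' `T(t) = mean + seasonal sine + diurnal sine + AR(1) noise`, reproducible
#' per seed. The AR(1) process is started from its stationary distribution,
#' so the noise is statistically homogeneous across the year.
#'
#' @param params a [climate_params()].
#' @param seed integer seed.
#' @return a [temperature_series()].
#' @export
generate_temperature_series <- function(params, seed) {
  stopifnot(inherits(params, "climate_params"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  yr <- params$year
  jan1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", yr), tz = "UTC")
  if (params$resolution == "hourly") {
    end <- as.POSIXct(sprintf("%d-12-31 23:00:00", yr), tz = "UTC")
    ts <- seq(jan1, end, by = 3600)
    doy <- as.numeric(ts - jan1, units = "days") + 1
    hour <- as.numeric(format(ts, "%H"))
    diurnal <- -params$diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
  } else {
    end <- as.Date(sprintf("%d-12-31", yr))
    ts <- seq(as.Date(sprintf("%d-01-01", yr)), end, by = "day")
    doy <- as.numeric(ts - as.Date(sprintf("%d-01-01", yr))) + 1
    diurnal <- 0
  }
  seasonal <- -params$seasonal_amplitude *
    cos(2 * pi * (doy - params$seasonal_phase_day) / 365.25)
  n <- length(ts)
  set.seed(seed)
  if (params$noise_sd > 0) {
    innov <- stats::rnorm(n, 0, params$noise_sd)
    init <- stats::rnorm(1, 0,
                         params$noise_sd / sqrt(1 - params$ar_coef^2))
    noise <- as.numeric(stats::filter(innov, params$ar_coef,
                                      method = "recursive", init = init))
  } else {
    noise <- numeric(n)
  }
  temperature_series(ts, params$annual_mean + seasonal + diurnal + noise,
                     resolution = params$resolution)
}

#' Trap monitoring protocol
#'
#' Describes how sticky-trap (or visual) monitoring censors a true event
#' date: checks are performed at a 3-7 day interval over the season, an
#' event is detected at the first check on or after its true date, and the
#' recorded observation is the midpoint of the bracketing checks.
#'
#' @param interval_days either a single check interval in days, or a length-2
#'   range `c(min, max)` from which each successive interval is drawn
#'   uniformly (integers); must lie within 1..7.
#' @param season_start,season_end month-day strings (`"mm-dd"`) delimiting
#'   the monitoring season.
#' @param miss_prob probability that a check on or after the true date fails
#'   to detect the event (recorded as a negative check); default 0, i.e.
#'   detection is perfect at the first qualifying check.
#' @return a list of class `trap_protocol`.
#' @export
trap_protocol <- function(interval_days = c(3, 7), season_start = "04-01",
                          season_end = "07-31", miss_prob = 0) {
  if (!length(interval_days) %in% c(1, 2) ||
      any(interval_days < 1 | interval_days > 7)) {
    stop("'interval_days' must be a value or range within 1..7 days",
         call. = FALSE)
  }
  if (length(interval_days) == 2 && interval_days[1] > interval_days[2]) {
    stop("'interval_days' range must be increasing", call. = FALSE)
  }
  if (miss_prob < 0 || miss_prob >= 1) {
    stop("'miss_prob' must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(interval_days = as.integer(interval_days),
         season_start = season_start, season_end = season_end,
         miss_prob = miss_prob),
    class = "trap_protocol"
  )
}

#' Interval-censor a true event date through trap monitoring
#'
#' Draws a schedule of check dates over the season (starting with a negative
#' check at the season start), detects the event at the first check on or
#' after its true date, and returns the bracketing checks plus the derived
#' observed date. A 1-day bracket pins the event exactly (the observed date
#' is the detection day); wider brackets use the midpoint rounded toward the
#' earlier day, matching [mean_observation_date()].
#'
#' @param true_event_date `Date`, the true event date; must lie strictly
#'   inside the monitoring season.
#' @param protocol a [trap_protocol()].
#' @param seed integer seed (drives the interval jitter and any misses).
#' @return list with `last_negative`, `first_positive`, `observed`
#'   (all `Date`).
#' @export
generate_trap_observations <- function(true_event_date, protocol, seed) {
  stopifnot(inherits(protocol, "trap_protocol"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  true_event_date <- as.Date(true_event_date)
  yr <- format(true_event_date, "%Y")
  s0 <- as.Date(paste0(yr, "-", protocol$season_start))
  s1 <- as.Date(paste0(yr, "-", protocol$season_end))
  if (is.na(true_event_date) || true_event_date <= s0 ||
      true_event_date > s1) {
    stop("true event date must lie inside the monitoring season (",
         format(s0), " .. ", format(s1), ")", call. = FALSE)
  }
  set.seed(seed)
  iv <- protocol$interval_days
  checks <- s0
  while (checks[length(checks)] < s1) {
    step <- if (length(iv) == 1) iv else sample(seq(iv[1], iv[2]), 1L)
    checks <- c(checks, checks[length(checks)] + step)
  }
  last_negative <- max(checks[checks < true_event_date])
  candidates <- checks[checks >= true_event_date]
  first_positive <- as.Date(NA)
  for (ck in seq_along(candidates)) {
    if (protocol$miss_prob == 0 ||
        stats::runif(1) >= protocol$miss_prob) {
      first_positive <- candidates[ck]
      break
    }
    last_negative <- candidates[ck]
  }
  if (is.na(first_positive)) {
    stop("event never detected before season end (all checks missed)",
         call. = FALSE)
  }
  gap <- as.numeric(first_positive - last_negative)
  observed <- if (gap == 1) first_positive
              else last_negative + floor(gap / 2)
  list(last_negative = last_negative, first_positive = first_positive,
       observed = observed)
}

#' Simulate a multi-year monitoring campaign end to end
#'
#' For each synthetic year: generate a weather series, run the phenology
#' engine for both species to obtain true (= predicted) event dates, censor
#' each reached event through the trap protocol, and assemble validation
#' tables ready for [regress_observed_on_predicted()]. Events not reached
#' in a cold year are recorded as `NA` rows.
#'
#' @param climate a [climate_params()] (its `year` field is overridden per
#'   simulated year).
#' @param amali,elanigerum [rate_model][make_polynomial_model]s for the two
#'   species.
#' @param protocol a [trap_protocol()].
#' @param n_years number of monitoring years.
#' @param seed integer master seed; per-year and per-event seeds are derived
#'   from it.
#' @param start_year first calendar year.
#' @return list of three [validation_table()]s: `g1`, `g2`, `migration`.
#' @export
end_to_end_scenario <- function(climate = climate_params(),
                                amali = amali_model(),
                                elanigerum = elanigerum_model(),
                                protocol = trap_protocol(),
                                n_years = 11, seed, start_year = 2010) {
  stopifnot(inherits(climate, "climate_params"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  years <- seq(start_year, length.out = n_years)
  specs <- list(
    g1 = list(model = amali, start = 0.5, threshold = 1, event = "G1 adults"),
    g2 = list(model = amali, start = 0.5, threshold = 2, event = "G2 adults"),
    migration = list(model = elanigerum, start = 0, threshold = 1,
                     event = "first migration")
  )
  pred <- obs <- lastneg <- firstpos <- lapply(specs, function(s)
    as.Date(rep(NA, n_years)))
  for (i in seq_len(n_years)) {
    cl <- climate
    cl$year <- years[i]
    series <- generate_temperature_series(cl, seed = seed + 101L * i)
    for (sp in names(specs)) {
      s <- specs[[sp]]
      fc <- accumulate_development(s$model, series,
                                   start_fraction = s$start)
      ev <- predict_event_dates(fc, stats::setNames(s$threshold, s$event))
      if (!ev$reached[1]) next
      pred[[sp]][i] <- ev$date[1]
      trap <- tryCatch(
        generate_trap_observations(ev$date[1], protocol,
                                   seed = seed + 101L * i +
                                     match(sp, names(specs))),
        error = function(e) NULL
      )
      if (!is.null(trap)) {
        obs[[sp]][i] <- trap$observed
        lastneg[[sp]][i] <- trap$last_negative
        firstpos[[sp]][i] <- trap$first_positive
      }
    }
  }
  lapply(stats::setNames(names(specs), names(specs)), function(sp) {
    validation_table(years, pred[[sp]], observed = obs[[sp]],
                     last_negative = lastneg[[sp]],
                     first_positive = firstpos[[sp]],
                     event = specs[[sp]]$event)
  })
}
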