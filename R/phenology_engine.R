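#' Orchard temperature series
#'
#' Validates and normalises a time-ordered temperature record at hourly or
#' daily resolution. Timestamps must be strictly increasing; temperatures
#' must lie within -40..55 degrees Celsius. Short gaps (up to 6 missing
#' hours at hourly resolution, 1 missing day at daily resolution) are filled
#' by linear interpolation; longer gaps are an error, never silently filled.
#'
#' @param timestamp `POSIXct` (hourly) or `Date` (daily) vector.
#' @param temperature_c numeric temperatures, degrees Celsius.
#' @param resolution `"hourly"`, `"daily"`, or `NULL` to auto-detect from
#'   the median timestamp spacing.
#' @return a `data.frame` of class `temperature_series` with columns
#'   `timestamp`, `temperature_c` and attribute `resolution`.
#' @export
temperature_series <- function(timestamp, temperature_c, resolution = NULL) {
  if (length(timestamp) != length(temperature_c) || length(timestamp) < 2) {
    stop("'timestamp' and 'temperature_c' must have equal length >= 2",
         call. = FALSE)
  }
  if (inherits(timestamp, "Date")) {
    step_sec <- 86400
    detected <- "daily"
  } else if (inherits(timestamp, "POSIXct")) {
    d <- as.numeric(stats::median(diff(as.numeric(timestamp))))
    detected <- if (d <= 3 * 3600) "hourly" else "daily"
    step_sec <- if (detected == "hourly") 3600 else 86400
  } else {
    stop("'timestamp' must be POSIXct (hourly) or Date (daily)",
         call. = FALSE)
  }
  if (is.null(resolution)) resolution <- detected
  resolution <- match.arg(resolution, c("hourly", "daily"))
  if (resolution == "hourly" && inherits(timestamp, "Date")) {
    stop("hourly resolution requires POSIXct timestamps", call. = FALSE)
  }
  if (any(!is.finite(temperature_c))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  if (any(temperature_c < -40 | temperature_c > 55)) {
    stop("temperatures outside the plausible -40..55 degC range",
         call. = FALSE)
  }
  tnum <- as.numeric(timestamp)
  dd <- diff(tnum)
  if (any(dd <= 0)) stop("timestamps must be strictly increasing",
                         call. = FALSE)
  step_sec <- if (resolution == "hourly") 3600 else 86400
  max_fill <- if (resolution == "hourly") 6 * 3600 else 1 * 86400
  gaps <- which(dd > 1.5 * step_sec)
  if (length(gaps)) {
    too_big <- dd[gaps] - step_sec > max_fill + step_sec / 2
    if (any(too_big)) {
      i <- gaps[which(too_big)[1]]
      stop(sprintf(
        "gap of %.1f hours after %s exceeds the %s fill window",
        dd[i] / 3600, format(timestamp[i]),
        if (resolution == "hourly") "6-hour" else "1-day"), call. = FALSE)
    }
    full <- seq(tnum[1], tnum[length(tnum)], by = step_sec)
    temperature_c <- stats::approx(tnum, temperature_c, xout = full)$y
    timestamp <- if (inherits(timestamp, "Date")) {
      as.Date(full / 86400, origin = "1970-01-01")
    } else {
      as.POSIXct(full, origin = "1970-01-01", tz = attr(timestamp, "tzone") %||% "UTC")
    }
  }
  out <- data.frame(timestamp = timestamp, temperature_c = temperature_c)
  attr(out, "resolution") <- resolution
  class(out) <- c("temperature_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a temperature series from delimited text
#'
#' Expects a header with columns `timestamp` (ISO-8601, either dates or
#' date-times) and `temperature_c`.
#'
#' @param path file path.
#' @param sep field separator.
#' @param resolution forwarded to [temperature_series()] (`NULL` =
#'   auto-detect).
#' @return a [temperature_series()].
#' @export
read_temperature_series <- function(path, sep = ",", resolution = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temperature_c") %in% names(d))) {
    stop("weather file must have columns timestamp, temperature_c",
         call. = FALSE)
  }
  ts <- if (all(nchar(d$timestamp) <= 10)) {
    as.Date(d$timestamp)
  } else {
    as.POSIXct(d$timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  }
  if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
  temperature_series(ts, d$temperature_c, resolution = resolution)
}

series_dates <- function(series) {
  if (inherits(series$timestamp, "Date")) series$timestamp
  else as.Date(series$timestamp, tz = attr(series$timestamp, "tzone") %||% "UTC")
}

#' Accumulate temperature-driven development over a season
#'
#' Starting from 1 January of the forecast year, sums clamped development
#' rates over the series: `D(t_k) = start_fraction + sum_j rate(T_j) * dt`
#' with `dt` = 1 day for daily records and 1/24 day for hourly records.
#' Timesteps at or below the lower threshold, at or above the upper cutoff,
#' or where the raw rate curve is negative contribute exactly zero. `D` is
#' measured in generation units: `D = 1` means one full development
#' (egg to adult) completed since 1 January.
#'
#' The `start_fraction` encodes the overwintering state on 1 January: 0.5
#' for *A. mali* (overwintering as full-grown larvae or pupae, taken as
#' halfway through egg-to-adult development; see
#' [stage_fraction_from_ratio()]) and 0 for *E. lanigerum* (overwintering
#' first-instar nymphs, with migration predicted after one full generation).
#'
#' @param model a [rate_model][make_polynomial_model].
#' @param series a [temperature_series()] covering 1 January onwards of the
#'   forecast year.
#' @param start_fraction initial cumulative development on 1 January, in
#'   generation units; must be in `[0, 1)`.
#' @param year forecast year; defaults to the year of the first record.
#' @return an object of class `phenology_forecast`: list with
#'   `species_label`, `start_fraction`, `resolution`, and `trajectory`
#'   (data frame: `timestamp`, `temperature_c`, `rate`, `cum_dev`).
#' @export
accumulate_development <- function(model, series, start_fraction = 0,
                                   year = NULL) {
  stopifnot(inherits(model, "rate_model"),
            inherits(series, "temperature_series"))
  if (!is.numeric(start_fraction) || start_fraction < 0 ||
      start_fraction >= 1) {
    stop("'start_fraction' must be in [0, 1)", call. = FALSE)
  }
  dates <- series_dates(series)
  if (is.null(year)) year <- as.integer(format(dates[1], "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  if (dates[1] > jan1) {
    stop("series must start on or before 1 January ", year,
         " (accumulation begins at the 1 January overwintering state)",
         call. = FALSE)
  }
  keep <- dates >= jan1
  series <- series[keep, , drop = FALSE]
  dates <- dates[keep]
  res <- attr(series, "resolution") %||% "daily"
  dt <- if (res == "hourly") 1 / 24 else 1
  rate <- evaluate_rate(model, series$temperature_c)
  traj <- data.frame(timestamp = series$timestamp,
                     temperature_c = series$temperature_c,
                     rate = rate,
                     cum_dev = start_fraction + cumsum(rate * dt))
  structure(
    list(species_label = model$species_label,
         start_fraction = start_fraction,
         resolution = res,
         year = year,
         trajectory = traj),
    class = "phenology_forecast"
  )
}

#' Extract predicted event dates from a development trajectory
#'
#' An event fires on the calendar date of the first timestep at which the
#' cumulative development reaches its threshold (first-crossing convention).
#' Thresholds are in generation units, e.g. for *A. mali* started at 0.5:
#' first-generation (G1) adults at `D >= 1`, second-generation (G2) adults
#' at `D >= 2`; for *E. lanigerum* started at 0: first crawler migration at
#' `D >= 1`. Events whose threshold is not reached within the series are
#' reported with an `NA` date.
#'
#' @param forecast a [accumulate_development()] result.
#' @param events named numeric vector of strictly increasing thresholds;
#'   names label the events.
#' @return a `data.frame` with columns `event`, `threshold`, `date`
#'   (class `Date`, `NA` when not reached), `reached`.
#' @export
predict_event_dates <- function(forecast, events) {
  stopifnot(inherits(forecast, "phenology_forecast"),
            is.numeric(events), length(events) >= 1,
            !is.null(names(events)))
  if (is.unsorted(events, strictly = TRUE)) {
    stop("event thresholds must be strictly increasing", call. = FALSE)
  }
  dts <- if (inherits(forecast$trajectory$timestamp, "Date")) {
    forecast$trajectory$timestamp
  } else {
    as.Date(forecast$trajectory$timestamp, tz = "UTC")
  }
  cum <- forecast$trajectory$cum_dev
  date <- as.Date(vapply(events, function(th) {
    i <- which(cum >= th)
    if (length(i) == 0) NA_real_ else as.numeric(dts[i[1]])
  }, 0), origin = "1970-01-01")
  data.frame(event = names(events), threshold = unname(events),
             date = date, reached = !is.na(date),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a stochastic cohort of developing individuals
#'
#' Individual-based counterpart of [accumulate_development()]: each of `n`
#' individuals accumulates development with a per-timestep rate drawn from a
#' normal distribution centred on the deterministic (clamped) rate with
#' standard deviation `sd` (1/days), truncated at zero. Timesteps where the
#' deterministic rate is zero (below the lower threshold, above the cutoff)
#' contribute exactly zero for every individual: stochasticity perturbs
#' development speed, it does not create development where none is possible.
#' With `sd = 0` every individual reproduces the deterministic forecast
#' exactly.
#'
#' The headline "predicted first date" of an event is the earliest
#' individual's crossing, matching how first field detections work; the
#' median and 10/90 percent quantile dates are also reported.
#'
#' @param model a [rate_model][make_polynomial_model].
#' @param series a [temperature_series()].
#' @param n number of individuals (the reference configuration uses 50).
#' @param sd stochasticity of the development rate, 1/days (reference
#'   configuration: 0.015).
#' @param seed integer seed; required for reproducibility.
#' @param start_fraction initial development, as in
#'   [accumulate_development()].
#' @param events named threshold vector, as in [predict_event_dates()].
#' @param year forecast year (default: year of the first record).
#' @return an object of class `cohort_result`: list with `n`, `sd`, `seed`,
#'   `events` (data frame: `event`, `threshold`, `first`, `median`, `q10`,
#'   `q90`, `n_reached`), `individual_dates` (n x n_events data frame of
#'   `Date`), and `deterministic` (the [predict_event_dates()] table of the
#'   sd = 0 path).
#' @export
simulate_individuals <- function(model, series, n = 50, sd = 0.015, seed,
                                 start_fraction = 0, events, year = NULL) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (missing(seed)) stop("'seed' is required for reproducibility",
                          call. = FALSE)
  n <- as.integer(n)
  det <- accumulate_development(model, series, start_fraction, year)
  det_events <- predict_event_dates(det, events)
  rate <- det$trajectory$rate
  dt <- if (det$resolution == "hourly") 1 / 24 else 1
  dts <- if (inherits(det$trajectory$timestamp, "Date")) {
    det$trajectory$timestamp
  } else {
    as.Date(det$trajectory$timestamp, tz = "UTC")
  }
  m <- length(rate)
  active <- rate > 0
  set.seed(seed)
  ind_dates <- matrix(as.Date(NA), nrow = n, ncol = length(events))
  ind_num <- matrix(NA_real_, nrow = n, ncol = length(events))
  for (i in seq_len(n)) {
    if (sd == 0) {
      cum <- det$trajectory$cum_dev
    } else {
      draws <- rate
      draws[active] <- pmax(0, stats::rnorm(sum(active), rate[active], sd))
      cum <- start_fraction + cumsum(draws * dt)
    }
    for (j in seq_along(events)) {
      k <- which(cum >= events[j])
      if (length(k)) ind_num[i, j] <- as.numeric(dts[k[1]])
    }
  }
  summ <- data.frame(
    event = names(events), threshold = unname(events),
    first  = as.Date(apply(ind_num, 2, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
      origin = "1970-01-01"),
    median = as.Date(apply(ind_num, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)),
      origin = "1970-01-01"),
    q10 = as.Date(apply(ind_num, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.1, na.rm = TRUE,
                                                       names = FALSE)),
      origin = "1970-01-01"),
    q90 = as.Date(apply(ind_num, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.9, na.rm = TRUE,
                                                       names = FALSE)),
      origin = "1970-01-01"),
    n_reached = apply(ind_num, 2, function(v) sum(!is.na(v))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  idf <- as.data.frame(lapply(seq_along(events), function(j)
    as.Date(ind_num[, j], origin = "1970-01-01")))
  names(idf) <- names(events)
  structure(
    list(n = n, sd = sd, seed = seed, events = summ,
         individual_dates = idf, deterministic = det_events),
    class = "cohort_result"
  )
}

#' Fraction of egg-to-adult development completed after given stages
#'
#' For a species whose immature stages have development times in a fixed
#' ratio (for *A. mali*, egg : larva : pupa = 1 : 4 : 5), returns the
#' fraction of the total egg-to-adult timespan completed once a prefix of
#' stages is finished. A full-grown *A. mali* larva has completed
#' (1 + 4) / (1 + 4 + 5) = 50 percent of its development, which is why the
#' overwintering initialization uses a start fraction of 0.5.
#'
#' @param ratio named positive numeric vector of stage-duration parts, in
#'   developmental order, e.g. `c(egg = 1, larva = 4, pupa = 5)`.
#' @param completed character vector of completed stage names; must be a
#'   prefix of `names(ratio)` (possibly empty).
#' @return a single fraction in `[0, 1]`.
#' @examples
#' stage_fraction_from_ratio(c(egg = 1, larva = 4, pupa = 5),
#'                           c("egg", "larva"))  # 0.5
#' @export
stage_fraction_from_ratio <- function(ratio, completed = character()) {
  if (!is.numeric(ratio) || is.null(names(ratio)) || any(ratio <= 0)) {
    stop("'ratio' must be a named numeric vector of positive parts",
         call. = FALSE)
  }
  if (length(completed)) {
    unknown <- setdiff(completed, names(ratio))
    if (length(unknown)) {
      stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (!identical(as.character(completed),
                   names(ratio)[seq_along(completed)])) {
      stop("'completed' must be a prefix of the stage list (",
           paste(names(ratio), collapse = " < "), ")", call. = FALSE)
    }
  }
  sum(ratio[seq_along(completed)]) / sum(ratio)
}

#' @export
print.phenology_forecast <- function(x, ...) {
  traj <- x$trajectory
  cat("<phenology_forecast>", x$species_label, sprintf("(%d)\n", x$year))
  cat(sprintf("  %s resolution, %d steps, D: %.3f -> %.3f generations\n",
              x$resolution, nrow(traj), x$start_fraction,
              traj$cum_dev[nrow(traj)]))
  invisible(x)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> n = %d, sd = %g, seed = %d\n",
              x$n, x$sd, x$seed))
  print(x$events)
  invisible(x)
}
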