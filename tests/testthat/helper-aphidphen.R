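# Shared helpers: independent oracles and fixture builders.

# Independent Horner-scheme polynomial oracle (highest-order first
# internally, distinct from the package's constant-first accumulation).
horner <- function(coefficients, x) {
  out <- 0
  for (co in rev(coefficients)) out <- out * x + co
  out
}

# A constant-temperature series.
constant_series <- function(temp, days = 120, year = 2018,
                            resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  if (resolution == "daily") {
    ts <- seq(as.Date(sprintf("%d-01-01", year)), by = "day",
              length.out = days)
  } else {
    ts <- seq(as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC"),
              by = 3600, length.out = days * 24)
  }
  temperature_series(ts, rep(temp, length(ts)))
}

# Development dataset generated exactly from a rate model at given
# temperatures (development time = 1 / raw polynomial rate).
dataset_from_model <- function(model, temps) {
  rate <- evaluate_rate(model, temps)
  stopifnot(all(rate > 0))
  dev_dataset(temps, 1 / rate, species_label = model$species_label)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "aphidphen", mustWork = TRUE)
}
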