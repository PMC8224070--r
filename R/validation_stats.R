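#' Convert calendar dates to days after 31 March
#'
#' Spring phenology dates are compared on a common numeric scale: the number
#' of days after 31 March of the same year (1 April = 1, 6 May = 36). The
#' mapping is exact calendar arithmetic, so leap years are handled
#' automatically, and it is invertible via [day_index_to_date()].
#'
#' @param date a `Date` vector; every element must fall after 31 March of
#'   its own year.
#' @return integer vector of day indices.
#' @export
date_to_day_index <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  origin <- as.Date(sprintf("%d-03-31", yr))
  idx <- as.integer(date - origin)
  if (any(idx <= 0, na.rm = TRUE)) {
    stop("dates on or before 31 March cannot be indexed", call. = FALSE)
  }
  idx
}

#' @rdname date_to_day_index
#' @param index integer day index (days after 31 March).
#' @param year calendar year.
#' @export
day_index_to_date <- function(index, year) {
  as.Date(sprintf("%d-03-31", as.integer(year))) + as.integer(index)
}

#' Mean observation date between bracketing trap checks
#'
#' Field monitoring only brackets an event: the last check at which nothing
#' was caught and the first check with a detection. The working observed
#' date is the midpoint of the two checks; when the midpoint falls on a half
#' day it is rounded toward the earlier day (conservative for spray
#' advisories: assuming an earlier emergence widens the protection window).
#'
#' @param last_negative `Date`, last check with no detection.
#' @param first_positive `Date`, first check with a detection; must be
#'   strictly later, and at most 14 days later (sanity guard against
#'   mismatched records).
#' @return the midpoint `Date`.
#' @examples
#' mean_observation_date(as.Date("2018-04-14"), as.Date("2018-04-18"))
#' @export
mean_observation_date <- function(last_negative, first_positive) {
  last_negative <- as.Date(last_negative)
  first_positive <- as.Date(first_positive)
  gap <- as.numeric(first_positive - last_negative)
  if (any(gap <= 0)) {
    stop("'first_positive' must be strictly after 'last_negative'",
         call. = FALSE)
  }
  if (any(gap > 14)) {
    stop("bracketing interval exceeds 14 days; check the records",
         call. = FALSE)
  }
  last_negative + floor(gap / 2)
}

#' Assemble a validation table of predicted and observed event dates
#'
#' One row per monitoring year for a single event (e.g. "G1 adults"). The
#' observed date may be given directly or derived from bracketing checks via
#' [mean_observation_date()]; years without usable observations keep `NA`
#' and are dropped (with a message) from the statistics.
#'
#' @param year integer vector of monitoring years.
#' @param predicted `Date` vector of model-predicted dates.
#' @param observed `Date` vector of observed dates, or `NULL` to derive from
#'   brackets.
#' @param last_negative,first_positive optional `Date` vectors of bracketing
#'   checks, used where `observed` is missing.
#' @param event event label.
#' @return a `data.frame` of class `validation_table`.
#' @export
validation_table <- function(year, predicted, observed = NULL,
                             last_negative = NULL, first_positive = NULL,
                             event = "event") {
  n <- length(year)
  predicted <- as.Date(predicted)
  if (is.null(observed)) observed <- as.Date(rep(NA, n))
  observed <- as.Date(observed)
  stopifnot(length(predicted) == n, length(observed) == n)
  if (!is.null(last_negative) && !is.null(first_positive)) {
    last_negative <- as.Date(last_negative)
    first_positive <- as.Date(first_positive)
    fill <- which(is.na(observed) & !is.na(last_negative) &
                    !is.na(first_positive))
    if (length(fill)) {
      observed[fill] <- mean_observation_date(last_negative[fill],
                                              first_positive[fill])
    }
  } else {
    last_negative <- as.Date(rep(NA, n))
    first_positive <- as.Date(rep(NA, n))
  }
  d <- data.frame(year = as.integer(year), predicted = predicted,
                  observed = observed, last_negative = last_negative,
                  first_positive = first_positive,
                  stringsAsFactors = FALSE)
  attr(d, "event") <- event
  class(d) <- c("validation_table", "data.frame")
  d
}

complete_rows <- function(table) {
  ok <- !is.na(table$predicted) & !is.na(table$observed)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " row(s) without a complete predicted/observed pair ",
            "excluded from statistics")
  }
  table[ok, , drop = FALSE]
}

#' Prediction error metrics in days
#'
#' Reports three summaries of `observed - predicted` (days): the mean
#' absolute error, the root-mean-square error and the mean signed error.
#' All three are given because a bare "mean error of +/- k days" can denote
#' either of the first two.
#'
#' @param table a [validation_table()].
#' @return list with `n`, `mae`, `rmse`, `mean_signed_error` (days).
#' @export
error_metrics <- function(table) {
  stopifnot(inherits(table, "validation_table"))
  tab <- complete_rows(table)
  if (nrow(tab) < 1) stop("no complete predicted/observed pairs",
                          call. = FALSE)
  d <- as.numeric(tab$observed - tab$predicted)
  list(n = nrow(tab), mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
       mean_signed_error = mean(d))
}

#' Observed-on-predicted validation regression
#'
#' Quantifies prediction accuracy the standard way for phenology models:
#' ordinary least squares of observed (y) on predicted (x) event dates, both
#' expressed as days after 31 March. An ideal model gives slope 1, intercept
#' 0 and r-squared 1. The p-value is the two-sided t-test of slope = 0 on
#' n - 2 degrees of freedom. Error metrics ([error_metrics()]) are included
#' in the report.
#'
#' @param table a [validation_table()] with at least 3 complete rows.
#' @return object of class `accuracy_report`: list with `event`, `n`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `mae`, `rmse`,
#'   `mean_signed_error`.
#' @export
regress_observed_on_predicted <- function(table) {
  stopifnot(inherits(table, "validation_table"))
  tab <- complete_rows(table)
  if (nrow(tab) < 3) {
    stop("need at least 3 complete predicted/observed pairs for the ",
         "validation regression, got ", nrow(tab), call. = FALSE)
  }
  x <- date_to_day_index(tab$predicted)
  y <- date_to_day_index(tab$observed)
  fit <- stats::lm(y ~ x)
  # an ideal table (observed == predicted) triggers the benign
  # "essentially perfect fit" warning; the r^2 = 1 result is exact
  sm <- suppressWarnings(summary(fit))
  em <- error_metrics(table)
  structure(
    list(event = attr(table, "event"), n = nrow(tab),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         mae = em$mae, rmse = em$rmse,
         mean_signed_error = em$mean_signed_error),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>", x$event, sprintf("(n = %d)\n", x$n))
  cat(sprintf("  observed = %.3f + %.3f * predicted;  r^2 = %.4f,  p = %.4g\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  cat(sprintf("  MAE %.2f d, RMSE %.2f d, mean signed error %+.2f d\n",
              x$mae, x$rmse, x$mean_signed_error))
  invisible(x)
}

#' Read a validation table from delimited text
#'
#' Expects a header with columns `year`, `event`, `predicted` and either
#' `observed` or the bracket pair `last_negative`/`first_positive`, dates in
#' ISO-8601 (empty fields = NA).
#'
#' @param path file path.
#' @param event optional: restrict to rows with this event label (required
#'   when the file mixes several events).
#' @param sep field separator.
#' @return a [validation_table()].
#' @export
read_validation_table <- function(path, event = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("year", "event", "predicted") %in% names(d))) {
    stop("observation file must have columns year, event, predicted",
         call. = FALSE)
  }
  if (!is.null(event)) {
    d <- d[d$event == event, , drop = FALSE]
    if (nrow(d) == 0) stop("no rows with event '", event, "' in ", path,
                           call. = FALSE)
  } else if (length(unique(d$event)) > 1) {
    stop("file contains several events (",
         paste(unique(d$event), collapse = ", "),
         "); pass 'event' to select one", call. = FALSE)
  }
  as_date_col <- function(nm) {
    if (nm %in% names(d)) as.Date(d[[nm]]) else NULL
  }
  validation_table(d$year, as.Date(d$predicted),
                   observed = as_date_col("observed"),
                   last_negative = as_date_col("last_negative"),
                   first_positive = as_date_col("first_positive"),
                   event = unique(d$event)[1])
}

#' Parasitism degree of a woolly aphid colony
#'
#' Number of parasitized (mummified) aphids per 10 square centimetres of
#' woolly aphid colony surface, the standard field measure of *A. mali*
#' activity.
#'
#' @param mummy_count number of mummified aphids counted (>= 0).
#' @param colony_surface_cm2 assessed colony surface in square centimetres
#'   (> 0).
#' @return mummies per 10 cm2.
#' @export
parasitism_degree <- function(mummy_count, colony_surface_cm2) {
  if (any(colony_surface_cm2 <= 0)) {
    stop("'colony_surface_cm2' must be positive", call. = FALSE)
  }
  if (any(mummy_count < 0)) stop("'mummy_count' must be >= 0", call. = FALSE)
  10 * mummy_count / colony_surface_cm2
}

#' Leaf wall area of a treated orchard row section
#'
#' Two-sided treated canopy area used to express spray doses in vertical
#' crops: `n_trees * row_spacing * treated_height * 2`.
#'
#' @param n_trees number of trees (> 0).
#' @param row_spacing_m planting distance within the row, metres (> 0).
#' @param treated_height_m treated tree height, metres (> 0).
#' @return leaf wall area in square metres.
#' @examples
#' compute_lwa(7, 1.75, 3.10)  # one 7-tree plot
#' @export
compute_lwa <- function(n_trees, row_spacing_m, treated_height_m) {
  if (any(n_trees <= 0) || any(row_spacing_m <= 0) ||
      any(treated_height_m <= 0)) {
    stop("all leaf-wall-area inputs must be positive", call. = FALSE)
  }
  n_trees * row_spacing_m * treated_height_m * 2
}
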