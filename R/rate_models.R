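#' Temperature-dependent development-rate models
#'
#' A `rate_model` maps temperature (degrees Celsius) to an insect development
#' rate (1/days, i.e. the fraction of a full development completed per day at
#' that temperature). Two families are supported:
#'
#' * `"polynomial"`: a saturated polynomial in temperature,
#'   `f(T) = c0 + c1*T + ... + cn*T^n`, coefficients stored constant-first.
#' * `"linear_dd"`: the classical linear degree-day model,
#'   `f(T) = (T - T_low) / DD_total` for `T > T_low`, where `DD_total` is the
#'   thermal constant in degree-days.
#'
#' Evaluated rates are clamped to zero below `lower_threshold`, at and above
#' the upper cutoff, and wherever the raw function is negative, so that the
#' model never produces a biologically impossible negative rate.
#'
#' @param coefficients numeric vector, constant-first (`c0, c1, ..., cn`);
#'   a degree-n polynomial needs `n + 1` coefficients and at least 2 are
#'   required.
#' @param lower_threshold lower developmental threshold in degrees Celsius;
#'   no development accrues at or below it.
#' @param upper_cutoff either a temperature in degrees Celsius above which the
#'   rate is forced to zero, or `"auto"` (polynomial family only) to locate
#'   the first zero crossing of the raw polynomial above its maximum
#'   numerically; see [resolve_upper_cutoff()].
#' @param species_label free-text label carried through reports.
#' @return an object of class `rate_model`.
#' @examples
#' m <- amali_model()
#' evaluate_rate(m, c(5, 15, 25))
#' @seealso [evaluate_rate()], [resolve_upper_cutoff()],
#'   [make_linear_dd_model()]
#' @export
make_polynomial_model <- function(coefficients, lower_threshold,
                                  upper_cutoff = "auto",
                                  species_label = "") {
  if (!is.numeric(coefficients) || length(coefficients) < 2 ||
      anyNA(coefficients)) {
    stop("'coefficients' must be a numeric vector of length >= 2 ",
         "(constant-first) with no missing values", call. = FALSE)
  }
  if (!is.numeric(lower_threshold) || length(lower_threshold) != 1 ||
      !is.finite(lower_threshold)) {
    stop("'lower_threshold' must be a single finite temperature",
         call. = FALSE)
  }
  if (!(identical(upper_cutoff, "auto") ||
        (is.numeric(upper_cutoff) && length(upper_cutoff) == 1 &&
         !is.na(upper_cutoff)))) {
    stop("'upper_cutoff' must be \"auto\" or a single temperature",
         call. = FALSE)
  }
  structure(
    list(
      species_label   = as.character(species_label),
      family          = "polynomial",
      coefficients    = as.numeric(coefficients),
      lower_threshold = lower_threshold,
      upper_cutoff    = upper_cutoff
    ),
    class = "rate_model"
  )
}

#' Linear degree-day rate model
#'
#' Constructs the linear thermal-summation model in which development
#' proceeds at `(T - t_low) / dd_total` generations per day above the lower
#' threshold `t_low`. At a constant temperature `T > t_low` a full
#' development therefore takes `dd_total / (T - t_low)` days, i.e. exactly
#' `dd_total` degree-days.
#'
#' @param t_low lower developmental threshold, degrees Celsius.
#' @param dd_total thermal constant, degree-days above `t_low` needed for one
#'   full development.
#' @param species_label free-text label.
#' @param upper_cutoff optional upper cutoff temperature; default `Inf`
#'   (the plain linear model has no upper limit).
#' @return an object of class `rate_model` with `family = "linear_dd"`.
#' @export
make_linear_dd_model <- function(t_low, dd_total, species_label = "",
                                 upper_cutoff = Inf) {
  if (!is.numeric(dd_total) || length(dd_total) != 1 || dd_total <= 0) {
    stop("'dd_total' must be a single positive number of degree-days",
         call. = FALSE)
  }
  m <- make_polynomial_model(c(t_low, dd_total), lower_threshold = t_low,
                             upper_cutoff = upper_cutoff,
                             species_label = species_label)
  m$family <- "linear_dd"
  m
}

#' Built-in models for the two orchard species
#'
#' `amali_model()` returns the published egg-to-adult development-rate model
#' for the parasitoid *Aphelinus mali*; `elanigerum_model()` the model for
#' apterous virginoparae of the woolly apple aphid *Eriosoma lanigerum*.
#' Both are available in two families:
#'
#' * `"polynomial"`: the degree-5 (*A. mali*) and degree-6 (*E. lanigerum*)
#'   saturated polynomials fitted to literature constant-temperature rearing
#'   data, with lower thresholds of 8.3 and 5.2 degrees Celsius respectively
#'   and an automatic upper zero-crossing cutoff.
#' * `"linear_dd"`: the corresponding linear degree-day models, 254.8 DD
#'   above 8.3 for *A. mali* and 267.6 DD above 5.2 for *E. lanigerum*.
#'
#' @param family `"polynomial"` or `"linear_dd"`.
#' @return a `rate_model`.
#' @examples
#' evaluate_rate(amali_model(), 25)            # about 0.073 / day
#' evaluate_rate(elanigerum_model("linear_dd"), 20)
#' @export
amali_model <- function(family = c("polynomial", "linear_dd")) {
  family <- match.arg(family)
  if (family == "polynomial") {
    make_polynomial_model(
      coefficients = c(-2.940e-3, -1.716e-4, 4.895e-4,
                       -5.389e-5, 2.653e-6, -4.303e-8),
      lower_threshold = 8.3, upper_cutoff = "auto",
      species_label = "Aphelinus mali"
    )
  } else {
    make_linear_dd_model(8.3, 254.8, species_label = "Aphelinus mali")
  }
}

#' @rdname amali_model
#' @export
elanigerum_model <- function(family = c("polynomial", "linear_dd")) {
  family <- match.arg(family)
  if (family == "polynomial") {
    make_polynomial_model(
      coefficients = c(1.013e-3, -9.014e-4, -2.011e-4, 1.044e-4,
                       -8.425e-6, 2.731e-7, -3.209e-9),
      lower_threshold = 5.2, upper_cutoff = "auto",
      species_label = "Eriosoma lanigerum"
    )
  } else {
    make_linear_dd_model(5.2, 267.6, species_label = "Eriosoma lanigerum")
  }
}

# Raw (unclamped) rate of the underlying function.
raw_rate <- function(model, temperature) {
  if (model$family == "linear_dd") {
    t_low <- model$coefficients[1]
    dd    <- model$coefficients[2]
    (temperature - t_low) / dd
  } else {
    co <- model$coefficients
    out <- rep(co[length(co)], length(temperature))
    for (k in seq(length(co) - 1L, 1L)) {
      out <- out * temperature + co[k]
    }
    out
  }
}

#' Evaluate a development-rate model
#'
#' Returns the development rate (1/days) at one or more temperatures, with
#' zero-clamping applied: the rate is exactly 0 at and below the lower
#' threshold, at and above the upper cutoff, and wherever the raw function
#' would be negative.
#'
#' @param model a [rate_model][make_polynomial_model].
#' @param temperature numeric vector of temperatures, degrees Celsius; must
#'   be finite.
#' @return numeric vector of non-negative rates, same length as
#'   `temperature`.
#' @export
evaluate_rate <- function(model, temperature) {
  stopifnot(inherits(model, "rate_model"))
  if (length(model$coefficients) == 0) {
    stop("rate model has no coefficients", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) == 0 ||
      any(!is.finite(temperature))) {
    stop("'temperature' must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  cutoff <- resolve_upper_cutoff(model)
  r <- raw_rate(model, temperature)
  r[temperature <= model$lower_threshold | temperature >= cutoff | r < 0] <- 0
  r
}

#' Resolve the upper cutoff temperature of a rate model
#'
#' Saturated polynomial rate curves fall after their optimum and eventually
#' cross zero; beyond that crossing the raw polynomial is negative and the
#' model must report zero development. When a model's `upper_cutoff` is
#' `"auto"` this function locates, to better than 0.01 degrees Celsius, the
#' first temperature above the rate maximum where the raw polynomial crosses
#' zero from above. An explicit numeric `upper_cutoff` (e.g. a literature
#' value) is returned unchanged, which lets a configured cutoff override the
#' numeric crossing of rounded published coefficients.
#'
#' @param model a [rate_model][make_polynomial_model].
#' @param search_max upper end of the search interval, degrees Celsius.
#' @return a single temperature in degrees Celsius.
#' @export
resolve_upper_cutoff <- function(model, search_max = 60) {
  stopifnot(inherits(model, "rate_model"))
  if (!identical(model$upper_cutoff, "auto")) {
    return(as.numeric(model$upper_cutoff))
  }
  if (model$family != "polynomial") {
    return(Inf)
  }
  lo <- model$lower_threshold
  grid <- seq(lo, search_max, length.out = 4096L)
  vals <- raw_rate(model, grid)
  if (all(vals <= 0)) {
    stop("polynomial rate is never positive above the lower threshold; ",
         "cannot resolve an upper cutoff", call. = FALSE)
  }
  i_max <- which.max(vals)
  neg <- which(vals < 0 & seq_along(vals) > i_max)
  if (length(neg) == 0) {
    stop("polynomial does not cross zero above its maximum below ",
         search_max, " degrees C; supply an explicit upper_cutoff",
         call. = FALSE)
  }
  i_neg <- neg[1]
  stats::uniroot(function(x) raw_rate(model, x),
                 lower = grid[i_neg - 1L], upper = grid[i_neg],
                 tol = 1e-8)$root
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model>", if (nzchar(x$species_label)) x$species_label else NULL,
      "\n")
  if (x$family == "linear_dd") {
    cat(sprintf("  family: linear degree-day (T_low = %g degC, DD = %g)\n",
                x$coefficients[1], x$coefficients[2]))
  } else {
    cat(sprintf("  family: polynomial, degree %d\n",
                length(x$coefficients) - 1L))
    cat("  coefficients (constant-first):",
        paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  lower threshold: %g degC; upper cutoff: %s\n",
              x$lower_threshold,
              if (identical(x$upper_cutoff, "auto")) {
                sprintf("auto (%.2f degC)", resolve_upper_cutoff(x))
              } else {
                sprintf("%g degC", x$upper_cutoff)
              }))
  invisible(x)
}
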