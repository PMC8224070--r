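#' Constant-temperature development datasets
#'
#' Bundles (temperature, development time) observations from rearing insects
#' at constant temperatures, the raw material for fitting development-rate
#' curves. Rates are always derived as `1 / dev_time_days`; the curves are
#' fitted to rates, not times, so short development times (warm temperatures)
#' carry the most weight in the least-squares criterion.
#'
#' @param temperature_c numeric, rearing temperatures in degrees Celsius.
#' @param dev_time_days numeric, mean development times in days; must be
#'   positive.
#' @param stage optional character, life-stage label per record (e.g.
#'   instar); temperatures must be distinct within a stage.
#' @param species_label free-text label.
#' @return a `data.frame` of class `dev_dataset` with columns
#'   `temperature_c`, `dev_time_days`, `stage`.
#' @export
dev_dataset <- function(temperature_c, dev_time_days, stage = NULL,
                        species_label = "") {
  if (length(temperature_c) != length(dev_time_days)) {
    stop("'temperature_c' and 'dev_time_days' must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(temperature_c)) || any(!is.finite(dev_time_days))) {
    stop("temperatures and development times must be finite", call. = FALSE)
  }
  if (any(dev_time_days <= 0)) {
    stop("development times must be positive", call. = FALSE)
  }
  if (is.null(stage)) stage <- rep(NA_character_, length(temperature_c))
  d <- data.frame(temperature_c = as.numeric(temperature_c),
                  dev_time_days = as.numeric(dev_time_days),
                  stage = as.character(stage),
                  stringsAsFactors = FALSE)
  attr(d, "species_label") <- as.character(species_label)
  class(d) <- c("dev_dataset", "data.frame")
  d
}

#' Read a development dataset from delimited text
#'
#' Expects a header with columns `temperature_c`, `dev_time_days` and an
#' optional `stage` column.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param species_label label attached to the dataset.
#' @return a [dev_dataset()].
#' @export
read_dev_dataset <- function(path, sep = ",", species_label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("temperature_c", "dev_time_days")
  if (!all(need %in% names(d))) {
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dev_dataset(d$temperature_c, d$dev_time_days,
              stage = if ("stage" %in% names(d)) d$stage else NULL,
              species_label = species_label)
}

dataset_fingerprint <- function(data) {
  o <- order(data$temperature_c, data$dev_time_days)
  paste(signif(data$temperature_c[o], 12), signif(data$dev_time_days[o], 12),
        data$stage[o], collapse = ";")
}

#' Fit a development-rate model to constant-temperature data
#'
#' Fits the chosen rate-model family to observed rates `1 / dev_time_days`
#' by least squares. For the polynomial family the coefficients are obtained
#' by a linear least-squares solve on the monomial basis (the model is linear
#' in its coefficients, so this is the exact minimiser of the nonlinear
#' least-squares criterion) and then verified/refined with a Gauss-Newton
#' pass through [stats::nls()]; exact interpolation, where `nls` cannot
#' iterate on a zero-residual surface, falls back to the linear solution.
#' For the `linear_dd` family an ordinary regression `rate ~ T` is converted
#' to the threshold/thermal-constant parameterisation
#' `T_low = -intercept/slope`, `DD_total = 1/slope`.
#'
#' @param data a [dev_dataset()].
#' @param family `"polynomial"` or `"linear_dd"`.
#' @param degree polynomial degree (ignored for `linear_dd`); needs at least
#'   `degree + 1` records.
#' @param lower_threshold lower threshold attached to the fitted polynomial
#'   model (the clamp is applied at prediction time, not during fitting).
#' @param upper_cutoff upper cutoff attached to the fitted model
#'   (`"auto"` by default).
#' @param stage restrict the fit to records with this life-stage label.
#' @return an object of class `rate_fit`: a list with elements `model`
#'   ([rate_model][make_polynomial_model]), `rss`, `aic`, `n_obs`,
#'   `residuals` (data frame), `converged`.
#' @export
fit_rate_model <- function(data, family = c("polynomial", "linear_dd"),
                           degree = 5, lower_threshold = 0,
                           upper_cutoff = "auto", stage = NULL) {
  stopifnot(inherits(data, "dev_dataset"))
  family <- match.arg(family)
  if (!is.null(stage)) data <- data[data$stage %in% stage, , drop = FALSE]
  n <- nrow(data)
  tt <- data$temperature_c
  rate <- 1 / data$dev_time_days

  if (family == "polynomial") {
    k_par <- degree + 1L
    if (n < k_par) {
      stop("need at least ", k_par, " records to fit a degree-", degree,
           " polynomial, got ", n, call. = FALSE)
    }
    X <- outer(tt, 0:degree, `^`)
    # QR on the design matrix, not the normal equations: the raw monomial
    # basis is badly conditioned at degree 5-6
    start <- qr.coef(qr(X, LAPACK = TRUE), rate)
    names(start) <- paste0("c", 0:degree)
    co <- start
    converged <- TRUE
    if (n > k_par) {
      terms <- paste(sprintf("c%d * temperature^%d", 0:degree, 0:degree),
                     collapse = " + ")
      fml <- stats::as.formula(paste("rate ~", terms))
      fit <- tryCatch(
        withCallingHandlers(
          stats::nls(fml, data = data.frame(temperature = tt, rate = rate),
                     start = as.list(start),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE)),
          warning = function(w) invokeRestart("muffleWarning")
        ),
        error = function(e) NULL
      )
      # the polynomial is linear in its coefficients, so the linear solve
      # already is the least-squares optimum; keep the Gauss-Newton result
      # only if it did not drift uphill on an ill-conditioned surface
      if (!is.null(fit) &&
          sum((rate - stats::fitted(fit))^2) <=
            sum((rate - drop(X %*% start))^2)) {
        co <- stats::coef(fit)
        converged <- fit$convInfo$isConv
      }
    }
    model <- make_polynomial_model(unname(co), lower_threshold,
                                   upper_cutoff,
                                   attr(data, "species_label"))
    fitted <- raw_rate(model, tt)
  } else {
    if (n < 3) {
      stop("need at least 3 records for the linear degree-day fit",
           call. = FALSE)
    }
    lf <- stats::lm(rate ~ tt)
    slope <- unname(stats::coef(lf)[2])
    if (slope <= 0) {
      stop("linear degree-day fit has non-positive slope; rates do not ",
           "increase with temperature over this dataset", call. = FALSE)
    }
    t_low <- -unname(stats::coef(lf)[1]) / slope
    model <- make_linear_dd_model(t_low, 1 / slope,
                                  species_label = attr(data, "species_label"))
    fitted <- raw_rate(model, tt)
    converged <- TRUE
  }

  res <- rate - fitted
  rss <- sum(res^2)
  k <- length(model$coefficients) + 1L  # + error variance
  underflow <- rss < n * 1e-24
  if (underflow) {
    warning("residual sum of squares is numerically zero (exact ",
            "interpolation); AIC is undefined and reported as NA",
            call. = FALSE)
  }
  structure(
    list(
      model = model,
      rss = rss,
      aic = if (underflow) NA_real_ else n * log(rss / n) + 2 * k,
      n_obs = n,
      k = k,
      residuals = data.frame(temperature_c = tt, observed_rate = rate,
                             fitted_rate = fitted, residual = res),
      converged = converged,
      rss_underflow = underflow,
      data_fingerprint = dataset_fingerprint(data)
    ),
    class = "rate_fit"
  )
}

#' Compare fitted models by AIC
#'
#' Ranks fits of the same dataset by the Akaike Information Criterion,
#' computed under a Gaussian error likelihood as `n * log(RSS/n) + 2k` with
#' `k` = number of coefficients + 1 (the error variance). Only AIC
#' differences are meaningful; `delta_aic` is relative to the best model.
#' Exact-interpolation fits (RSS numerically zero, AIC undefined) are placed
#' first and flagged rather than assigned `-Inf`.
#'
#' @param fits a list of `rate_fit` objects on the same dataset.
#' @return a `data.frame` with one row per fit, ordered best-first: columns
#'   `label`, `n_par`, `rss`, `aic`, `delta_aic`, `rss_underflow`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "rate_fit")))
  fps <- vapply(fits, `[[`, "", "data_fingerprint")
  if (length(unique(fps)) != 1) {
    stop("all fits must be computed on the same dataset", call. = FALSE)
  }
  tab <- data.frame(
    label = vapply(fits, function(f) {
      if (f$model$family == "linear_dd") "linear_dd"
      else sprintf("poly%d", length(f$model$coefficients) - 1L)
    }, ""),
    n_par = vapply(fits, `[[`, 0L, "k"),
    rss = vapply(fits, `[[`, 0, "rss"),
    aic = vapply(fits, `[[`, 0, "aic"),
    rss_underflow = vapply(fits, `[[`, TRUE, "rss_underflow"),
    stringsAsFactors = FALSE
  )
  key <- ifelse(tab$rss_underflow, -Inf, tab$aic)
  tab <- tab[order(key), , drop = FALSE]
  best <- if (any(!tab$rss_underflow)) min(tab$aic, na.rm = TRUE) else NA_real_
  tab$delta_aic <- tab$aic - best
  rownames(tab) <- NULL
  tab[, c("label", "n_par", "rss", "aic", "delta_aic", "rss_underflow")]
}

#' Residual diagnostics for a rate fit
#'
#' @param fit a `rate_fit`.
#' @return a list: `table` (temperature, observed rate, fitted rate,
#'   residual), `max_abs_residual`, and `sign_runs` (number of runs of the
#'   residual sign along increasing temperature, a crude curvature-misfit
#'   indicator: very few runs suggest a systematically bowed fit).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rate_fit"))
  tab <- fit$residuals[order(fit$residuals$temperature_c), , drop = FALSE]
  rownames(tab) <- NULL
  s <- sign(tab$residual)
  s <- s[s != 0]
  runs <- if (length(s) == 0) 0L else 1L + sum(s[-1] != s[-length(s)])
  list(table = tab,
       max_abs_residual = max(abs(tab$residual)),
       sign_runs = runs)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit>", x$model$species_label, "\n")
  cat(sprintf("  family %s, %d observations, RSS %.4g, AIC %s\n",
              x$model$family, x$n_obs, x$rss,
              if (is.na(x$aic)) "NA (exact interpolation)"
              else sprintf("%.2f", x$aic)))
  invisible(x)
}
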