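#' Parameters of the modified Smeed equation
#'
#' The modified Smeed equation relates a country's road-traffic mortality
#' (deaths per 100,000 persons, `D/P`) to its motorization level (registered
#' motor vehicles per person, `N/P = x`):
#'
#' \deqn{D/P = a \, x \, e^{-b x}}
#'
#' Taking logs gives the linear form \eqn{Y = \beta_0 + \beta_1 x} with
#' \eqn{Y = \ln(D/P) - \ln(N/P)}, \eqn{\beta_0 = \ln a} and
#' \eqn{\beta_1 = -b}. A parameter object stores both parameterizations and
#' keeps them consistent.
#'
#' Units are fixed throughout the package: `D/P` in deaths per 100,000
#' persons and `x` in vehicles per person, so `a` is in deaths per 100,000
#' per (vehicle per person) and `b` is per (vehicle per person).
#'
#' @param a Multiplicative parameter, `exp(beta0)`; must be positive.
#' @param b Exponential-decay parameter, `-beta1`. Positive `b` gives a
#'   unimodal curve with an interior peak at `x = 1/b`; `b <= 0` is
#'   representable (the curve is then monotone) but peak quantities are
#'   undefined for it.
#' @param beta0,beta1 Intercept and slope of the log-linear form. Supply
#'   either `(a, b)` or `(beta0, beta1)`, not both.
#'
#' @return An object of class `smeed_params`: a list with elements `beta0`,
#'   `beta1`, `a`, `b`.
#' @examples
#' p <- smeed_params(a = 273.42, b = 5.742)
#' p$beta0                      # log(273.42)
#' params_from_linear(5.611, -5.742)$a
#' @export
smeed_params <- function(a = NULL, b = NULL, beta0 = NULL, beta1 = NULL) {
  from_ab <- !is.null(a) || !is.null(b)
  from_lin <- !is.null(beta0) || !is.null(beta1)
  if (from_ab && from_lin)
    stop("supply either (a, b) or (beta0, beta1), not both", call. = FALSE)
  if (from_ab) {
    if (is.null(a) || is.null(b))
      stop("both 'a' and 'b' are required", call. = FALSE)
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
      stop("'a' must be a single positive number", call. = FALSE)
    if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
      stop("'b' must be a single finite number", call. = FALSE)
    beta0 <- log(a)
    beta1 <- -b
  } else {
    if (is.null(beta0) || is.null(beta1))
      stop("both 'beta0' and 'beta1' are required", call. = FALSE)
    stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
              is.numeric(beta1), length(beta1) == 1L, is.finite(beta1))
    a <- exp(beta0)
    b <- -beta1
  }
  structure(list(beta0 = beta0, beta1 = beta1, a = a, b = b),
            class = "smeed_params")
}

#' @rdname smeed_params
#' @export
params_from_linear <- function(beta0, beta1) {
  smeed_params(beta0 = beta0, beta1 = beta1)
}

#' @rdname smeed_params
#' @return `params_to_linear()` returns the named numeric vector
#'   `c(beta0, beta1)`.
#' @param params A `smeed_params` object.
#' @export
params_to_linear <- function(params) {
  stopifnot(inherits(params, "smeed_params"))
  c(beta0 = params$beta0, beta1 = params$beta1)
}

#' @export
print.smeed_params <- function(x, ...) {
  cat("Modified Smeed parameters\n")
  cat(sprintf("  a = %.4f  b = %.4f   (beta0 = %.4f, beta1 = %.4f)\n",
              x$a, x$b, x$beta0, x$beta1))
  if (x$b > 0)
    cat(sprintf("  peak: %.1f deaths/100,000 at %.3f vehicles/person\n",
                predicted_maximum_mortality(x), peak_motorization(x)))
  else
    cat("  b <= 0: monotone regime, no interior peak\n")
  invisible(x)
}

stop_not_params <- function(params) {
  if (!inherits(params, "smeed_params"))
    stop("'params' must be a smeed_params object", call. = FALSE)
}

#' Predicted road-traffic mortality at a motorization level
#'
#' Evaluates the modified Smeed curve `a * x * exp(-b * x)`.
#'
#' @param params A [smeed_params] object.
#' @param x Motorization level(s), vehicles per person; must be `>= 0`.
#' @return Predicted mortality in deaths per 100,000 persons, same length
#'   as `x`. Zero at `x = 0`.
#' @examples
#' p <- smeed_params(a = 273.42, b = 5.742)
#' predict_mortality(p, 0.174)   # near the curve's maximum
#' @export
predict_mortality <- function(params, x) {
  stop_not_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative", call. = FALSE)
  params$a * x * exp(-params$b * x)
}

#' Derivative of the modified Smeed curve
#'
#' Returns `d(D/P)/dx = a * exp(-b*x) * (1 - b*x)`. For `b > 0` the
#' derivative is positive on `(0, 1/b)`, zero at `x = 1/b` and negative
#' beyond, so the curve rises to a single interior maximum and then falls.
#'
#' @inheritParams predict_mortality
#' @return Derivative values, same length as `x`; equals `a` at `x = 0`.
#' @export
mortality_derivative <- function(params, x) {
  stop_not_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative", call. = FALSE)
  params$a * exp(-params$b * x) * (1 - params$b * x)
}

#' Peak quantities of a fitted modified Smeed curve
#'
#' `predicted_maximum_mortality()` returns the curve's global maximum
#' `a / (e * b)` — the worst mortality the model predicts the country
#' passes through (PMM). `peak_motorization()` returns the motorization
#' level `1/b` at which that maximum is attained; lower values are read as
#' a mortality peak reached earlier in the motorization process.
#'
#' Both require `b > 0`; with `b <= 0` the curve is monotone and has no
#' interior peak.
#'
#' @inheritParams predict_mortality
#' @return A single number: deaths per 100,000 persons for
#'   `predicted_maximum_mortality()`, vehicles per person for
#'   `peak_motorization()`.
#' @examples
#' p <- smeed_params(a = 273.42, b = 5.742)
#' predicted_maximum_mortality(p)  # 17.5 to one decimal
#' peak_motorization(p)            # 0.174 to three decimals
#' @export
predicted_maximum_mortality <- function(params) {
  stop_not_params(params)
  if (params$b <= 0)
    stop("no interior peak: 'b' must be positive", call. = FALSE)
  params$a / (exp(1) * params$b)
}

#' @rdname predicted_maximum_mortality
#' @export
peak_motorization <- function(params) {
  stop_not_params(params)
  if (params$b <= 0)
    stop("no interior peak: 'b' must be positive", call. = FALSE)
  1 / params$b
}

#' Log-linear transformation of a country series
#'
#' Converts observed `(year, deaths, vehicles, population)` records to the
#' regression inputs `x = N/P` (vehicles per person) and
#' `Y = ln(D/P) - ln(N/P)` with `D/P` in deaths per 100,000 persons.
#' Records with zero deaths or zero vehicles have no defined logarithm and
#' are excluded with a message, not an error.
#'
#' @param series A [country_series] object (or a data frame with columns
#'   `year`, `deaths`, `vehicles`, `population`).
#' @return A data frame with columns `year`, `x`, `y`, one row per usable
#'   record, suitable for [fit_ols()].
#' @examples
#' s <- country_series("Demo", data.frame(
#'   year = 2001:2003, deaths = c(900, 1000, 1100),
#'   vehicles = c(4e6, 5e6, 6e6), population = 5e7))
#' transform_series(s)
#' @export
transform_series <- function(series) {
  rec <- series_records(series)
  usable <- rec$deaths > 0 & rec$vehicles > 0
  if (any(!usable))
    message(sum(!usable), " record(s) with zero deaths or vehicles excluded: year(s) ",
            paste(rec$year[!usable], collapse = ", "))
  rec <- rec[usable, , drop = FALSE]
  if (nrow(rec) < 3L)
    stop("fewer than 3 usable records after exclusions; cannot transform",
         call. = FALSE)
  x <- rec$vehicles / rec$population
  y <- log(rec$deaths / rec$population * 1e5) - log(x)
  data.frame(year = rec$year, x = x, y = y)
}

#' Fitted-curve data for plotting
#'
#' Evaluates the fitted mortality curve on an x-grid, for export to an
#' external plotting tool.
#'
#' @inheritParams predict_mortality
#' @param x_grid Numeric vector of motorization levels; defaults to an even
#'   grid from 0 to `3/b` (three times the peak location) when `b > 0`.
#' @param n Grid size used when `x_grid` is not supplied.
#' @return A data frame with columns `x` and `mortality`.
#' @export
smeed_curve <- function(params, x_grid = NULL, n = 200L) {
  stop_not_params(params)
  if (is.null(x_grid)) {
    upper <- if (params$b > 0) 3 / params$b else 1
    x_grid <- seq(0, upper, length.out = n)
  }
  data.frame(x = x_grid, mortality = predict_mortality(params, x_grid))
}
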