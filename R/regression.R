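#' Fit the log-linear Smeed model by ordinary least squares
#'
#' Fits `Y = beta0 + beta1 * x + eps` on transformed points (see
#' [transform_series()]) and converts the coefficients back to the curve
#' parameters `a = exp(beta0)`, `b = -beta1`. Goodness of fit is the
#' coefficient of determination and the overall F test on (1, n - 2)
#' degrees of freedom.
#'
#' @param points Data frame with columns `x`, `y` and optionally `year`;
#'   at least 3 rows, x values not all identical.
#' @return An object of class `smeed_fit`: a list with elements `params`
#'   ([smeed_params]), `r_squared`, `f_stat`, `p_value`, `n`,
#'   `residual_variance` (residual mean square), `sigma`, `points`, and
#'   the underlying `lm` object in `model`.
#' @examples
#' pts <- data.frame(x = c(0.05, 0.1, 0.2, 0.3),
#'                   y = 5.6 - 5.7 * c(0.05, 0.1, 0.2, 0.3))
#' fit_ols(pts)$params$b
#' @export
fit_ols <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  if (nrow(points) < 3L)
    stop("at least 3 points are required", call. = FALSE)
  if (diff(range(points$x)) == 0)
    stop("degenerate design: all x values identical", call. = FALSE)
  model <- stats::lm(y ~ x, data = points)
  sm <- summary(model)
  n <- nrow(points)
  f_stat <- unname(sm$fstatistic["value"])
  p_value <- stats::pf(f_stat, 1, n - 2L, lower.tail = FALSE)
  cf <- stats::coef(model)
  structure(list(
    params = params_from_linear(unname(cf[1L]), unname(cf[2L])),
    r_squared = sm$r.squared,
    f_stat = f_stat,
    p_value = p_value,
    n = n,
    residual_variance = sm$sigma^2,
    sigma = sm$sigma,
    points = points,
    model = model
  ), class = "smeed_fit")
}

#' @export
print.smeed_fit <- function(x, ...) {
  cat(sprintf("Log-linear Smeed fit: n = %d, R^2 = %.3f, F = %.3f, p %s\n",
              x$n, x$r_squared, x$f_stat, format_p(x$p_value)))
  print(x$params)
  invisible(x)
}

# Table-style display convention: p below 0.001 prints as "<0.001".
format_p <- function(p) if (p < 0.001) "<0.001" else sprintf("= %.3f", p)

#' Influence diagnostics for a fitted log-linear Smeed model
#'
#' Computes, per observation: leverage (hat value), the raw residual, the
#' internally and externally studentized residuals, and Cook's distance.
#' Outlier calling follows the convention of flagging observations with
#' |externally studentized residual| strictly greater than `sr_threshold`
#' or Cook's distance strictly greater than `cooks_threshold`. The internal
#' variant is included so the sensitivity of the call to the studentization
#' choice can be inspected.
#'
#' @param fit A `smeed_fit` from [fit_ols()].
#' @param sr_threshold Studentized-residual cutoff (default 3.0).
#' @param cooks_threshold Cook's distance cutoff (default 1.0).
#' @return A data frame with columns `year` (NA if the points carried
#'   none), `x`, `y`, `residual`, `leverage`, `studentized`,
#'   `studentized_internal`, `cooks_d`, `is_outlier`.
#' @export
fit_diagnostics <- function(fit, sr_threshold = 3, cooks_threshold = 1) {
  stopifnot(inherits(fit, "smeed_fit"))
  if (fit$n <= 3L)
    warning("diagnostics with n <= 3 are unstable", call. = FALSE)
  model <- fit$model
  out <- data.frame(
    year = if ("year" %in% names(fit$points)) fit$points$year else NA_integer_,
    x = fit$points$x,
    y = fit$points$y,
    residual = unname(stats::residuals(model)),
    leverage = unname(stats::hatvalues(model)),
    studentized = unname(stats::rstudent(model)),
    studentized_internal = unname(stats::rstandard(model)),
    cooks_d = unname(stats::cooks.distance(model))
  )
  out$is_outlier <- abs(out$studentized) > sr_threshold |
    out$cooks_d > cooks_threshold
  out
}

#' Flag outlying observations from a diagnostics table
#'
#' Returns the rows whose |externally studentized residual| exceeds
#' `sr_threshold` or whose Cook's distance exceeds `cooks_threshold`. Both
#' comparisons are strict, so a value exactly at a threshold is not
#' flagged.
#'
#' @param diags Diagnostics data frame from [fit_diagnostics()].
#' @inheritParams fit_diagnostics
#' @return The flagged subset of `diags` (possibly zero rows).
#' @export
flag_outliers <- function(diags, sr_threshold = 3, cooks_threshold = 1) {
  stopifnot(is.data.frame(diags),
            all(c("studentized", "cooks_d") %in% names(diags)))
  diags[abs(diags$studentized) > sr_threshold |
          diags$cooks_d > cooks_threshold, , drop = FALSE]
}

#' Fit with outlier exclusion and refit
#'
#' The standard modelling procedure: fit all points, compute influence
#' diagnostics, flag outliers, remove them, and refit on the remainder.
#' By default this is a single diagnose-remove-refit pass; `iterate = TRUE`
#' repeats the cycle until no further points are flagged (off by default).
#' If exclusion would leave fewer than 3 points the original fit is
#' returned with a warning and nothing excluded.
#'
#' @param points Data frame with columns `x`, `y` and optionally `year`;
#'   at least 4 rows so the fit survives one exclusion.
#' @inheritParams fit_diagnostics
#' @param iterate Repeat the exclusion cycle until stable?
#' @return An object of class `smeed_fit_result`: a list with elements
#'   `params`, `r_squared`, `f_stat`, `p_value`, `n_used`,
#'   `residual_variance`, `diagnostics` (table for the pre-exclusion fit),
#'   `excluded` (data frame of `year`, `x`, `reason`), `fit` (the final
#'   `smeed_fit`) and `initial_fit`.
#' @examples
#' set.seed(1)
#' x <- seq(0.02, 0.3, length.out = 20)
#' y <- 5.6 - 5.7 * x + rnorm(20, 0, 0.1)
#' y[10] <- y[10] + 1.5
#' fit_with_exclusion(data.frame(year = 1994 + seq_along(x), x = x, y = y))
#' @export
fit_with_exclusion <- function(points, sr_threshold = 3, cooks_threshold = 1,
                               iterate = FALSE) {
  points <- as.data.frame(points)
  if (nrow(points) < 4L)
    stop("at least 4 points are required for exclusion-and-refit",
         call. = FALSE)
  initial_fit <- fit_ols(points)
  diags <- fit_diagnostics(initial_fit, sr_threshold, cooks_threshold)
  excluded <- data.frame(year = integer(), x = numeric(),
                         reason = character())
  current <- points
  current_diags <- diags
  fit <- initial_fit
  repeat {
    flagged <- flag_outliers(current_diags, sr_threshold, cooks_threshold)
    if (nrow(flagged) == 0L) break
    if (nrow(current) - nrow(flagged) < 3L) {
      warning("exclusion would leave fewer than 3 points; ",
              "returning fit without exclusion", call. = FALSE)
      break
    }
    reason <- ifelse(abs(flagged$studentized) > sr_threshold,
                     sprintf("|studentized residual| = %.2f > %.1f",
                             abs(flagged$studentized), sr_threshold),
                     sprintf("Cook's distance = %.2f > %.1f",
                             flagged$cooks_d, cooks_threshold))
    excluded <- rbind(excluded, data.frame(year = flagged$year,
                                           x = flagged$x, reason = reason))
    keep <- !(paste(current_diags$year, current_diags$x) %in%
                paste(flagged$year, flagged$x))
    current <- current[keep, , drop = FALSE]
    fit <- fit_ols(current)
    if (!iterate) break
    current_diags <- fit_diagnostics(fit, sr_threshold, cooks_threshold)
  }
  structure(list(
    params = fit$params,
    r_squared = fit$r_squared,
    f_stat = fit$f_stat,
    p_value = fit$p_value,
    n_used = fit$n,
    residual_variance = fit$residual_variance,
    diagnostics = diags,
    excluded = excluded,
    fit = fit,
    initial_fit = initial_fit
  ), class = "smeed_fit_result")
}

#' @export
print.smeed_fit_result <- function(x, ...) {
  cat(sprintf(
    "Smeed fit with outlier exclusion: n_used = %d, excluded = %d\n",
    x$n_used, nrow(x$excluded)))
  if (nrow(x$excluded))
    cat(paste0("  - ", x$excluded$year, ": ", x$excluded$reason, "\n"),
        sep = "")
  cat(sprintf("  R^2 = %.3f, F = %.3f, p %s\n",
              x$r_squared, x$f_stat, format_p(x$p_value)))
  print(x$params)
  invisible(x)
}

#' Export a fit result
#'
#' `write_fit_json()` serialises a `smeed_fit_result` (parameters,
#' goodness of fit, exclusions) to JSON; `write_diagnostics_csv()` writes
#' the per-observation diagnostics table to CSV.
#'
#' @param result A `smeed_fit_result` from [fit_with_exclusion()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(result, path) {
  stopifnot(inherits(result, "smeed_fit_result"))
  payload <- list(
    params = unclass(result$params),
    r_squared = result$r_squared,
    f_stat = result$f_stat,
    p_value = result$p_value,
    p_display = if (result$p_value < 0.001) "<0.001" else
      formatC(result$p_value, digits = 3, format = "f"),
    n_used = result$n_used,
    residual_variance = result$residual_variance,
    excluded = result$excluded
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_diagnostics_csv <- function(result, path) {
  stopifnot(inherits(result, "smeed_fit_result"))
  utils::write.csv(result$diagnostics, path, row.names = FALSE)
  invisible(path)
}
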