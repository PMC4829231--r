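#' Locate the calendar period of the mortality peak
#'
#' The fitted curve peaks at motorization `1/b`; this maps that level back
#' onto the observed motorization trajectory to label when the country
#' passed (or will pass) its mortality peak:
#'
#' * `"Before <first year>"` if `peak_x` is below the smallest observed
#'   motorization (the country was already past its peak when data begin);
#' * `"After <last year>"` if `peak_x` exceeds the largest observed value;
#' * a single year if some observed motorization matches `peak_x` within
#'   relative tolerance `rel_tol`;
#' * otherwise the pair of observed years bracketing the first crossing,
#'   as `"<year_below>-<year_above>"` (an ASCII hyphen). With gap years
#'   the label spans the gap, e.g. `"1980-1990"`.
#'
#' Motorization trajectories are normally monotone; if not, the first
#' crossing is used and a warning is raised.
#'
#' @param series A [country_series] (or a data frame of records, or a
#'   data frame with columns `year` and `x`).
#' @param peak_x Peak motorization, vehicles per person; positive.
#' @param rel_tol Relative tolerance for calling an exact-year match;
#'   defaults to `1e-3`, the precision at which peak motorization is
#'   conventionally reported (3 decimals).
#' @return A single character label.
#' @examples
#' s <- country_series("Demo", data.frame(
#'   year = 2000:2004, deaths = 1000, vehicles = c(1, 2, 3, 4, 5) * 1e6,
#'   population = 1e7))
#' locate_peak_year(s, 0.25)   # crosses between 2001 and 2002
#' locate_peak_year(s, 0.05)   # "Before 2000"
#' @export
locate_peak_year <- function(series, peak_x, rel_tol = 1e-3) {
  stopifnot(is.numeric(peak_x), length(peak_x) == 1L, is.finite(peak_x),
            peak_x > 0)
  if (is.data.frame(series) && all(c("year", "x") %in% names(series))) {
    year <- series$year
    x <- series$x
  } else {
    rec <- series_records(series)
    year <- rec$year
    x <- rec$vehicles / rec$population
  }
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  ord <- order(year)
  year <- year[ord]
  x <- x[ord]

  near <- abs(x - peak_x) <= rel_tol * peak_x
  if (any(near)) return(as.character(year[which(near)[1L]]))
  if (peak_x < min(x)) return(paste("Before", year[1L]))
  if (peak_x > max(x)) return(paste("After", year[length(year)]))

  d <- diff(x)
  if (any(d > 0) && any(d < 0))
    warning("non-monotone motorization trajectory; using first crossing",
            call. = FALSE)
  cross <- which((x[-length(x)] - peak_x) * (x[-1L] - peak_x) < 0)[1L]
  paste0(year[cross], "-", year[cross + 1L])
}

#' Summarise a fitted model as one peak-analysis report row
#'
#' Combines the closed-form peak quantities of a fit with the observed
#' motorization trajectory: predicted maximum mortality (PMM), the
#' motorization level at the peak, and the calendar period in which the
#' observed trajectory crosses it. With `b <= 0` the curve is monotone:
#' the peak fields are returned as `NA` with an explanatory note, not an
#' error.
#'
#' @param series The [country_series] the model was fitted to.
#' @param fit A `smeed_fit_result` ([fit_with_exclusion()]), `smeed_fit`
#'   ([fit_ols()]), or bare [smeed_params] object.
#' @inheritParams locate_peak_year
#' @return An object of class `peak_summary`: a one-row data frame with
#'   columns `country`, `source_note`, `pmm` (deaths per 100,000),
#'   `peak_x` (vehicles per person), `peak_period`, `note`.
#' @export
summarize_peak <- function(series, fit, rel_tol = 1e-3) {
  params <- if (inherits(fit, "smeed_params")) fit else fit$params
  stop_not_params(params)
  country <- if (inherits(series, "country_series")) series$country else ""
  note <- if (inherits(series, "country_series")) series$source_note else ""
  if (params$b <= 0) {
    out <- data.frame(country = country, source_note = note,
                      pmm = NA_real_, peak_x = NA_real_,
                      peak_period = NA_character_,
                      note = "no interior peak (b <= 0, monotone regime)")
  } else {
    peak_x <- peak_motorization(params)
    out <- data.frame(country = country, source_note = note,
                      pmm = predicted_maximum_mortality(params),
                      peak_x = peak_x,
                      peak_period = locate_peak_year(series, peak_x, rel_tol),
                      note = "")
  }
  class(out) <- c("peak_summary", "data.frame")
  out
}

#' Ranked cross-country comparison of mortality peaks
#'
#' Assembles peak summaries into one report ranked by peak motorization
#' (ascending; ties broken by country label), the ordering used to compare
#' how early in the motorization process each country passed its mortality
#' peak. Optionally, a reference set of countries defines a plausible
#' range: any non-reference entry whose peak motorization falls below the
#' reference minimum is flagged in `below_reference_min` — peaks earlier
#' than every reference country are suspect.
#'
#' The returned table carries `pmm_range` and `peak_x_range` attributes
#' (min/max over all rows with a defined peak).
#'
#' @param summaries A list of `peak_summary` rows from [summarize_peak()].
#' @param reference Optional character vector of country labels forming
#'   the reference set.
#' @return A data frame of class `peak_comparison`, one row per summary,
#'   sorted by `peak_x`, with logical column `below_reference_min`.
#' @export
comparison_table <- function(summaries, reference = NULL) {
  if (inherits(summaries, "peak_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L)
  tab <- do.call(rbind, lapply(summaries, function(s) {
    stopifnot(inherits(s, "peak_summary"))
    as.data.frame(s)
  }))
  tab <- tab[order(tab$peak_x, tab$country), , drop = FALSE]
  rownames(tab) <- NULL
  tab$below_reference_min <- FALSE
  if (!is.null(reference)) {
    in_ref <- tab$country %in% reference
    if (!any(in_ref))
      stop("no summary matches the reference set", call. = FALSE)
    ref_min <- min(tab$peak_x[in_ref], na.rm = TRUE)
    tab$below_reference_min <- !in_ref & !is.na(tab$peak_x) &
      tab$peak_x < ref_min
  }
  defined <- !is.na(tab$peak_x)
  attr(tab, "pmm_range") <- range(tab$pmm[defined])
  attr(tab, "peak_x_range") <- range(tab$peak_x[defined])
  class(tab) <- c("peak_comparison", "data.frame")
  tab
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("Peak-analysis comparison (ranked by peak motorization)\n")
  shown <- as.data.frame(x)
  shown$pmm <- round(shown$pmm, 1)
  shown$peak_x <- round(shown$peak_x, 3)
  print(shown)
  pr <- attr(x, "pmm_range"); xr <- attr(x, "peak_x_range")
  cat(sprintf("PMM range: %.1f-%.1f deaths/100,000; peak motorization range: %.3f-%.3f\n",
              pr[1], pr[2], xr[1], xr[2]))
  invisible(x)
}

#' Export a peak-analysis report
#'
#' Writes a [comparison_table()] to CSV or JSON, with the conventional
#' display rounding (PMM to 1 decimal, peak motorization to 3 decimals).
#'
#' @param tab A `peak_comparison` table.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(tab, path, format = c("csv", "json")) {
  stopifnot(inherits(tab, "peak_comparison"))
  format <- match.arg(format)
  out <- as.data.frame(tab)
  out$pmm <- round(out$pmm, 1)
  out$peak_x <- round(out$peak_x, 3)
  if (format == "csv") utils::write.csv(out, path, row.names = FALSE)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
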