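#' Country-year panel container
#'
#' A `country_series` bundles one country's annual records: calendar year,
#' road-traffic deaths, registered motor vehicles and population, plus the
#' fatality-count definition in force (`"seven_day"` or `"thirty_day"`).
#' Records are stored sorted by year; gap years are allowed — the model
#' treats observations as exchangeable points, not a time series.
#'
#' @param country Country label.
#' @param records Data frame with columns `year`, `deaths`, `vehicles`,
#'   `population`, and optionally `definition` (defaults to
#'   `"thirty_day"`).
#' @param source_note Free-text provenance note (e.g. "police data").
#' @return An object of class `country_series`: a list with elements
#'   `country`, `records`, `source_note`.
#' @examples
#' country_series("Demo", data.frame(
#'   year = 2001:2003, deaths = c(900, 1000, 1100),
#'   vehicles = c(4e6, 5e6, 6e6), population = 5e7))
#' @export
country_series <- function(country, records, source_note = "") {
  stopifnot(is.character(country), length(country) == 1L,
            is.data.frame(records))
  need <- c("year", "deaths", "vehicles", "population")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"definition" %in% names(records))
    records$definition <- "thirty_day"
  bad_def <- !records$definition %in% c("seven_day", "thirty_day")
  if (any(bad_def))
    stop("definition must be 'seven_day' or 'thirty_day'", call. = FALSE)
  if (nrow(records) < 3L)
    stop("a country series needs at least 3 records", call. = FALSE)
  if (anyDuplicated(records$year))
    stop("duplicate year(s) in series for ", country, call. = FALSE)
  if (any(records$population <= 0))
    stop("population must be positive", call. = FALSE)
  if (any(records$deaths < 0) || any(records$vehicles < 0))
    stop("deaths and vehicles must be non-negative", call. = FALSE)
  records <- records[order(records$year),
                     c("year", "deaths", "vehicles", "population", "definition")]
  rownames(records) <- NULL
  structure(list(country = country, records = records,
                 source_note = source_note),
            class = "country_series")
}

#' @export
print.country_series <- function(x, ...) {
  cat(sprintf("Country series: %s (%d records, %d-%d)%s\n", x$country,
              nrow(x$records), min(x$records$year), max(x$records$year),
              if (nzchar(x$source_note)) paste0(" [", x$source_note, "]") else ""))
  print(utils::head(x$records, 5L))
  if (nrow(x$records) > 5L) cat("  ...\n")
  invisible(x)
}

# Accept a country_series or a bare records data frame.
series_records <- function(series) {
  if (inherits(series, "country_series")) return(series$records)
  if (is.data.frame(series)) return(series)
  stop("expected a country_series or a data frame", call. = FALSE)
}

#' Read and write country-year panels
#'
#' `read_panel()` reads a CSV with one row per (country, year) and columns
#' `country`, `year`, `deaths`, `vehicles`, `population` and optionally
#' `definition`, returning one [country_series] per country. Rows with a
#' missing deaths, vehicles or population value are dropped with a message
#' (national yearbooks have occasional gaps). Duplicate (country, year)
#' pairs are an error. `write_panel()` is its inverse.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping the standard
#'   column names to the names used in the file, e.g.
#'   `c(deaths = "fatalities")`.
#' @return `read_panel()`: a named list of [country_series].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' s <- country_series("Demo", data.frame(
#'   year = 2001:2003, deaths = c(900, 1000, 1100),
#'   vehicles = c(4e6, 5e6, 6e6), population = 5e7))
#' write_panel(list(s), tmp)
#' read_panel(tmp)
#' @export
read_panel <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      from <- column_map[[std]]
      if (!from %in% names(raw))
        stop("column_map refers to absent column '", from, "'", call. = FALSE)
      names(raw)[names(raw) == from] <- std
    }
  }
  need <- c("country", "year", "deaths", "vehicles", "population")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"definition" %in% names(raw)) raw$definition <- "thirty_day"
  key <- paste(raw$country, raw$year)
  if (anyDuplicated(key))
    stop("duplicate (country, year) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  incomplete <- is.na(raw$deaths) | is.na(raw$vehicles) | is.na(raw$population)
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " row(s) with missing deaths/vehicles/population: ",
            paste(key[incomplete], collapse = "; "))
    raw <- raw[!incomplete, , drop = FALSE]
  }
  out <- lapply(split(raw, raw$country), function(d)
    country_series(d$country[1L], d[, setdiff(names(d), "country")]))
  out[order(names(out))]
}

#' @rdname read_panel
#' @param series_list A list of [country_series] objects.
#' @export
write_panel <- function(series_list, path) {
  if (inherits(series_list, "country_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "country_series"))
    cbind(country = s$country, s$records)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Convert 7-day fatality counts to the 30-day definition
#'
#' Police statistics in some countries count only deaths occurring within
#' 7 days of the crash; the international convention is 30 days. Following
#' the European Conference of Ministers of Transport standard, 7-day counts
#' are converted by multiplying by 1.08. The factor is a statistical
#' correction, so adjusted counts are kept at full (possibly fractional)
#' precision, not rounded back to integers. Records already on the 30-day
#' definition pass through unchanged, making the operation idempotent.
#'
#' @param x A [country_series], or a data frame of records with `deaths`
#'   and `definition` columns.
#' @return The same type as the input, with 7-day deaths scaled by 1.08 and
#'   `definition` set to `"thirty_day"` everywhere.
#' @examples
#' adjust_fatality_definition(data.frame(
#'   year = 2000, deaths = 1000, vehicles = 1e6, population = 1e7,
#'   definition = "seven_day"))
#' @export
adjust_fatality_definition <- function(x) {
  if (inherits(x, "country_series")) {
    x$records <- adjust_fatality_definition(x$records)
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("deaths", "definition") %in% names(x)))
  seven <- x$definition == "seven_day"
  x$deaths[seven] <- x$deaths[seven] * 1.08
  x$definition[seven] <- "thirty_day"
  x
}

#' Mortality and motorization rates
#'
#' `mortality_per_100k()` returns road-traffic deaths per 100,000 persons;
#' `vehicles_per_person()` returns registered motor vehicles per person.
#' These two scales are the units on which the modified Smeed model is
#' defined and fitted throughout the package.
#'
#' @param x A records data frame (or [country_series]), or a numeric vector
#'   of deaths/vehicles counts.
#' @param population Population count(s); required when `x` is numeric.
#' @return Numeric vector of rates.
#' @examples
#' mortality_per_100k(17500, 1e8)   # 17.5
#' vehicles_per_person(17400000, 1e8)  # 0.174
#' @export
mortality_per_100k <- function(x, population = NULL) {
  counts <- rate_inputs(x, population, "deaths")
  counts$num / counts$pop * 1e5
}

#' @rdname mortality_per_100k
#' @export
vehicles_per_person <- function(x, population = NULL) {
  counts <- rate_inputs(x, population, "vehicles")
  counts$num / counts$pop
}

rate_inputs <- function(x, population, field) {
  if (inherits(x, "country_series")) x <- x$records
  if (is.data.frame(x)) {
    stopifnot(all(c(field, "population") %in% names(x)))
    num <- x[[field]]
    pop <- x$population
  } else {
    if (is.null(population))
      stop("'population' is required when '", field, "' is given as a vector",
           call. = FALSE)
    num <- x
    pop <- population
  }
  if (any(!is.finite(pop)) || any(pop <= 0))
    stop("population must be positive", call. = FALSE)
  list(num = num, pop = pop)
}
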