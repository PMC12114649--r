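# Reading, validation and calendar arithmetic for daily climate and
# phenology tables.

#' Day-of-year of a calendar date
#'
#' 1-based day index within the calendar year: 1 January is 1, 31 December
#' is 365 (366 in leap years). 1 November is day 305 in a common year and
#' 306 in a leap year, the boundary used by the fall-winter accumulation
#' window.
#'
#' @param date a `Date` vector.
#' @return integer vector of day-of-year values.
#' @examples
#' doy(as.Date(c("2001-01-01", "2000-11-01", "2000-12-31")))
#' @export
doy <- function(date) {
  if (!inherits(date, "Date")) stop("`date` must be a Date", call. = FALSE)
  as.POSIXlt(date)$yday + 1L
}

#' Convert a (year, day-of-year) pair to a calendar date
#'
#' The inverse of [doy()]. `d = 0` is accepted and names 31 December of the
#' preceding year, which is convenient when a window ends at "the day before
#' day-of-year S" with S = 1.
#'
#' @param year integer calendar year(s).
#' @param d integer day-of-year (0 allowed, see above).
#' @return a `Date` vector.
#' @export
doy_to_date <- function(year, d) {
  as.Date(d - 1, origin = as.Date(paste0(year, "-01-01")))
}

#' Construct a validated daily climate series
#'
#' Validates a daily temperature table and attaches calendar indexing
#' (year, day-of-year) plus a validation report. Row invariants are
#' `t_min <= t_mean <= t_max`; dates must be unique. Interior missing dates
#' are detected and reported as gaps (they are not imputed; windows that
#' touch a gap fail loudly).
#'
#' @param df data frame with columns `date` (`Date`), `t_min`, `t_max`,
#'   `t_mean` (degrees C).
#' @param strict if `TRUE` (default) any row violating the temperature
#'   ordering is an error; if `FALSE` offending rows are dropped with a
#'   warning (creating gaps).
#' @return a `climate_series`: the ordered data frame with extra columns
#'   `year` and `doy`, and attributes `gaps` (Date vector of missing days)
#'   and `report` (list used by [write_validation_report()]).
#' @export
climate_series <- function(df, strict = TRUE) {
  need <- c("date", "t_min", "t_max", "t_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!inherits(df$date, "Date")) stop("`date` must be Date", call. = FALSE)
  if (anyNA(df$date)) stop("unparseable/missing dates present", call. = FALSE)
  if (anyDuplicated(df$date)) {
    stop("duplicate dates in climate series", call. = FALSE)
  }
  df <- df[order(df$date), need, drop = FALSE]

  bad <- which(!is.finite(df$t_min) | !is.finite(df$t_max) |
    !is.finite(df$t_mean) | df$t_min > df$t_max |
    df$t_mean < df$t_min | df$t_mean > df$t_max)
  if (length(bad)) {
    msg <- sprintf(
      "%d row(s) violate t_min <= t_mean <= t_max (first offending date: %s)",
      length(bad), format(df$date[bad[1]])
    )
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " -- rows dropped", call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid climate records", call. = FALSE)

  full <- seq(min(df$date), max(df$date), by = "day")
  gaps <- full[!full %in% df$date]

  df$year <- as.integer(format(df$date, "%Y"))
  df$doy <- doy(df$date)
  report <- list(
    n_records = nrow(df),
    date_range = format(range(df$date)),
    n_dropped = if (strict) 0L else length(bad),
    n_gaps = length(gaps),
    gap_dates = format(utils::head(gaps, 20L)),
    t_mean_imputed = FALSE
  )
  structure(df,
    gaps = gaps, report = report,
    class = c("climate_series", class(df))
  )
}

#' Read a daily climate CSV
#'
#' Expects a comma-separated file with a header. Columns are resolved
#' through `col_map`; dates are ISO-8601 by default. A missing `t_mean`
#' column is an error unless `impute_t_mean = TRUE`, in which case it is
#' computed as `(t_min + t_max) / 2` and flagged in the validation report.
#'
#' @param path file path.
#' @param col_map named character vector mapping the canonical names
#'   `date`, `t_min`, `t_max`, `t_mean` to the file's column names.
#' @param date_format `strptime` format for the date column.
#' @param impute_t_mean impute a missing daily-mean column from the
#'   min/max midpoint (default `FALSE`: recorded means are required).
#' @param strict passed to [climate_series()].
#' @return a `climate_series`.
#' @export
read_climate_csv <- function(path,
                             col_map = c(
                               date = "date", t_min = "t_min",
                               t_max = "t_max", t_mean = "t_mean"
                             ),
                             date_format = "%Y-%m-%d",
                             impute_t_mean = FALSE,
                             strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_col <- function(canon, required = TRUE) {
    nm <- if (canon %in% names(col_map)) col_map[[canon]] else canon
    if (!nm %in% names(raw)) {
      if (required) {
        stop(sprintf(
          "column `%s` (for %s) not found in %s", nm, canon, path
        ), call. = FALSE)
      }
      return(NULL)
    }
    raw[[nm]]
  }
  dates <- as.Date(as.character(get_col("date")), format = date_format)
  if (anyNA(dates)) {
    stop(sprintf(
      "%d unparseable date(s) in %s (format `%s`)",
      sum(is.na(dates)), path, date_format
    ), call. = FALSE)
  }
  t_mean <- get_col("t_mean", required = !impute_t_mean)
  t_min <- as.numeric(get_col("t_min"))
  t_max <- as.numeric(get_col("t_max"))
  imputed <- is.null(t_mean)
  if (imputed) t_mean <- (t_min + t_max) / 2
  out <- climate_series(
    data.frame(
      date = dates, t_min = t_min, t_max = t_max,
      t_mean = as.numeric(t_mean)
    ),
    strict = strict
  )
  attr(out, "report")$t_mean_imputed <- imputed
  out
}

#' Write a climate series back to CSV
#'
#' Inverse of [read_climate_csv()]; a write/read round trip reproduces all
#' fields.
#'
#' @param series a `climate_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(series, path) {
  utils::write.csv(
    data.frame(
      date = format(series$date), t_min = series$t_min,
      t_max = series$t_max, t_mean = series$t_mean
    ),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a phenology CSV (year, observed event day-of-year)
#'
#' @param path file path.
#' @param col_map named character vector mapping `year` and `ffd` to the
#'   file's column names.
#' @return data frame with integer columns `year` and `ffd` (day-of-year of
#'   the observed event, 1-based), one row per year, sorted by year.
#' @export
read_phenology_csv <- function(path, col_map = c(year = "year", ffd = "ffd_doy")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (canon in c("year", "ffd")) {
    nm <- col_map[[canon]]
    if (!nm %in% names(raw)) {
      stop(sprintf("column `%s` not found in %s", nm, path), call. = FALSE)
    }
  }
  phenology_records(raw[[col_map[["year"]]]], raw[[col_map[["ffd"]]]])
}

#' Construct validated phenology records
#'
#' @param year integer years (unique).
#' @param ffd observed event day-of-year per year, in 1..366.
#' @return data frame `year`, `ffd` sorted by year.
#' @export
phenology_records <- function(year, ffd) {
  year <- as.integer(year)
  ffd <- as.numeric(ffd)
  if (anyNA(year) || anyNA(ffd)) stop("NA in phenology records", call. = FALSE)
  if (anyDuplicated(year)) stop("duplicate years", call. = FALSE)
  if (any(ffd < 1 | ffd > 366)) {
    stop("observed day-of-year outside 1..366", call. = FALSE)
  }
  out <- data.frame(year = year, ffd = ffd)
  out[order(out$year), , drop = FALSE]
}

#' Extract an inclusive window of daily records
#'
#' Returns the ordered slice of a climate series between two (year,
#' day-of-year) endpoints, both inclusive, crossing the year boundary
#' correctly. Any missing day inside the window is an error naming the
#' dates.
#'
#' @param series a `climate_series`.
#' @param from_year,from_doy start endpoint.
#' @param to_year,to_doy end endpoint.
#' @return data frame of daily records (date, t_min, t_max, t_mean, year,
#'   doy).
#' @export
climate_window <- function(series, from_year, from_doy, to_year, to_doy) {
  from <- doy_to_date(from_year, from_doy)
  to <- doy_to_date(to_year, to_doy)
  if (from > to) stop("window start is after window end", call. = FALSE)
  wanted <- seq(from, to, by = "day")
  idx <- match(wanted, series$date)
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop(sprintf(
      "climate series does not cover %d day(s) in the window %s..%s (first missing: %s)",
      length(missing), format(from), format(to), format(missing[1])
    ), call. = FALSE)
  }
  as.data.frame(series)[idx, , drop = FALSE]
}

#' Write the validation report of a climate series as JSON
#'
#' @param series a `climate_series`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(series, path) {
  jsonlite::write_json(attr(series, "report"), path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

# Per-year daily-mean temperature vectors indexed by day-of-year, used by
# the forcing methods. Returns a list keyed by year: numeric vector with
# element j = t_mean on day-of-year j, covering 1..(last covered DOY).
# Requires complete coverage from DOY 1 through at least `through_doy`.
.year_tmean <- function(series, years, through_doy = NULL) {
  out <- vector("list", length(years))
  names(out) <- as.character(years)
  for (k in seq_along(years)) {
    y <- years[k]
    sub <- series[series$year == y, , drop = FALSE]
    if (!nrow(sub)) stop("no climate data for year ", y, call. = FALSE)
    sub <- sub[order(sub$doy), , drop = FALSE]
    need <- if (is.null(through_doy)) max(sub$doy) else through_doy
    if (!identical(sub$doy[seq_len(min(nrow(sub), need))], seq_len(need)) ||
      nrow(sub) < need) {
      stop(sprintf(
        "climate data for year %d must cover day-of-year 1..%d without gaps",
        y, need
      ), call. = FALSE)
    }
    out[[k]] <- sub$t_mean
  }
  out
}
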