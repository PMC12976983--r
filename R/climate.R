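#' Column mapping for daily climate files
#'
#' Describes how to read a delimited daily climate file: which columns hold
#' the date, the daily mean temperature and the 24-h rainfall total, and the
#' date format. The default matches the package's native schema
#' `date,tmean_c,rain_mm` with ISO-8601 dates.
#'
#' @param date_col,temp_col,rain_col Column names in the file.
#' @param date_format A [base::strptime()] format string for the date column.
#'
#' @return A list of class `climate_dialect`.
#' @export
#' @examples
#' climate_dialect(date_col = "Date", temp_col = "Value", date_format = "%d/%m/%Y")
climate_dialect <- function(date_col = "date", temp_col = "tmean_c",
                            rain_col = "rain_mm", date_format = "%Y-%m-%d") {
  structure(
    list(date_col = date_col, temp_col = temp_col, rain_col = rain_col,
         date_format = date_format),
    class = "climate_dialect"
  )
}

#' Read and validate a daily climate series
#'
#' Reads a delimited text file of daily mean temperature (deg C) and total
#' rainfall (mm), validates it (unique, parseable dates; non-negative rain;
#' finite temperature) and returns it ordered by date. Calendar gaps are
#' permitted; they are reported by [climate_gaps()].
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @param dialect A [climate_dialect()] naming the columns.
#'
#' @return A tibble with columns `date`, `tmean_c`, `rain_mm`, one row per
#'   observed day, strictly increasing in `date`.
#' @export
read_daily_climate <- function(path, dialect = climate_dialect()) {
  stopifnot(inherits(dialect, "climate_dialect"))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(dialect$date_col, dialect$temp_col, dialect$rain_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(glue::glue("climate file is missing column(s): {toString(missing_cols)}"))
  }
  dates <- as.Date(as.character(raw[[dialect$date_col]]),
                   format = dialect$date_format)
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    abort(glue::glue(
      "unparseable date in climate file at data row {bad[1]}: ",
      "'{raw[[dialect$date_col]][bad[1]]}' (format '{dialect$date_format}')"
    ))
  }
  out <- tibble(
    date = dates,
    tmean_c = as.numeric(raw[[dialect$temp_col]]),
    rain_mm = as.numeric(raw[[dialect$rain_col]])
  )
  validate_climate(out)
}

#' Validate a daily climate tibble
#'
#' Used by [read_daily_climate()] and by the weather generator; exported so
#' climate data assembled in R can be checked against the same invariants.
#'
#' @param climate A data frame with columns `date` (Date), `tmean_c`, `rain_mm`.
#' @return The validated tibble, sorted by date.
#' @export
validate_climate <- function(climate) {
  climate <- as_tibble(climate)
  stopifnot(all(c("date", "tmean_c", "rain_mm") %in% names(climate)))
  if (!inherits(climate$date, "Date")) {
    abort("`date` must be a Date column")
  }
  dup <- climate$date[duplicated(climate$date)]
  if (length(dup) > 0) {
    abort(glue::glue("duplicate date(s) in climate series: {toString(head(unique(dup), 5))}"))
  }
  if (any(!is.finite(climate$tmean_c))) {
    abort("non-finite tmean_c in climate series")
  }
  if (any(is.na(climate$rain_mm) | climate$rain_mm < 0)) {
    abort("rain_mm must be present and >= 0 for every day")
  }
  arrange(climate, .data$date)
}

#' List calendar days missing from a climate series
#'
#' @param climate A validated climate tibble.
#' @return A tibble with column `date` holding every calendar day inside the
#'   series span that has no record (empty if the series is gap-free).
#' @export
climate_gaps <- function(climate) {
  full <- seq(min(climate$date), max(climate$date), by = "day")
  tibble(date = as.Date(setdiff(full, climate$date), origin = "1970-01-01"))
}

#' Compute a monthly climate baseline
#'
#' Averages daily mean temperature and rainfall per baseline key. Two modes
#' are supported: `"calendar_month_longterm"` pools all years, giving one
#' long-term mean per calendar month (the default used for ECE calibration);
#' `"month_within_year"` keeps each year-month separate.
#'
#' @param climate A validated climate tibble.
#' @param mode Baseline mode; see Details.
#' @return A tibble of baseline means: columns `month` (and `year` for
#'   `month_within_year`), `tmean_bar`, `rain_bar`; the mode is stored in the
#'   `baseline_mode` attribute.
#' @export
compute_monthly_baseline <- function(climate,
                                     mode = c("calendar_month_longterm",
                                              "month_within_year")) {
  mode <- match.arg(mode)
  if (nrow(climate) == 0) abort("empty climate series")
  keyed <- mutate(climate,
                  month = as.integer(format(.data$date, "%m")),
                  year = as.integer(format(.data$date, "%Y")))
  keys <- if (mode == "calendar_month_longterm") "month" else c("year", "month")
  out <- keyed |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(tmean_bar = mean(.data$tmean_c),
              rain_bar = mean(.data$rain_mm), .groups = "drop")
  if (any(!is.finite(out$tmean_bar)) || any(!is.finite(out$rain_bar))) {
    abort("non-finite baseline value; check the input series")
  }
  attr(out, "baseline_mode") <- mode
  out
}

#' Daily deviations from a monthly baseline
#'
#' Subtracts the baseline mean for each day's key from the raw daily values,
#' yielding the temperature and rainfall deviation series on which ECE
#' thresholds are calibrated. `deviation + baseline` reconstructs the raw
#' series exactly.
#'
#' @param climate A validated climate tibble.
#' @param baseline Output of [compute_monthly_baseline()].
#' @return A tibble `date, tmean_c, rain_mm, tdev_c, raindev_mm` with the
#'   baseline mode recorded in the `baseline_mode` attribute.
#' @export
compute_deviations <- function(climate, baseline) {
  mode <- attr(baseline, "baseline_mode")
  if (is.null(mode)) abort("`baseline` must come from compute_monthly_baseline()")
  keyed <- mutate(climate,
                  month = as.integer(format(.data$date, "%m")),
                  year = as.integer(format(.data$date, "%Y")))
  keys <- if (mode == "calendar_month_longterm") "month" else c("year", "month")
  joined <- left_join(keyed, baseline, by = keys)
  uncovered <- filter(joined, is.na(.data$tmean_bar))
  if (nrow(uncovered) > 0) {
    abort(glue::glue(
      "baseline does not cover date(s): {toString(head(uncovered$date, 5))}"
    ))
  }
  out <- joined |>
    mutate(tdev_c = .data$tmean_c - .data$tmean_bar,
           raindev_mm = .data$rain_mm - .data$rain_bar) |>
    select("date", "tmean_c", "rain_mm", "tdev_c", "raindev_mm")
  attr(out, "baseline_mode") <- mode
  out
}

#' Write a climate series in the package's native CSV schema
#'
#' @param climate A validated climate tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_climate <- function(climate, path) {
  readr::write_csv(select(climate, "date", "tmean_c", "rain_mm"), path)
  invisible(path)
}
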