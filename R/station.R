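# Station weather series container and leafing-observation validation.

#' Daily weather series for one station
#'
#' Bundles station metadata with a gap-free daily weather table. The table
#' must have one row per calendar day with strictly increasing dates (leap
#' days included in leap years), non-negative precipitation, `tmin <= tmean`,
#' and relative humidity (when present) within \[0, 100\]. `rh` is the only
#' field that may be missing; it is required only by the GSI model.
#'
#' @param station_id station label.
#' @param latitude degrees north.
#' @param longitude degrees east.
#' @param elevation metres above sea level.
#' @param data data.frame with columns `date` (Date), `tmean`, `tmin`,
#'   `precip`, `rh`.
#' @return an object of class `station_series`.
#' @export
station_series <- function(station_id, latitude, longitude, elevation, data) {
  required <- c("date", "tmean", "tmin", "precip", "rh")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    ptp_stop("phenoTP_validation_error", "weather data lacks columns: %s",
             paste(missing_cols, collapse = ", "))
  }
  data <- data[required]
  if (!inherits(data$date, "Date")) data$date <- as.Date(data$date)
  if (nrow(data) == 0L) {
    ptp_stop("phenoTP_validation_error", "weather data has no rows")
  }
  dd <- diff(as.integer(data$date))
  if (any(dd != 1L)) {
    bad <- which(dd != 1L)[1]
    ptp_stop("phenoTP_coverage_error",
             "weather series is not contiguous: gap or disorder between %s and %s",
             data$date[bad], data$date[bad + 1L])
  }
  for (col in c("tmean", "tmin", "precip")) {
    if (any(is.na(data[[col]]))) {
      ptp_stop("phenoTP_validation_error",
               "column '%s' has missing values (first at %s)", col,
               data$date[which(is.na(data[[col]]))[1]])
    }
  }
  if (any(data$precip < 0)) {
    ptp_stop("phenoTP_validation_error",
             "negative precipitation at %s",
             data$date[which(data$precip < 0)[1]])
  }
  if (any(data$tmin > data$tmean + 1e-9)) {
    ptp_stop("phenoTP_validation_error",
             "tmin exceeds tmean at %s",
             data$date[which(data$tmin > data$tmean + 1e-9)[1]])
  }
  rh_bad <- !is.na(data$rh) & (data$rh < 0 | data$rh > 100)
  if (any(rh_bad)) {
    ptp_stop("phenoTP_validation_error",
             "relative humidity outside [0, 100] at %s",
             data$date[which(rh_bad)[1]])
  }
  structure(
    list(station_id = as.character(station_id),
         latitude = as.numeric(latitude),
         longitude = as.numeric(longitude),
         elevation = as.numeric(elevation),
         data = data),
    class = "station_series"
  )
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("<station_series '%s'> %s to %s (%d days), lat %.2f, lon %.2f, elev %.0f m\n",
              x$station_id, min(x$data$date), max(x$data$date),
              nrow(x$data), x$latitude, x$longitude, x$elevation))
  invisible(x)
}

series_start <- function(series) series$data$date[1L]
series_end <- function(series) series$data$date[nrow(series$data)]

# Row index of `date` within a contiguous series (no bounds check).
series_row <- function(series, date) {
  as.integer(as.Date(date) - series_start(series)) + 1L
}

check_coverage <- function(series, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from < series_start(series) || to > series_end(series)) {
    ptp_stop("phenoTP_coverage_error",
             "series '%s' covers %s to %s but %s to %s is required",
             series$station_id, series_start(series), series_end(series),
             from, to)
  }
  invisible(TRUE)
}

#' Extract a contiguous sub-series
#'
#' @param series a [station_series()].
#' @param start,end first and last dates to keep (inclusive); both must lie
#'   within the series coverage.
#' @return a `station_series` spanning exactly `start` to `end`.
#' @export
slice_window <- function(series, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) {
    ptp_stop("phenoTP_input_error", "start date %s is after end date %s",
             start, end)
  }
  check_coverage(series, start, end)
  rows <- series_row(series, start):series_row(series, end)
  station_series(series$station_id, series$latitude, series$longitude,
                 series$elevation, series$data[rows, , drop = FALSE])
}

#' Total precipitation over one calendar year
#'
#' Sums daily precipitation from Jan 1 to Dec 31 of `year`; this is the
#' previous-year precipitation total `P_b` used by the TP model.
#'
#' @param series a [station_series()] covering the full calendar year.
#' @param year calendar year.
#' @return precipitation sum, mm.
#' @export
annual_precip <- function(series, year) {
  check_coverage(series, jan1(year), dec31(year))
  rows <- series_row(series, jan1(year)):series_row(series, dec31(year))
  sum(series$data$precip[rows])
}

#' Validate a table of leafing observations
#'
#' @param df data.frame with columns `station_id`, `species`, `year`,
#'   `leafing_doy` (integer day of year in \[1, 366\], not exceeding the
#'   length of `year`). Duplicate (station, species, year) keys are rejected.
#' @return the validated data.frame, invisibly classed `leafing_observations`.
#' @export
leafing_observations <- function(df) {
  required <- c("station_id", "species", "year", "leafing_doy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ptp_stop("phenoTP_validation_error", "phenology data lacks columns: %s",
             paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$year <- as.integer(df$year)
  df$leafing_doy <- as.integer(df$leafing_doy)
  if (any(is.na(df$year)) || any(is.na(df$leafing_doy))) {
    ptp_stop("phenoTP_validation_error",
             "missing or non-numeric year/leafing_doy (row %d)",
             which(is.na(df$year) | is.na(df$leafing_doy))[1])
  }
  bad <- df$leafing_doy < 1L | df$leafing_doy > days_in_year(df$year)
  if (any(bad)) {
    ptp_stop("phenoTP_validation_error",
             "leafing_doy out of range for its year (row %d: doy %d, year %d)",
             which(bad)[1], df$leafing_doy[which(bad)[1]], df$year[which(bad)[1]])
  }
  key <- paste(df$station_id, df$species, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    ptp_stop("phenoTP_validation_error",
             "duplicate (station, species, year) observation (row %d)",
             which(duplicated(key))[1])
  }
  class(df) <- c("leafing_observations", "data.frame")
  df
}
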