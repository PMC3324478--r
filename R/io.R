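# CSV surfaces. Weather files use the dialect
#   date,tmean,tmin,precip,rh        (ISO-8601 dates; only rh may be empty)
# phenology files use
#   station_id,species,year,leafing_doy
# and station metadata files use
#   station_id,latitude,longitude,elevation

#' Read a daily weather CSV into a station series
#'
#' The header must be exactly `date,tmean,tmin,precip,rh`. Dates are
#' ISO-8601; an empty field means missing, which is tolerated only for `rh`.
#' Gaps and invariant violations are reported with the offending date or
#' line number.
#'
#' @param path CSV file path.
#' @param station_id,latitude,longitude,elevation station metadata (the
#'   weather dialect itself carries none); latitude is required by the GSI
#'   model.
#' @return a [station_series()].
#' @export
read_weather_csv <- function(path, station_id = "station",
                             latitude = NA_real_, longitude = NA_real_,
                             elevation = NA_real_) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, c("date", "tmean", "tmin", "precip", "rh"))) {
    ptp_stop("phenoTP_parse_error",
             "weather header must be 'date,tmean,tmin,precip,rh', got '%s'",
             paste(header, collapse = ","))
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "numeric", "numeric", "numeric",
                                "numeric"))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    ptp_stop("phenoTP_parse_error", "unparseable date '%s' at line %d",
             df$date[which(is.na(dates))[1]], which(is.na(dates))[1] + 1L)
  }
  df$date <- dates
  station_series(station_id, latitude, longitude, elevation, df)
}

#' Write a station series to the weather CSV dialect
#'
#' Numeric values are written at full round-trip precision so that
#' write-then-read reproduces the series exactly.
#'
#' @param series a [station_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path) {
  d <- series$data
  out <- data.frame(date = format(d$date, "%Y-%m-%d"),
                    tmean = format(d$tmean, digits = 17, trim = TRUE),
                    tmin = format(d$tmin, digits = 17, trim = TRUE),
                    precip = format(d$precip, digits = 17, trim = TRUE),
                    rh = ifelse(is.na(d$rh), "",
                                format(d$rh, digits = 17, trim = TRUE)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read leafing observations from CSV
#'
#' Header must be `station_id,species,year,leafing_doy`; out-of-range days
#' of year and duplicate (station, species, year) keys are rejected with the
#' offending row.
#'
#' @param path CSV file path.
#' @return a [leafing_observations()] data.frame.
#' @export
read_phenology_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, c("station_id", "species", "year", "leafing_doy"))) {
    ptp_stop("phenoTP_parse_error",
             "phenology header must be 'station_id,species,year,leafing_doy', got '%s'",
             paste(header, collapse = ","))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  leafing_observations(df)
}

#' Write leafing observations to CSV
#'
#' @param observations a [leafing_observations()] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenology_csv <- function(observations, path) {
  write.csv(as.data.frame(observations)[
    c("station_id", "species", "year", "leafing_doy")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read station metadata CSV
#'
#' Header `station_id,latitude,longitude,elevation`.
#'
#' @param path CSV file path.
#' @return data.frame of station metadata.
#' @export
read_station_metadata <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header,
                 c("station_id", "latitude", "longitude", "elevation"))) {
    ptp_stop("phenoTP_parse_error",
             "metadata header must be 'station_id,latitude,longitude,elevation'")
  }
  read.csv(path, stringsAsFactors = FALSE)
}
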