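# Calendar and derived-meteorology helpers shared by every model.

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_year <- function(year) {
  ifelse(is_leap_year(year), 366L, 365L)
}

#' Day of year (1-based Julian day)
#'
#' @param date a `Date` vector.
#' @return Integer day-of-year, 1 for Jan 1, up to 366 in leap years.
#' @export
doy_of <- function(date) {
  as.POSIXlt(date)$yday + 1L
}

jan1 <- function(year) as.Date(sprintf("%d-01-01", year))
dec31 <- function(year) as.Date(sprintf("%d-12-31", year))

#' Saturation vapor pressure (Tetens formula)
#'
#' `es = 610.7 * 10^(7.5 T / (237.3 + T))` in pascals, the standard
#' over-water Tetens approximation used in the growing-season-index
#' literature.
#'
#' @param tmean air temperature, degrees C.
#' @return saturation vapor pressure, Pa.
#' @export
saturation_vapor_pressure <- function(tmean) {
  610.7 * 10 ^ (7.5 * tmean / (237.3 + tmean))
}

#' Vapor pressure deficit from mean temperature and relative humidity
#'
#' VPD = es(tmean) * (1 - rh/100), with es the Tetens saturation vapor
#' pressure. Uses daily mean temperature and daily mean relative humidity.
#'
#' @param tmean daily mean air temperature, degrees C.
#' @param rh daily mean relative humidity, percent, in \[0, 100\].
#' @return vapor pressure deficit, Pa (>= 0).
#' @export
#' @examples
#' compute_vpd(20, 100) # saturated air: 0
#' compute_vpd(20, 50)
compute_vpd <- function(tmean, rh) {
  if (any(is.na(rh)) || any(rh < 0 | rh > 100)) {
    ptp_stop("phenoTP_domain_error",
             "relative humidity must be within [0, 100] and non-missing")
  }
  saturation_vapor_pressure(tmean) * (1 - rh / 100)
}

#' Astronomical day length
#'
#' Photoperiod from the sunrise equation: the solar declination follows the
#' Forsythe et al. (1995) revolution-angle formulation,
#' `delta = asin(0.39795 cos(0.2163108 + 2 atan(0.9671396 tan(0.00860 (doy - 186)))))`,
#' and the sunset hour angle is `omega = acos(-tan(lat) tan(delta))`; day
#' length is `86400 * omega / pi` seconds. No atmospheric refraction or
#' twilight correction is applied.
#'
#' @param latitude degrees north; must satisfy `abs(latitude) < 66.5`
#'   (polar day/night is outside the supported domain).
#' @param doy day of year (may be a vector).
#' @return day length in seconds, in (0, 86400).
#' @export
#' @examples
#' compute_photoperiod(43.95, 172) # near-solstice day length, seconds
compute_photoperiod <- function(latitude, doy) {
  if (any(is.na(latitude)) || any(abs(latitude) >= 66.5)) {
    ptp_stop("phenoTP_domain_error",
             "latitude must satisfy |latitude| < 66.5 degrees")
  }
  decl <- asin(0.39795 * cos(0.2163108 +
                               2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))))
  x <- -tan(latitude * pi / 180) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  86400 * acos(x) / pi
}
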