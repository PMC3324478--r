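# Synthetic daily weather and leafing observations with known ground truth.
#
# The default climate emulates a continental monsoon station in Northeast
# China: annual mean near 4.5 degrees C with a seasonal swing from about
# -18 degrees C in January to about 22 degrees C in July, roughly 514 mm of
# annual precipitation of which about three quarters falls May-August.

#' Synthetic climate configuration
#'
#' Defines the statistical climate of [generate_weather()]: a sinusoidal
#' mean-temperature cycle with AR(1) residuals (synoptic anomalies persist
#' across days), daily minimum temperature offset below the mean,
#' occurrence-times-amount precipitation (monthly wet-day probability and a
#' gamma amount distribution), and Gaussian relative humidity clipped to
#' \[5, 100\].
#'
#' @param annual_mean annual mean temperature, degrees C.
#' @param amplitude seasonal half-range of the temperature cycle, degrees C.
#' @param peak_doy day of year of the warmest day.
#' @param ar1 AR(1) coefficient of daily temperature residuals, in \[0, 1).
#' @param resid_sd innovation standard deviation of the residuals, degrees C.
#' @param tmin_offset_mean,tmin_offset_sd mean/sd of the (positive) offset of
#'   tmin below tmean, degrees C.
#' @param wet_prob length-12 vector of wet-day probabilities per month.
#' @param gamma_shape,gamma_scale gamma parameters of wet-day precipitation,
#'   mm.
#' @param rh_mean,rh_sd relative humidity mean/sd, percent.
#' @param latitude station latitude, degrees north.
#' @return a `climate_config` list.
#' @export
climate_config <- function(annual_mean = 4.5, amplitude = 20.3,
                           peak_doy = 205L, ar1 = 0.7, resid_sd = 3.5,
                           tmin_offset_mean = 5.5, tmin_offset_sd = 1.5,
                           wet_prob = c(0.05, 0.05, 0.08, 0.12, 0.50, 0.60,
                                        0.65, 0.55, 0.18, 0.10, 0.06, 0.05),
                           gamma_shape = 0.7, gamma_scale = 8,
                           rh_mean = 62, rh_sd = 12, latitude = 43.95) {
  if (amplitude < 0) ptp_stop("phenoTP_input_error", "amplitude must be >= 0")
  if (ar1 < 0 || ar1 >= 1) {
    ptp_stop("phenoTP_input_error", "ar1 must lie in [0, 1)")
  }
  if (resid_sd < 0 || tmin_offset_sd < 0 || rh_sd < 0) {
    ptp_stop("phenoTP_input_error", "standard deviations must be >= 0")
  }
  if (length(wet_prob) != 12L || any(wet_prob < 0 | wet_prob > 1)) {
    ptp_stop("phenoTP_input_error",
             "wet_prob must be 12 monthly probabilities in [0, 1]")
  }
  if (gamma_shape <= 0 || gamma_scale <= 0) {
    ptp_stop("phenoTP_input_error", "gamma shape and scale must be > 0")
  }
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 peak_doy = as.integer(peak_doy), ar1 = ar1,
                 resid_sd = resid_sd, tmin_offset_mean = tmin_offset_mean,
                 tmin_offset_sd = tmin_offset_sd, wet_prob = wet_prob,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 rh_mean = rh_mean, rh_sd = rh_sd, latitude = latitude),
            class = "climate_config")
}

#' Generate a synthetic daily weather series
#'
#' Draws a gap-free daily series of `n_years` calendar years starting Jan 1
#' of `start_year` from the climate in `config`. The mean temperature is a
#' sinusoid plus AR(1) noise, `tmin = tmean - |offset draw|`, precipitation
#' is Bernoulli(wet) times a gamma amount, and relative humidity is Gaussian
#' clipped to \[5, 100\]. Fully reproducible per seed; the caller's RNG
#' state is untouched.
#'
#' @param config a [climate_config()].
#' @param start_year first calendar year.
#' @param n_years number of years (>= 2, so accumulation models have a
#'   previous year).
#' @param seed integer random seed.
#' @param station_id label for the generated station.
#' @return a [station_series()].
#' @export
generate_weather <- function(config, start_year, n_years, seed,
                             station_id = "synthetic") {
  stopifnot(inherits(config, "climate_config"))
  if (n_years < 2) {
    ptp_stop("phenoTP_input_error",
             "n_years must be >= 2 (models need the previous year)")
  }
  dates <- seq(jan1(start_year), dec31(start_year + n_years - 1L), by = "day")
  n <- length(dates)
  doy <- doy_of(dates)
  month <- as.POSIXlt(dates)$mon + 1L
  clim <- config$annual_mean +
    config$amplitude * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  with_seed(seed, {
    resid <- numeric(n)
    if (config$resid_sd > 0) {
      resid[1] <- rnorm(1, 0, config$resid_sd / sqrt(1 - config$ar1^2))
      innov <- rnorm(n - 1L, 0, config$resid_sd)
      for (t in 2:n) resid[t] <- config$ar1 * resid[t - 1L] + innov[t - 1L]
    }
    tmean <- clim + resid
    tmin <- tmean - abs(rnorm(n, config$tmin_offset_mean, config$tmin_offset_sd))
    wet <- runif(n) < config$wet_prob[month]
    precip <- ifelse(wet,
                     rgamma(n, shape = config$gamma_shape,
                            scale = config$gamma_scale), 0)
    rh <- pmin(100, pmax(5, rnorm(n, config$rh_mean, config$rh_sd)))
    station_series(station_id, config$latitude, 120, 500,
                   data.frame(date = dates, tmean = tmean, tmin = tmin,
                              precip = precip, rh = rh))
  })
}

#' Ground-truth specification for synthetic leafing observations
#'
#' @param params a `model_params` object: the generating model and its true
#'   parameter values.
#' @param noise_sd observation noise standard deviation, days (>= 0);
#'   predicted dates are perturbed by centred Gaussian noise and rounded to
#'   integer DOY.
#' @param species,station_id labels written into the observations.
#' @return a `truth_spec` list.
#' @export
truth_spec <- function(params, noise_sd = 1, species = "synthetic",
                       station_id = "synthetic") {
  stopifnot(inherits(params, "model_params"))
  if (noise_sd < 0) ptp_stop("phenoTP_input_error", "noise_sd must be >= 0")
  structure(list(params = params, noise_sd = noise_sd, species = species,
                 station_id = station_id),
            class = "truth_spec")
}

#' Generate leafing observations from a known model
#'
#' Predicts a leafing date for every usable year of `series` with the truth
#' model (the first year is skipped: accumulation models need previous-year
#' weather), adds rounded Gaussian observation noise, and clips to
#' \[1, days-in-year\]. A year in which the truth model never reaches its
#' thresholds raises a generation error naming the year, so the caller can
#' adjust the truth parameters.
#'
#' @param series a [station_series()].
#' @param truth a [truth_spec()].
#' @param seed integer random seed.
#' @return a [leafing_observations()] data.frame with one row per usable
#'   year.
#' @export
generate_leafing <- function(series, truth, seed) {
  stopifnot(inherits(truth, "truth_spec"))
  y0 <- as.POSIXlt(series_start(series))$year + 1900L
  y1 <- as.POSIXlt(series_end(series))$year + 1900L
  years <- (y0 + 1L):y1
  if (length(years) < 1L || series_start(series) != jan1(y0) ||
      series_end(series) != dec31(y1)) {
    ptp_stop("phenoTP_input_error",
             "series must span whole calendar years with at least one usable year")
  }
  pred <- predict_years(series, truth$params, years)
  if (any(is.na(pred$predicted_doy))) {
    ptp_stop("phenoTP_generation_error",
             "truth model reaches no leafing date in year(s): %s",
             paste(pred$year[is.na(pred$predicted_doy)], collapse = ", "))
  }
  with_seed(seed, {
    noisy <- pred$predicted_doy + round(rnorm(length(years), 0, truth$noise_sd))
    noisy <- pmin(days_in_year(years), pmax(1, noisy))
    leafing_observations(data.frame(
      station_id = truth$station_id, species = truth$species,
      year = years, leafing_doy = as.integer(noisy)))
  })
}
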