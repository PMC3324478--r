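# The six leafing-date predictors. Each model is a pure function from a
# station series plus parameters to a prediction for one leafing year.
#
# Conventions (shared with the calibrator):
#   - accumulation sums include both t0 and the candidate day;
#   - leafing is the FIRST day the defining inequality holds (>=, not >);
#   - the leafing day is reported as a day number relative to Jan 1 of the
#     leafing year (1 = Jan 1); a threshold met in the preceding autumn
#     yields values <= 0, keeping errors continuous across New Year;
#   - a threshold never reached by Dec 31 gives leafing_doy = NA.

#' Degree-day forcing rate
#'
#' `max(0, tmean - T_b)`: heat accumulated above the base temperature.
#'
#' @param tmean daily mean temperature, degrees C (vectorized).
#' @param T_b base temperature, degrees C.
#' @return degree-days contributed by the day, degree C day.
#' @export
forcing_gdd <- function(tmean, T_b) {
  pmax(0, tmean - T_b)
}

#' Sigmoid forcing rate
#'
#' `va / (1 + exp(vb * (tmean + vc)))`, the logistic forcing response used by
#' the sequential and parallel models; strictly increasing in `tmean` when
#' `vb < 0`, with upper asymptote `va` and midpoint `va / 2` at
#' `tmean = -vc`.
#'
#' @param tmean daily mean temperature, degrees C (vectorized).
#' @param va,vb,vc sigmoid constants (`va > 0`).
#' @return forcing units contributed by the day.
#' @export
forcing_sigmoid <- function(tmean, va = 28.4, vb = -0.185, vc = -18.4) {
  va / (1 + exp(vb * (tmean + vc)))
}

#' Triangular chilling rate
#'
#' Zero at or outside `T_low` and `T_high`, rising linearly to 1 at the
#' optimum `T_o`.
#'
#' @param tmean daily mean temperature, degrees C (vectorized).
#' @param T_low,T_o,T_high triangle feet and peak (`T_low < T_o < T_high`).
#' @return chill units contributed by the day, in \[0, 1\].
#' @export
chilling_triangular <- function(tmean, T_low = -3.4, T_o = 5, T_high = 10.4) {
  check_chill_shape(T_low, T_o, T_high)
  out <- numeric(length(tmean))
  up <- tmean > T_low & tmean <= T_o
  down <- tmean > T_o & tmean < T_high
  out[up] <- (tmean[up] - T_low) / (T_o - T_low)
  out[down] <- (T_high - tmean[down]) / (T_high - T_o)
  out
}

first_at_least <- function(x, threshold) {
  idx <- which(x >= threshold)
  if (length(idx)) idx[1L] else NA_integer_
}

# ---- accumulator cores -----------------------------------------------------
# Each core takes numeric vectors starting at t0 and ending Dec 31 of the
# leafing year, and returns 1-based indices relative to t0 (NA = not reached).

core_sw <- function(tmean, T_b, F_star) {
  list(idx = first_at_least(cumsum(forcing_gdd(tmean, T_b)), F_star))
}

core_tp <- function(tmean, precip, P_b, T_b, F_star, k1, k2, P_crit) {
  idx_thermal <- first_at_least(cumsum(forcing_gdd(tmean, T_b)), F_star)
  idx_hydro <- first_at_least(k1 * P_b + k2 * cumsum(precip), P_crit)
  idx <- if (is.na(idx_thermal) || is.na(idx_hydro)) NA_integer_ else
    max(idx_thermal, idx_hydro)
  list(idx = idx, idx_thermal = idx_thermal, idx_hydro = idx_hydro)
}

core_sm <- function(tmean, T_b, C_star, F_star, T_o, T_low, T_high,
                    va, vb, vc) {
  S_c <- cumsum(chilling_triangular(tmean, T_low, T_o, T_high))
  t1 <- first_at_least(S_c, C_star)
  if (is.na(t1)) return(list(idx = NA_integer_, t1 = NA_integer_))
  rate <- forcing_sigmoid(tmean, va, vb, vc)
  rate[tmean <= T_b] <- 0
  k <- first_at_least(cumsum(rate[t1:length(tmean)]), F_star)
  list(idx = if (is.na(k)) NA_integer_ else t1 - 1L + k, t1 = t1)
}

core_pm <- function(tmean, C_star, F_star, K_m, T_o, T_low, T_high,
                    va, vb, vc) {
  S_c <- cumsum(chilling_triangular(tmean, T_low, T_o, T_high))
  competence <- if (C_star <= 0) 1 else K_m + (1 - K_m) * pmin(S_c / C_star, 1)
  S_f <- cumsum(competence * forcing_sigmoid(tmean, va, vb, vc))
  list(idx = first_at_least(S_f, F_star),
       t1 = first_at_least(S_c, C_star))
}

core_am <- function(tmean, T_b, C_star, a, b) {
  S_c <- cumsum(tmean < T_b)
  S_f <- cumsum(forcing_gdd(tmean, T_b))
  ok <- S_c >= C_star & S_f >= a * exp(b * S_c)
  idx <- which(ok)
  list(idx = if (length(idx)) idx[1L] else NA_integer_)
}

core_gsi <- function(tmin, vpd, photo, p) {
  ramp <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))
  igsi <- ramp(tmin, p$tmin_lo, p$tmin_hi) *
    (1 - ramp(vpd, p$vpd_lo, p$vpd_hi)) *
    ramp(photo, p$photo_lo, p$photo_hi)
  n <- length(igsi)
  w <- min(p$window, n)
  cg <- cumsum(igsi)
  gsi <- cg / seq_len(n)
  if (n > w) {
    t_long <- (w + 1L):n
    gsi[t_long] <- (cg[t_long] - cg[t_long - w]) / w
  }
  list(idx = first_at_least(gsi, p$threshold), gsi = gsi)
}

# ---- prediction wrappers ---------------------------------------------------

new_prediction <- function(model, year, offset, idx, extra = list()) {
  doy <- if (is.na(idx)) NA_integer_ else offset + idx - 1L
  date <- if (is.na(idx)) as.Date(NA) else jan1(year) + (doy - 1L)
  structure(c(list(model = model, year = year, leafing_doy = doy,
                   leafing_date = date), extra),
            class = "leafing_prediction")
}

#' @export
print.leafing_prediction <- function(x, ...) {
  cat(sprintf("<%s prediction %d> %s\n", x$model, x$year,
              if (is.na(x$leafing_doy)) "threshold not reached"
              else sprintf("leafing DOY %d (%s)", x$leafing_doy,
                           x$leafing_date)))
  invisible(x)
}

# Extract tmean/precip/... row ranges for one model window.
model_window <- function(series, t0_date, year) {
  check_coverage(series, t0_date, dec31(year))
  rows <- series_row(series, t0_date):series_row(series, dec31(year))
  series$data[rows, , drop = FALSE]
}

#' Predict leafing with the spring warming (SW) model
#'
#' Degree-days `max(0, tmean - T_b)` accumulate from `t0` (default Jan 1);
#' leafing is the first day the sum reaches `F_star`.
#'
#' @param series a [station_series()] covering `t0` through Dec 31 of `year`.
#' @param params [sw_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction` with fields `leafing_doy` (day relative to
#'   Jan 1 of `year`, NA if the threshold is never met), `leafing_date`, and
#'   `reached_thermal`.
#' @export
predict_sw <- function(series, params, year) {
  stopifnot(inherits(params, "sw_params"))
  t0 <- resolve_start_date(params$t0, year)
  w <- model_window(series, t0, year)
  res <- core_sw(w$tmean, params$T_b, params$F_star)
  new_prediction("SW", year, start_offset(params$t0, year), res$idx,
                 list(reached_thermal = !is.na(res$idx)))
}

#' Predict leafing with the temperature-precipitation (TP) model
#'
#' Leafing is the first day on which both conditions hold:
#' `k1 * P_b + k2 * sum(R_i from t0) >= P_crit` (water) and
#' `sum(max(0, T_i - T_b) from t0) >= F_star` (heat), where `P_b` is the
#' previous calendar year's total precipitation. Equivalently the later of
#' the first day each condition is met.
#'
#' @param series a [station_series()] covering Jan 1 of `year - 1` (for
#'   `P_b`) through Dec 31 of `year`.
#' @param params [tp_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction` with `reached_thermal`/`reached_hydro`
#'   flags and the first day each condition held (`doy_thermal`,
#'   `doy_hydro`, relative to Jan 1).
#' @export
predict_tp <- function(series, params, year) {
  stopifnot(inherits(params, "tp_params"))
  P_b <- annual_precip(series, year - 1L)
  t0 <- resolve_start_date(params$t0, year)
  w <- model_window(series, t0, year)
  res <- core_tp(w$tmean, w$precip, P_b, params$T_b, params$F_star,
                 params$k1, params$k2, params$P_crit)
  o <- start_offset(params$t0, year)
  new_prediction("TP", year, o, res$idx, list(
    reached_thermal = !is.na(res$idx_thermal),
    reached_hydro = !is.na(res$idx_hydro),
    doy_thermal = if (is.na(res$idx_thermal)) NA_integer_ else o + res$idx_thermal - 1L,
    doy_hydro = if (is.na(res$idx_hydro)) NA_integer_ else o + res$idx_hydro - 1L,
    P_b = P_b))
}

#' Predict leafing with the sequential (SM) model
#'
#' Chilling accumulates from `t0` (default Sep 1 of the previous year) at
#' the triangular rate; the chilling requirement `C_star` defines the
#' rest-to-quiescence date `t1`, from which sigmoid forcing (zero on days
#' with `tmean <= T_b`) accumulates until `F_star`.
#'
#' @param series a [station_series()] covering `t0` through Dec 31 of `year`.
#' @param params [sm_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction`; `t1_date` reports when chilling was
#'   satisfied (NA if never).
#' @export
predict_sm <- function(series, params, year) {
  stopifnot(inherits(params, "sm_params"))
  t0 <- resolve_start_date(params$t0, year)
  w <- model_window(series, t0, year)
  res <- core_sm(w$tmean, params$T_b, params$C_star, params$F_star,
                 params$T_o, params$T_low, params$T_high,
                 params$va, params$vb, params$vc)
  new_prediction("SM", year, start_offset(params$t0, year), res$idx, list(
    reached_thermal = !is.na(res$idx),
    t1_date = if (is.na(res$t1)) as.Date(NA) else t0 + (res$t1 - 1L)))
}

#' Predict leafing with the parallel (PM) model
#'
#' Chilling and forcing accumulate simultaneously from `t0`; each day's
#' sigmoid forcing is scaled by the competence
#' `K_m + (1 - K_m) * min(S_c / C_star, 1)` computed from the chilling state
#' including the current day.
#'
#' @param series a [station_series()] covering `t0` through Dec 31 of `year`.
#' @param params [pm_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction`.
#' @export
predict_pm <- function(series, params, year) {
  stopifnot(inherits(params, "pm_params"))
  t0 <- resolve_start_date(params$t0, year)
  w <- model_window(series, t0, year)
  res <- core_pm(w$tmean, params$C_star, params$F_star, params$K_m,
                 params$T_o, params$T_low, params$T_high,
                 params$va, params$vb, params$vc)
  new_prediction("PM", year, start_offset(params$t0, year), res$idx,
                 list(reached_thermal = !is.na(res$idx)))
}

#' Predict leafing with the alternating (AM) model
#'
#' Chill days (`tmean < T_b`, one chill unit each) and degree-days accumulate
#' from `t0`; leafing is the first day with `S_c >= C_star` and
#' `S_f >= a * exp(b * S_c)`.
#'
#' @param series a [station_series()] covering `t0` through Dec 31 of `year`.
#' @param params [am_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction`.
#' @export
predict_am <- function(series, params, year) {
  stopifnot(inherits(params, "am_params"))
  t0 <- resolve_start_date(params$t0, year)
  w <- model_window(series, t0, year)
  res <- core_am(w$tmean, params$T_b, params$C_star, params$a, params$b)
  new_prediction("AM", year, start_offset(params$t0, year), res$idx,
                 list(reached_thermal = !is.na(res$idx)))
}

#' Predict leafing with the growing season index (GSI)
#'
#' Daily indicator products (minimum-temperature ramp x VPD ramp x
#' photoperiod ramp) are averaged over a trailing window starting Jan 1 of
#' the leafing year (shortened while fewer than `window` days have elapsed);
#' leafing is the first day the running mean reaches `threshold`. Requires
#' relative humidity on every day of the year and a station latitude.
#'
#' @param series a [station_series()] with known latitude covering the full
#'   leafing year; `rh` must be present on every day of it.
#' @param params [gsi_params()].
#' @param year the leafing year to predict.
#' @return a `leafing_prediction`.
#' @export
predict_gsi <- function(series, params, year) {
  stopifnot(inherits(params, "gsi_params"))
  w <- model_window(series, jan1(year), year)
  if (any(is.na(w$rh))) {
    ptp_stop("phenoTP_data_error",
             "GSI requires relative humidity on every day of %d; missing at %s",
             year, w$date[which(is.na(w$rh))[1]])
  }
  vpd <- compute_vpd(w$tmean, w$rh)
  photo <- compute_photoperiod(series$latitude, doy_of(w$date))
  res <- core_gsi(w$tmin, vpd, photo, params)
  new_prediction("GSI", year, 1L, res$idx,
                 list(reached_thermal = !is.na(res$idx)))
}

predictor_for <- function(model) {
  switch(model,
    SW = predict_sw, TP = predict_tp, SM = predict_sm,
    PM = predict_pm, AM = predict_am, GSI = predict_gsi,
    ptp_stop("phenoTP_input_error", "unknown model '%s'", model))
}

#' Predict leafing for any model by name
#'
#' Thin dispatcher over the per-model `predict_*` functions.
#'
#' @param series a [station_series()].
#' @param params a `model_params` object (its `model` field selects the
#'   predictor).
#' @param year the leafing year.
#' @return a `leafing_prediction`.
#' @export
predict_leafing <- function(series, params, year) {
  stopifnot(inherits(params, "model_params"))
  predictor_for(params$model)(series, params, year)
}
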