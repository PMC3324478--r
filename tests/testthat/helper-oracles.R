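# Independent day-by-day oracles: plain state-machine loops over calendar
# days, written without the package's vectorized accumulator cores, used to
# verify every predictor on random weather.

oracle_jan1 <- function(year) as.Date(sprintf("%d-01-01", year))

oracle_rel_doy <- function(date, year) {
  as.integer(date - oracle_jan1(year)) + 1L
}

oracle_days <- function(series, from, year) {
  dates <- seq(as.Date(from), as.Date(sprintf("%d-12-31", year)), by = "day")
  idx <- match(dates, series$data$date)
  stopifnot(!anyNA(idx))
  list(dates = dates, d = series$data[idx, , drop = FALSE])
}

oracle_sw <- function(series, params, year) {
  w <- oracle_days(series, resolve_start_date(params$t0, year), year)
  S_f <- 0
  for (i in seq_along(w$dates)) {
    S_f <- S_f + max(0, w$d$tmean[i] - params$T_b)
    if (S_f >= params$F_star) return(oracle_rel_doy(w$dates[i], year))
  }
  NA_integer_
}

oracle_tp <- function(series, params, year) {
  prev <- oracle_days(series, oracle_jan1(year - 1L), year - 1L)
  P_b <- 0
  for (i in seq_along(prev$dates)) P_b <- P_b + prev$d$precip[i]
  w <- oracle_days(series, resolve_start_date(params$t0, year), year)
  S_f <- 0
  W <- params$k1 * P_b
  for (i in seq_along(w$dates)) {
    S_f <- S_f + max(0, w$d$tmean[i] - params$T_b)
    W <- W + params$k2 * w$d$precip[i]
    if (S_f >= params$F_star && W >= params$P_crit) {
      return(oracle_rel_doy(w$dates[i], year))
    }
  }
  NA_integer_
}

oracle_triangle <- function(t, T_low, T_o, T_high) {
  if (t <= T_low || t >= T_high) return(0)
  if (t <= T_o) (t - T_low) / (T_o - T_low) else (T_high - t) / (T_high - T_o)
}

oracle_sigmoid <- function(t, va, vb, vc) va / (1 + exp(vb * (t + vc)))

oracle_sm <- function(series, params, year) {
  w <- oracle_days(series, resolve_start_date(params$t0, year), year)
  S_c <- 0; S_f <- 0; chilled <- FALSE
  for (i in seq_along(w$dates)) {
    t <- w$d$tmean[i]
    S_c <- S_c + oracle_triangle(t, params$T_low, params$T_o, params$T_high)
    if (!chilled && S_c >= params$C_star) chilled <- TRUE
    if (chilled) {
      if (t > params$T_b) {
        S_f <- S_f + oracle_sigmoid(t, params$va, params$vb, params$vc)
      }
      if (S_f >= params$F_star) return(oracle_rel_doy(w$dates[i], year))
    }
  }
  NA_integer_
}

oracle_pm <- function(series, params, year) {
  w <- oracle_days(series, resolve_start_date(params$t0, year), year)
  S_c <- 0; S_f <- 0
  for (i in seq_along(w$dates)) {
    t <- w$d$tmean[i]
    S_c <- S_c + oracle_triangle(t, params$T_low, params$T_o, params$T_high)
    comp <- if (params$C_star <= 0) 1 else
      params$K_m + (1 - params$K_m) * min(S_c / params$C_star, 1)
    S_f <- S_f + comp * oracle_sigmoid(t, params$va, params$vb, params$vc)
    if (S_f >= params$F_star) return(oracle_rel_doy(w$dates[i], year))
  }
  NA_integer_
}

oracle_am <- function(series, params, year) {
  w <- oracle_days(series, resolve_start_date(params$t0, year), year)
  S_c <- 0; S_f <- 0
  for (i in seq_along(w$dates)) {
    t <- w$d$tmean[i]
    if (t < params$T_b) S_c <- S_c + 1
    S_f <- S_f + max(0, t - params$T_b)
    if (S_c >= params$C_star && S_f >= params$a * exp(params$b * S_c)) {
      return(oracle_rel_doy(w$dates[i], year))
    }
  }
  NA_integer_
}

oracle_gsi <- function(series, params, year) {
  w <- oracle_days(series, oracle_jan1(year), year)
  ramp <- function(x, lo, hi) min(1, max(0, (x - lo) / (hi - lo)))
  ig <- numeric(0)
  for (i in seq_along(w$dates)) {
    vpd_i <- compute_vpd(w$d$tmean[i], w$d$rh[i])
    photo_i <- compute_photoperiod(series$latitude,
                                   oracle_rel_doy(w$dates[i], year))
    ig <- c(ig, ramp(w$d$tmin[i], params$tmin_lo, params$tmin_hi) *
              (1 - ramp(vpd_i, params$vpd_lo, params$vpd_hi)) *
              ramp(photo_i, params$photo_lo, params$photo_hi))
    wl <- min(params$window, i)
    if (mean(ig[(i - wl + 1):i]) >= params$threshold) return(i)
  }
  NA_integer_
}

# NOAA-style solar day length (Spencer declination) as an independent
# photoperiod oracle.
oracle_photoperiod <- function(latitude, doy) {
  g <- 2 * pi / 365 * (doy - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  x <- min(1, max(-1, -tan(latitude * pi / 180) * tan(decl)))
  86400 * acos(x) / pi
}

# ---- fixtures --------------------------------------------------------------

# Constant-input series; tmean/precip may be full-length vectors for
# day-by-day control.
const_series <- function(years, tmean, precip = 0, rh = 60, latitude = 44) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])),
               by = "day")
  n <- length(dates)
  tm <- rep_len(tmean, n)
  station_series("const", latitude, 120, 100,
                 data.frame(date = dates, tmean = tm, tmin = tm - 5,
                            precip = rep_len(precip, n),
                            rh = rep_len(rh, n)))
}

# Shared pool of short random series (two calendar years each; the second is
# the prediction year). Mixed start years include leap years.
series_pool <- local({
  pool <- NULL
  function(n = 25) {
    if (is.null(pool) || length(pool) < n) {
      pool <<- lapply(seq_len(n), function(i) {
        generate_weather(climate_config(), 1999 + (i %% 4), 2, seed = 5000 + i)
      })
    }
    pool[seq_len(n)]
  }
})

pool_year <- function(series) {
  as.POSIXlt(series$data$date[nrow(series$data)])$year + 1900L
}

rand_sw_params <- function() {
  sw_params(T_b = runif(1, 0, 10), F_star = runif(1, 10, 400))
}
rand_tp_params <- function() {
  tp_params(T_b = runif(1, 0, 10), F_star = runif(1, 10, 400),
            k1 = runif(1, 0, 0.3), k2 = runif(1, 0, 1),
            P_crit = runif(1, 0, 80))
}
rand_sm_params <- function() {
  sm_params(T_b = runif(1, 0, 8), C_star = runif(1, 0, 40),
            F_star = runif(1, 5, 300), T_o = runif(1, 0, 9))
}
rand_pm_params <- function() {
  pm_params(C_star = runif(1, 0, 60), F_star = runif(1, 50, 600),
            K_m = runif(1, 0, 1), T_o = runif(1, 0, 9))
}
rand_am_params <- function() {
  am_params(T_b = runif(1, 0, 10), C_star = runif(1, 0, 80),
            a = runif(1, 20, 500), b = runif(1, -0.15, 0.1))
}
rand_gsi_params <- function() {
  gsi_params(window = sample(5:30, 1), threshold = runif(1, 0.1, 0.9))
}
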