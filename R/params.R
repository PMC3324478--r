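# Parameter objects for the six leafing models, plus JSON (de)serialization.

#' Starting-date specification for accumulation models
#'
#' Accumulation models begin summing on a starting date `t0` that is either
#' fixed to a calendar month-day (Jan 1 of the leafing year for SW and TP,
#' Sep 1 of the preceding year for SM/PM/AM) or searched as a free parameter.
#' A parameterized start is an integer day offset relative to Jan 1 of the
#' leafing year: offset 1 is Jan 1, offset 0 is Dec 31 of the previous year,
#' offset -121 is Sep 1 of the previous (non-leap) year.
#'
#' @param mode `"fixed"` or `"parameterized"`.
#' @param month_day `"MM-DD"` string (fixed mode).
#' @param year_offset 0 for the leafing year, -1 for the previous year
#'   (fixed mode).
#' @param offset integer day offset relative to Jan 1 of the leafing year
#'   (parameterized mode).
#' @return an object of class `start_date_spec`.
#' @export
start_date_spec <- function(mode = c("fixed", "parameterized"),
                            month_day = "01-01", year_offset = 0L,
                            offset = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (!grepl("^[0-9]{2}-[0-9]{2}$", month_day)) {
      ptp_stop("phenoTP_input_error", "month_day must be 'MM-DD', got '%s'",
               month_day)
    }
    if (!year_offset %in% c(0L, -1L)) {
      ptp_stop("phenoTP_input_error", "year_offset must be 0 or -1")
    }
    spec <- list(mode = "fixed", month_day = month_day,
                 year_offset = as.integer(year_offset))
  } else {
    if (is.null(offset) || is.na(offset)) {
      ptp_stop("phenoTP_input_error",
               "parameterized start dates require an integer day offset")
    }
    spec <- list(mode = "parameterized", offset = as.integer(round(offset)))
  }
  structure(spec, class = "start_date_spec")
}

#' Resolve a start-date specification to a calendar date
#'
#' @param spec a [start_date_spec()].
#' @param year the leafing year.
#' @return a `Date`.
#' @export
resolve_start_date <- function(spec, year) {
  stopifnot(inherits(spec, "start_date_spec"))
  if (spec$mode == "fixed") {
    as.Date(sprintf("%d-%s", year + spec$year_offset, spec$month_day))
  } else {
    jan1(year) + (spec$offset - 1L)
  }
}

# Day offset of t0 relative to Jan 1 of `year` (1 = Jan 1). Pure integer
# arithmetic: this sits inside the annealing inner loop.
.cumdays <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)

start_offset <- function(spec, year) {
  if (spec$mode == "parameterized") return(spec$offset)
  y <- year + spec$year_offset
  mon <- as.integer(substr(spec$month_day, 1L, 2L))
  day <- as.integer(substr(spec$month_day, 4L, 5L))
  doy <- .cumdays[mon] + day + (mon > 2L && is_leap_year(y))
  if (spec$year_offset == 0L) doy else doy - days_in_year(y)
}

default_start <- function(model) {
  switch(model,
    SW = , TP = start_date_spec("fixed", "01-01", 0L),
    SM = , PM = , AM = start_date_spec("fixed", "09-01", -1L),
    GSI = start_date_spec("fixed", "01-01", 0L),
    ptp_stop("phenoTP_input_error", "unknown model '%s'", model))
}

new_params <- function(model, fields) {
  structure(c(list(model = model), fields),
            class = c(paste0(tolower(model), "_params"), "model_params"))
}

check_t0 <- function(t0) {
  if (!inherits(t0, "start_date_spec")) {
    ptp_stop("phenoTP_input_error", "t0 must be a start_date_spec")
  }
  t0
}

#' Spring warming (SW) model parameters
#'
#' Leafing occurs on the first day the degree-day sum
#' `sum(max(0, tmean - T_b))` from `t0` reaches `F_star`.
#'
#' @param t0 starting date ([start_date_spec()]); default Jan 1 of the
#'   leafing year.
#' @param T_b base temperature, degrees C.
#' @param F_star critical degree-day sum, degree C day (>= 0).
#' @return `sw_params` object.
#' @export
sw_params <- function(T_b, F_star, t0 = default_start("SW")) {
  check_t0(t0)
  if (F_star < 0) ptp_stop("phenoTP_input_error", "F_star must be >= 0")
  new_params("SW", list(t0 = t0, T_b = T_b, F_star = F_star))
}

#' Temperature-precipitation (TP) model parameters
#'
#' Leafing requires both thresholds by the same day: a water condition
#' `k1 * P_b + k2 * sum(R_i) >= P_crit` (with `P_b` the previous calendar
#' year's precipitation total and `R_i` daily precipitation accumulated from
#' `t0`) and the SW thermal condition `sum(max(0, T_i - T_b)) >= F_star`.
#'
#' @inheritParams sw_params
#' @param k1 efficiency of previous-year precipitation (>= 0, dimensionless).
#' @param k2 efficiency of current-year precipitation (>= 0, dimensionless).
#' @param P_crit water threshold, mm (>= 0).
#' @return `tp_params` object.
#' @export
tp_params <- function(T_b, F_star, k1, k2, P_crit, t0 = default_start("TP")) {
  check_t0(t0)
  if (F_star < 0 || k1 < 0 || k2 < 0 || P_crit < 0) {
    ptp_stop("phenoTP_input_error",
             "F_star, k1, k2 and P_crit must all be >= 0")
  }
  new_params("TP", list(t0 = t0, T_b = T_b, F_star = F_star,
                        k1 = k1, k2 = k2, P_crit = P_crit))
}

check_chill_shape <- function(T_low, T_o, T_high) {
  if (!(T_low < T_o && T_o < T_high)) {
    ptp_stop("phenoTP_input_error",
             "chilling temperatures must satisfy T_low < T_o < T_high")
  }
}

#' Sequential (SM) model parameters
#'
#' Chilling accumulates from `t0` at the triangular rate peaking at `T_o`;
#' once the chilling state reaches `C_star` (date `t1`), forcing accumulates
#' at the sigmoid rate `va / (1 + exp(vb (tmean + vc)))`, gated to zero on
#' days with `tmean <= T_b`; leafing occurs when forcing reaches `F_star`.
#' Defaults for `T_low`, `T_high`, `va`, `vb`, `vc` are the fixed literature
#' constants (-3.4, 10.4, 28.4, -0.185, -18.4).
#'
#' @inheritParams sw_params
#' @param C_star chilling requirement, chill units (>= 0).
#' @param F_star forcing requirement, forcing units (>= 0).
#' @param T_o optimal chilling temperature, degrees C.
#' @param T_low,T_high zero points of the triangular chilling response.
#' @param va,vb,vc sigmoid forcing constants (`va > 0`).
#' @return `sm_params` object.
#' @export
sm_params <- function(T_b, C_star, F_star, T_o,
                      T_low = -3.4, T_high = 10.4,
                      va = 28.4, vb = -0.185, vc = -18.4,
                      t0 = default_start("SM")) {
  check_t0(t0)
  check_chill_shape(T_low, T_o, T_high)
  if (C_star < 0 || F_star < 0 || va <= 0) {
    ptp_stop("phenoTP_input_error", "require C_star >= 0, F_star >= 0, va > 0")
  }
  new_params("SM", list(t0 = t0, T_b = T_b, C_star = C_star, F_star = F_star,
                        T_o = T_o, T_low = T_low, T_high = T_high,
                        va = va, vb = vb, vc = vc))
}

#' Parallel (PM) model parameters
#'
#' Chilling and forcing accumulate simultaneously from `t0`; the daily
#' forcing contribution is scaled by the bud competence
#' `K_m + (1 - K_m) * min(S_c / C_star, 1)` (1 when `C_star = 0`).
#'
#' @inheritParams sm_params
#' @param K_m minimum competence of unchilled buds, in \[0, 1\].
#' @return `pm_params` object.
#' @export
pm_params <- function(C_star, F_star, K_m, T_o,
                      T_low = -3.4, T_high = 10.4,
                      va = 28.4, vb = -0.185, vc = -18.4,
                      t0 = default_start("PM")) {
  check_t0(t0)
  check_chill_shape(T_low, T_o, T_high)
  if (K_m < 0 || K_m > 1) ptp_stop("phenoTP_input_error", "K_m must be in [0, 1]")
  if (C_star < 0 || F_star < 0 || va <= 0) {
    ptp_stop("phenoTP_input_error", "require C_star >= 0, F_star >= 0, va > 0")
  }
  new_params("PM", list(t0 = t0, C_star = C_star, F_star = F_star, K_m = K_m,
                        T_o = T_o, T_low = T_low, T_high = T_high,
                        va = va, vb = vb, vc = vc))
}

#' Alternating (AM) model parameters
#'
#' Chill days (`tmean < T_b`) and degree-days accumulate in parallel from
#' `t0`; leafing occurs on the first day with at least `C_star` chill days
#' and a degree-day sum reaching the moving requirement `a * exp(b * S_c)`.
#'
#' @inheritParams sw_params
#' @param C_star chill-day requirement, chill units (>= 0).
#' @param a forcing-requirement scale, degree C day (> 0).
#' @param b forcing-requirement rate per chill unit.
#' @return `am_params` object.
#' @export
am_params <- function(T_b, C_star, a, b, t0 = default_start("AM")) {
  check_t0(t0)
  if (a <= 0 || C_star < 0) {
    ptp_stop("phenoTP_input_error", "require a > 0 and C_star >= 0")
  }
  new_params("AM", list(t0 = t0, T_b = T_b, C_star = C_star, a = a, b = b))
}

#' Growing season index (GSI) parameters
#'
#' Each day is scored by the product of three indicators in \[0, 1\]: an
#' increasing ramp in minimum temperature between `tmin_lo` and `tmin_hi`, a
#' decreasing ramp in vapor pressure deficit between `vpd_lo` and `vpd_hi`,
#' and an increasing ramp in photoperiod between `photo_lo` and `photo_hi`.
#' The GSI is the trailing mean of this product over `window` days
#' (shortened near Jan 1); leafing is the first day GSI reaches `threshold`.
#' Defaults are the source-literature values (tmin -2/5 degrees C, VPD
#' 900/4100 Pa, photoperiod 36000/39600 s, 21-day window, threshold 0.5).
#'
#' @param tmin_lo,tmin_hi minimum-temperature ramp bounds, degrees C.
#' @param vpd_lo,vpd_hi vapor-pressure-deficit ramp bounds, Pa.
#' @param photo_lo,photo_hi photoperiod ramp bounds, seconds.
#' @param window trailing-mean length, days (>= 1).
#' @param threshold leafing threshold in (0, 1].
#' @return `gsi_params` object.
#' @export
gsi_params <- function(tmin_lo = -2, tmin_hi = 5,
                       vpd_lo = 900, vpd_hi = 4100,
                       photo_lo = 36000, photo_hi = 39600,
                       window = 21L, threshold = 0.5) {
  if (!(tmin_lo < tmin_hi && vpd_lo < vpd_hi && photo_lo < photo_hi)) {
    ptp_stop("phenoTP_input_error", "each ramp requires lo < hi")
  }
  if (window < 1) ptp_stop("phenoTP_input_error", "window must be >= 1 day")
  if (threshold <= 0 || threshold > 1) {
    ptp_stop("phenoTP_input_error", "threshold must be in (0, 1]")
  }
  new_params("GSI", list(tmin_lo = tmin_lo, tmin_hi = tmin_hi,
                         vpd_lo = vpd_lo, vpd_hi = vpd_hi,
                         photo_lo = photo_lo, photo_hi = photo_hi,
                         window = as.integer(window), threshold = threshold))
}

#' @export
print.model_params <- function(x, ...) {
  vals <- x[setdiff(names(x), c("model", "t0"))]
  cat(sprintf("<%s params> %s\n", x$model,
              paste(names(vals), signif(unlist(vals), 5),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$t0)) {
    if (x$t0$mode == "fixed") {
      cat(sprintf("  t0: fixed %s (year offset %d)\n",
                  x$t0$month_day, x$t0$year_offset))
    } else {
      cat(sprintf("  t0: parameterized, day offset %d from Jan 1\n",
                  x$t0$offset))
    }
  }
  invisible(x)
}

#' Serialize model parameters to JSON
#'
#' @param params a `model_params` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_params"))
  x <- unclass(params)
  if (!is.null(x$t0)) x$t0 <- unclass(x$t0)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize model parameters from JSON
#'
#' @param json JSON string, or a file path when `file = TRUE`.
#' @param file whether `json` names a file.
#' @return a `model_params` object.
#' @export
params_from_json <- function(json, file = FALSE) {
  x <- jsonlite::fromJSON(if (file) paste(readLines(json), collapse = "\n") else json)
  params_from_list(x)
}

#' Build model parameters from a plain named list
#'
#' Accepts the same structure as the JSON serialization (a `model` field
#' plus the per-model parameters, with an optional `t0` sub-list), e.g. as
#' read from a YAML configuration.
#'
#' @param x named list.
#' @return a `model_params` object.
#' @export
params_from_list <- function(x) {
  if (is.null(x$model)) {
    ptp_stop("phenoTP_parse_error", "parameter list lacks a 'model' field")
  }
  t0 <- if (is.null(x$t0)) {
    if (identical(x$model, "GSI")) NULL else default_start(x$model)
  } else if (identical(x$t0$mode, "fixed")) {
    start_date_spec("fixed", x$t0$month_day, x$t0$year_offset)
  } else {
    start_date_spec("parameterized", offset = x$t0$offset)
  }
  switch(x$model,
    SW = sw_params(x$T_b, x$F_star, t0 = t0),
    TP = tp_params(x$T_b, x$F_star, x$k1, x$k2, x$P_crit, t0 = t0),
    SM = sm_params(x$T_b, x$C_star, x$F_star, x$T_o, x$T_low, x$T_high,
                   x$va, x$vb, x$vc, t0 = t0),
    PM = pm_params(x$C_star, x$F_star, x$K_m, x$T_o, x$T_low, x$T_high,
                   x$va, x$vb, x$vc, t0 = t0),
    AM = am_params(x$T_b, x$C_star, x$a, x$b, t0 = t0),
    GSI = gsi_params(x$tmin_lo, x$tmin_hi, x$vpd_lo, x$vpd_hi,
                     x$photo_lo, x$photo_hi, x$window, x$threshold),
    ptp_stop("phenoTP_parse_error", "unknown model '%s'", x$model))
}
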