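# Least-RMSE calibration: box-bounded simulated annealing, an exhaustive
# grid search for small problems, and the odd/even-year validation protocol.

#' Construct a parameter search space
#'
#' A parameter space is a data.frame with one row per model parameter:
#' `name`, `lower`, `upper`, and `fixed` (a value inside the bounds removes
#' the parameter from the search; `NA` leaves it free). When the starting
#' date is searched, it appears as the integer day offset `t0_offset`
#' relative to Jan 1 of the leafing year.
#'
#' @param name character vector of parameter names.
#' @param lower,upper numeric bound vectors (`lower < upper` for every free
#'   parameter).
#' @param fixed numeric vector of fixed values (`NA` = free), inside the
#'   bounds.
#' @return a `parameter_space` data.frame.
#' @export
parameter_space <- function(name, lower, upper, fixed = NA_real_) {
  sp <- data.frame(name = as.character(name), lower = as.numeric(lower),
                   upper = as.numeric(upper), fixed = as.numeric(fixed),
                   stringsAsFactors = FALSE)
  check_space(sp)
  class(sp) <- c("parameter_space", "data.frame")
  sp
}

check_space <- function(sp) {
  if (anyDuplicated(sp$name)) {
    ptp_stop("phenoTP_input_error", "duplicate parameter names in space")
  }
  free <- is.na(sp$fixed)
  if (any(sp$lower[free] >= sp$upper[free])) {
    ptp_stop("phenoTP_input_error",
             "lower must be < upper for every free parameter ('%s')",
             sp$name[free][which(sp$lower[free] >= sp$upper[free])[1]])
  }
  fx <- !free
  if (any(sp$fixed[fx] < sp$lower[fx] | sp$fixed[fx] > sp$upper[fx])) {
    ptp_stop("phenoTP_input_error", "fixed value outside bounds ('%s')",
             sp$name[fx][which(sp$fixed[fx] < sp$lower[fx] |
                               sp$fixed[fx] > sp$upper[fx])[1]])
  }
  invisible(sp)
}

#' Default search space for a model
#'
#' Bounds cover the parameter ranges reported for these models in temperate
#' East Asian calibrations: `T_b` 0-15 degrees C, `F_star` 0-1000 degree C
#' day, `k1`/`k2` 0-1, `P_crit` 0-60 mm, `C_star` 0-100 CU, `K_m` 0-1,
#' `T_o` inside the fixed chilling triangle, `a` 1-1000, `b` -0.2-0.2. With
#' `start = "parameterized"` the day offset `t0_offset` is searched between
#' Sep 1 of the previous year (-121) and Jun 30 (181). For SM and PM the
#' literature constants `T_low`, `T_high`, `va`, `vb`, `vc` are fixed; for
#' GSI only the leafing threshold is free by default (set `fixed` to `NA`
#' on other rows to search them).
#'
#' @param model one of `"SW"`, `"TP"`, `"SM"`, `"PM"`, `"AM"`, `"GSI"`.
#' @param start `"fixed"` (calendar default start) or `"parameterized"`.
#' @return a [parameter_space()].
#' @export
default_parameter_space <- function(model, start = c("fixed", "parameterized")) {
  start <- match.arg(start)
  sp <- switch(model,
    SW = parameter_space(c("T_b", "F_star"), c(0, 0), c(15, 1000)),
    TP = parameter_space(c("T_b", "F_star", "k1", "k2", "P_crit"),
                         c(0, 0, 0, 0, 0), c(15, 1000, 1, 1, 60)),
    AM = parameter_space(c("T_b", "C_star", "a", "b"),
                         c(0, 0, 1, -0.2), c(15, 100, 1000, 0.2)),
    SM = parameter_space(
      c("T_b", "C_star", "F_star", "T_o", "T_low", "T_high", "va", "vb", "vc"),
      c(0, 0, 0, -3.3, -10, 5, 1, -1, -40),
      c(15, 100, 1000, 10.3, 0, 20, 80, 0, 0),
      c(NA, NA, NA, NA, -3.4, 10.4, 28.4, -0.185, -18.4)),
    PM = parameter_space(
      c("C_star", "F_star", "K_m", "T_o", "T_low", "T_high", "va", "vb", "vc"),
      c(0, 0, 0, -3.3, -10, 5, 1, -1, -40),
      c(100, 1000, 1, 10.3, 0, 20, 80, 0, 0),
      c(NA, NA, NA, NA, -3.4, 10.4, 28.4, -0.185, -18.4)),
    GSI = parameter_space(
      c("tmin_lo", "tmin_hi", "vpd_lo", "vpd_hi", "photo_lo", "photo_hi",
        "window", "threshold"),
      c(-10, 0, 100, 2000, 30000, 36000, 1, 0.05),
      c(0, 15, 2000, 7000, 40000, 46000, 40, 1),
      c(-2, 5, 900, 4100, 36000, 39600, 21, NA)),
    ptp_stop("phenoTP_input_error", "unknown model '%s'", model))
  if (start == "parameterized" && model != "GSI") {
    sp <- rbind(sp, data.frame(name = "t0_offset", lower = -121, upper = 181,
                               fixed = NA_real_))
    class(sp) <- c("parameter_space", "data.frame")
  }
  sp
}

# Full named value vector -> model_params object. A t0_offset entry switches
# the start date to parameterized mode; otherwise the model's calendar
# default start is used.
space_to_params <- function(model, v) {
  t0 <- if ("t0_offset" %in% names(v)) {
    start_date_spec("parameterized", offset = round(v[["t0_offset"]]))
  } else {
    default_start(model)
  }
  switch(model,
    SW = sw_params(v[["T_b"]], v[["F_star"]], t0 = t0),
    TP = tp_params(v[["T_b"]], v[["F_star"]], v[["k1"]], v[["k2"]],
                   v[["P_crit"]], t0 = t0),
    SM = sm_params(v[["T_b"]], v[["C_star"]], v[["F_star"]], v[["T_o"]],
                   v[["T_low"]], v[["T_high"]], v[["va"]], v[["vb"]],
                   v[["vc"]], t0 = t0),
    PM = pm_params(v[["C_star"]], v[["F_star"]], v[["K_m"]], v[["T_o"]],
                   v[["T_low"]], v[["T_high"]], v[["va"]], v[["vb"]],
                   v[["vc"]], t0 = t0),
    AM = am_params(v[["T_b"]], v[["C_star"]], v[["a"]], v[["b"]], t0 = t0),
    GSI = gsi_params(v[["tmin_lo"]], v[["tmin_hi"]], v[["vpd_lo"]],
                     v[["vpd_hi"]], v[["photo_lo"]], v[["photo_hi"]],
                     round(v[["window"]]), v[["threshold"]]))
}

#' Simulated-annealing configuration
#'
#' Metropolis annealing over a box-bounded space: uniform coordinate
#' perturbations scaled to a fraction of each bound range, acceptance
#' probability `min(1, exp(-delta / temperature))`, geometric cooling per
#' epoch. When `t_initial` is `NULL` it is calibrated from 50 warm-up
#' proposals so that roughly 80 percent of initial uphill moves accept.
#'
#' @param seed integer random seed (mandatory; fits are reproducible per
#'   seed).
#' @param t_initial initial acceptance temperature, days of RMSE (`NULL` =
#'   auto-calibrate).
#' @param cooling geometric cooling factor per epoch, in (0, 1).
#' @param steps_per_epoch proposals per epoch.
#' @param epochs number of epochs.
#' @param proposal_scale perturbation half-width as a fraction of each bound
#'   range.
#' @param penalty_days absolute error, days, charged for a year in which the
#'   model never reaches its thresholds (>= 365 so any real date is
#'   preferred).
#' @return an `anneal_config` list.
#' @export
anneal_config <- function(seed, t_initial = NULL, cooling = 0.9,
                          steps_per_epoch = 200L, epochs = 50L,
                          proposal_scale = 0.1, penalty_days = 400) {
  if (missing(seed)) ptp_stop("phenoTP_input_error", "a seed is required")
  if (cooling <= 0 || cooling >= 1) {
    ptp_stop("phenoTP_input_error", "cooling factor must be in (0, 1)")
  }
  if (penalty_days < 365) {
    ptp_stop("phenoTP_input_error", "penalty_days must be >= 365")
  }
  if (steps_per_epoch < 1 || epochs < 1 || proposal_scale <= 0) {
    ptp_stop("phenoTP_input_error",
             "steps_per_epoch, epochs and proposal_scale must be positive")
  }
  structure(list(seed = as.integer(seed), t_initial = t_initial,
                 cooling = cooling, steps_per_epoch = as.integer(steps_per_epoch),
                 epochs = as.integer(epochs), proposal_scale = proposal_scale,
                 penalty_days = penalty_days),
            class = "anneal_config")
}

# ---- prediction contexts ---------------------------------------------------
# Precompute per-observation-year weather vectors once so that the annealing
# loop runs on plain numeric slices. `offset_lower(year)` gives the earliest
# start offset (relative to Jan 1) any candidate parameter vector may request.

fit_context <- function(model, series, observations, offset_lower) {
  if (nrow(observations) == 0L) {
    ptp_stop("phenoTP_input_error", "observation set is empty")
  }
  bad <- integer(0)
  ctxs <- vector("list", nrow(observations))
  for (i in seq_len(nrow(observations))) {
    y <- observations$year[i]
    o_min <- if (model == "GSI") 1L else as.integer(floor(offset_lower(y)))
    from <- jan1(y) + (o_min - 1L)
    if (model == "TP") from <- min(from, jan1(y - 1L))
    to <- dec31(y)
    if (from < series_start(series) || to > series_end(series)) {
      bad <- c(bad, y)
      next
    }
    d <- series$data[series_row(series, from):series_row(series, to), ,
                     drop = FALSE]
    cy <- list(year = y, obs = observations$leafing_doy[i],
               jan1_idx = as.integer(jan1(y) - from) + 1L,
               tmean = d$tmean, precip = d$precip)
    if (model == "TP") cy$P_b <- annual_precip(series, y - 1L)
    if (model == "GSI") {
      if (any(is.na(d$rh))) {
        ptp_stop("phenoTP_data_error",
                 "GSI requires relative humidity on every day of %d", y)
      }
      cy$tmin <- d$tmin
      cy$vpd <- compute_vpd(d$tmean, d$rh)
      cy$photo <- compute_photoperiod(series$latitude, doy_of(d$date))
    }
    ctxs[[i]] <- cy
  }
  if (length(bad)) {
    ptp_stop("phenoTP_coverage_error",
             "weather coverage incomplete for observation years: %s",
             paste(sort(unique(bad)), collapse = ", "))
  }
  ctxs
}

ctx_predict <- function(params, cy) {
  model <- params$model
  if (model == "GSI") {
    idx <- core_gsi(cy$tmin, cy$vpd, cy$photo, params)$idx
    return(if (is.na(idx)) NA_real_ else as.numeric(idx))
  }
  o <- start_offset(params$t0, cy$year)
  s <- cy$jan1_idx + o - 1L
  n <- length(cy$tmean)
  if (s < 1L || s > n) {
    ptp_stop("phenoTP_coverage_error",
             "start offset %d is outside the prepared window for %d", o, cy$year)
  }
  tm <- cy$tmean[s:n]
  idx <- switch(model,
    SW = core_sw(tm, params$T_b, params$F_star)$idx,
    TP = core_tp(tm, cy$precip[s:n], cy$P_b, params$T_b, params$F_star,
                 params$k1, params$k2, params$P_crit)$idx,
    SM = core_sm(tm, params$T_b, params$C_star, params$F_star, params$T_o,
                 params$T_low, params$T_high, params$va, params$vb,
                 params$vc)$idx,
    PM = core_pm(tm, params$C_star, params$F_star, params$K_m, params$T_o,
                 params$T_low, params$T_high, params$va, params$vb,
                 params$vc)$idx,
    AM = core_am(tm, params$T_b, params$C_star, params$a, params$b)$idx)
  if (is.na(idx)) NA_real_ else o + idx - 1
}

ctx_offset_lower <- function(model, space) {
  if ("t0_offset" %in% space$name) {
    lo <- space$lower[space$name == "t0_offset"]
    fx <- space$fixed[space$name == "t0_offset"]
    if (!is.na(fx)) lo <- fx
    function(year) lo
  } else {
    function(year) start_offset(default_start(model), year)
  }
}

#' Calibration objective: RMSE of a parameter vector over observed years
#'
#' Predicts every observation year with `params` and returns the RMSE, with
#' years in which the model never reaches its thresholds contributing
#' `penalty_days` of absolute error.
#'
#' @param series a [station_series()] covering every needed window.
#' @param params a `model_params` object.
#' @param observations a [leafing_observations()] data.frame.
#' @param penalty_days error charged for a failed prediction, days.
#' @return RMSE in days.
#' @export
objective <- function(series, params, observations, penalty_days = 400) {
  stopifnot(inherits(params, "model_params"))
  off <- if (params$model == "GSI") function(year) 1L else
    function(year) start_offset(params$t0, year)
  ctxs <- fit_context(params$model, series, observations, off)
  pred <- vapply(ctxs, function(cy) ctx_predict(params, cy), numeric(1))
  obs <- vapply(ctxs, function(cy) as.numeric(cy$obs), numeric(1))
  err <- ifelse(is.na(pred), penalty_days, pred - obs)
  sqrt(mean(err^2))
}

new_fit <- function(model, method, best_x, space, objfun_best, preds, obs,
                    years, penalty_days, trace, seed, n_eval) {
  params <- space_to_params(model, best_x)
  structure(list(
    model = model, method = method, params = params, par = best_x,
    objective = objfun_best,
    calibration = compute_metrics(preds, obs, penalty_days),
    predictions = data.frame(year = years, observed = obs, predicted = preds),
    trace = trace, seed = seed, n_eval = n_eval, space = space),
    class = "pheno_fit")
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf("<%s fit (%s)> calibration RMSE %.3f days on %d years\n",
              x$model, x$method, x$calibration$rmse, x$calibration$n))
  free <- is.na(x$space$fixed)
  cat("  ", paste(names(x$par)[free], signif(x$par[free], 5),
                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate a model by simulated annealing
#'
#' Minimises the least-RMSE objective over the free parameters of `space`
#' with Metropolis simulated annealing (see [anneal_config()]). The best
#' parameter vector ever visited is returned; with every parameter fixed the
#' objective is evaluated once. Reproducible for a fixed seed.
#'
#' @param series a [station_series()].
#' @param observations calibration set (typically the odd years from
#'   [split_odd_even()]).
#' @param model model name; ignored if you pass a custom `space` built for
#'   another model.
#' @param space a [parameter_space()]; defaults to
#'   [default_parameter_space()] for `model`.
#' @param config an [anneal_config()].
#' @return a `pheno_fit` with fitted parameters, calibration metrics, the
#'   per-epoch best-RMSE trace (non-increasing), and the seed.
#' @export
fit_simulated_annealing <- function(series, observations, model = "SW",
                                    space = default_parameter_space(model),
                                    config = anneal_config(seed = 1)) {
  check_space(space)
  stopifnot(inherits(config, "anneal_config"))
  ctxs <- fit_context(model, series, observations,
                      ctx_offset_lower(model, space))
  obs_doy <- vapply(ctxs, function(cy) as.numeric(cy$obs), numeric(1))
  years <- vapply(ctxs, function(cy) as.numeric(cy$year), numeric(1))
  full <- stats::setNames(space$fixed, space$name)
  free <- which(is.na(space$fixed))
  n_eval <- 0L

  predict_all <- function(x) {
    v <- full
    v[free] <- x
    p <- space_to_params(model, v)
    vapply(ctxs, function(cy) ctx_predict(p, cy), numeric(1))
  }
  evalobj <- function(x) {
    n_eval <<- n_eval + 1L
    pred <- predict_all(x)
    err <- ifelse(is.na(pred), config$penalty_days, pred - obs_doy)
    sqrt(mean(err^2))
  }

  if (length(free) == 0L) {
    f0 <- evalobj(numeric(0))
    return(new_fit(model, "fixed", full, space, f0, predict_all(numeric(0)),
                   obs_doy, years, config$penalty_days, f0, config$seed,
                   n_eval))
  }

  lo <- space$lower[free]; hi <- space$upper[free]; rng <- hi - lo
  m <- length(free)
  out <- with_seed(config$seed, {
    x <- lo + runif(m) * rng
    fx <- evalobj(x)
    best_x <- x; best_f <- fx
    temp <- config$t_initial
    if (is.null(temp)) {
      # warm-up: size the temperature so ~80% of uphill moves would accept
      uphill <- numeric(0)
      for (k in seq_len(50L)) {
        xp <- pmin(hi, pmax(lo, x + runif(m, -1, 1) * config$proposal_scale * rng))
        fp <- evalobj(xp)
        if (fp > fx) uphill <- c(uphill, fp - fx)
        if (fp < best_f) { best_f <- fp; best_x <- xp }
      }
      temp <- if (length(uphill)) mean(uphill) / (-log(0.8)) else 1
    }
    trace <- numeric(config$epochs)
    for (e in seq_len(config$epochs)) {
      for (s in seq_len(config$steps_per_epoch)) {
        xp <- pmin(hi, pmax(lo, x + runif(m, -1, 1) * config$proposal_scale * rng))
        fp <- evalobj(xp)
        if (fp <= fx || runif(1) < exp(-(fp - fx) / temp)) {
          x <- xp; fx <- fp
          if (fx < best_f) { best_f <- fx; best_x <- x }
        }
      }
      trace[e] <- best_f
      temp <- temp * config$cooling
    }
    list(best_x = best_x, best_f = best_f, trace = trace)
  })

  v <- full
  v[free] <- out$best_x
  new_fit(model, "simulated_annealing", v, space, out$best_f,
          predict_all(out$best_x), obs_doy, years, config$penalty_days,
          out$trace, config$seed, n_eval)
}

#' Exhaustive grid-search calibration (verification oracle)
#'
#' Evaluates the objective on the full Cartesian grid over the free
#' parameters (at most 3, as a combinatorial guard) and returns the grid
#' optimum. Ties are broken toward smaller parameter values in declaration
#' order.
#'
#' @inheritParams fit_simulated_annealing
#' @param resolution grid points per free parameter.
#' @param penalty_days error charged for failed predictions, days.
#' @return a `pheno_fit`.
#' @export
fit_grid <- function(series, observations, model = "SW",
                     space = default_parameter_space(model),
                     resolution = 11L, penalty_days = 400) {
  check_space(space)
  free <- which(is.na(space$fixed))
  if (length(free) > 3L) {
    ptp_stop("phenoTP_guard_error",
             "grid search supports at most 3 free parameters, got %d",
             length(free))
  }
  ctxs <- fit_context(model, series, observations,
                      ctx_offset_lower(model, space))
  obs_doy <- vapply(ctxs, function(cy) as.numeric(cy$obs), numeric(1))
  years <- vapply(ctxs, function(cy) as.numeric(cy$year), numeric(1))
  full <- stats::setNames(space$fixed, space$name)

  predict_all <- function(x) {
    v <- full
    v[free] <- x
    p <- space_to_params(model, v)
    vapply(ctxs, function(cy) ctx_predict(p, cy), numeric(1))
  }
  evalobj <- function(x) {
    pred <- predict_all(x)
    err <- ifelse(is.na(pred), penalty_days, pred - obs_doy)
    sqrt(mean(err^2))
  }

  if (length(free) == 0L) {
    f0 <- evalobj(numeric(0))
    return(new_fit(model, "grid", full, space, f0, predict_all(numeric(0)),
                   obs_doy, years, penalty_days, f0, NA_integer_, 1L))
  }

  grids <- lapply(free, function(i) {
    seq(space$lower[i], space$upper[i], length.out = resolution)
  })
  # rows in lexicographic order of the parameters in declaration order, so
  # that keeping the first strict minimum breaks ties toward smaller values
  combos <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)
  combos <- as.matrix(combos[, rev(seq_along(grids)), drop = FALSE])
  best_f <- Inf; best_x <- NULL
  for (r in seq_len(nrow(combos))) {
    f <- evalobj(combos[r, ])
    if (f < best_f) { best_f <- f; best_x <- combos[r, ] }
  }
  v <- full
  v[free] <- best_x
  new_fit(model, "grid", v, space, best_f, predict_all(best_x), obs_doy,
          years, penalty_days, best_f, NA_integer_, nrow(combos))
}

#' Validate fitted parameters on an independent observation set
#'
#' Computes RMSE, R-squared and F on the validation years with the same
#' failed-prediction penalty policy as calibration.
#'
#' @param series a [station_series()].
#' @param fit a `pheno_fit` or a `model_params` object.
#' @param observations validation set (typically the even years).
#' @param penalty_days error charged for failed predictions, days.
#' @return list with `rmse`, `r2`, `f_stat`, `n`, `n_predicted` and a
#'   `predictions` data.frame (year, observed, predicted).
#' @export
validate_model <- function(series, fit, observations, penalty_days = 400) {
  params <- if (inherits(fit, "pheno_fit")) fit$params else fit
  stopifnot(inherits(params, "model_params"))
  if (nrow(observations) == 0L) {
    ptp_stop("phenoTP_input_error", "validation set is empty")
  }
  off <- if (params$model == "GSI") function(year) 1L else
    function(year) start_offset(params$t0, year)
  ctxs <- fit_context(params$model, series, observations, off)
  pred <- vapply(ctxs, function(cy) ctx_predict(params, cy), numeric(1))
  obs <- vapply(ctxs, function(cy) as.numeric(cy$obs), numeric(1))
  years <- vapply(ctxs, function(cy) as.numeric(cy$year), numeric(1))
  out <- compute_metrics(pred, obs, penalty_days)
  out$predictions <- data.frame(year = years, observed = obs, predicted = pred)
  out
}

#' Predict leafing days for several years
#'
#' @param series a [station_series()].
#' @param params a `model_params` object.
#' @param years integer vector of leafing years.
#' @return data.frame with `year` and `predicted_doy` (NA where the model
#'   never reaches its thresholds).
#' @export
predict_years <- function(series, params, years) {
  doys <- vapply(years, function(y) {
    p <- predict_leafing(series, params, y)
    if (is.na(p$leafing_doy)) NA_real_ else as.numeric(p$leafing_doy)
  }, numeric(1))
  data.frame(year = as.integer(years), predicted_doy = doys)
}
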