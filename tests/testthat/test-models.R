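# Predictor behaviour: rate functions, reductions, monotonicity, and
# day-by-day oracle agreement on random weather.

test_that("rate functions evaluate their closed forms", {
  expect_equal(forcing_gdd(10, 0), 10)
  expect_equal(forcing_gdd(-5, 0), 0)
  expect_equal(forcing_gdd(7.4, 7.4), 0)

  expect_equal(forcing_sigmoid(18.4, 28.4, -0.185, -18.4), 14.2)
  expect_equal(forcing_sigmoid(100, 28.4, -0.185, -18.4), 28.4,
               tolerance = 1e-6)
  expect_equal(forcing_sigmoid(0, 28.4, -0.185, -18.4),
               28.4 / (1 + exp(-0.185 * (0 - 18.4))))

  expect_equal(chilling_triangular(5, -3.4, 5, 10.4), 1)
  expect_equal(chilling_triangular(-3.4, -3.4, 5, 10.4), 0)
  expect_equal(chilling_triangular(10.4, -3.4, 5, 10.4), 0)
  expect_equal(chilling_triangular((-3.4 + 5) / 2, -3.4, 5, 10.4), 0.5)
})

test_that("degenerate thresholds leaf at the start date", {
  s <- const_series(2001:2002, tmean = 10)
  expect_equal(predict_sw(s, sw_params(0, 0), 2002)$leafing_doy, 1L)
  # SM with no chilling requirement is a pure forcing model from t0
  p <- predict_sm(s, sm_params(T_b = 0, C_star = 0, F_star = 1e9, T_o = 5),
                  2002)
  expect_equal(p$t1_date, as.Date("2001-09-01"))
  expect_true(is.na(p$leafing_doy))
})

test_that("predictors are deterministic and can leaf before Jan 1", {
  s <- series_pool()[[3]]
  y <- pool_year(s)
  p1 <- predict_tp(s, tp_params(3, 100, 0.05, 0.5, 20), y)
  p2 <- predict_tp(s, tp_params(3, 100, 0.05, 0.5, 20), y)
  expect_identical(p1, p2)
  # an autumn-start model with a trivial requirement finishes before Jan 1
  am <- predict_am(s, am_params(T_b = 30, C_star = 1, a = 1, b = 0), y)
  expect_lte(am$leafing_doy, 0L)
  expect_identical(am$leafing_date, as.Date(sprintf("%d-01-01", y)) +
                     (am$leafing_doy - 1L))
})

test_that("each predictor matches its day-by-day oracle on random weather", {
  set.seed(42)
  pool <- series_pool()
  cases_per_model <- 12
  models <- list(
    SW = list(rand = rand_sw_params, oracle = oracle_sw, fun = predict_sw),
    TP = list(rand = rand_tp_params, oracle = oracle_tp, fun = predict_tp),
    SM = list(rand = rand_sm_params, oracle = oracle_sm, fun = predict_sm),
    PM = list(rand = rand_pm_params, oracle = oracle_pm, fun = predict_pm),
    AM = list(rand = rand_am_params, oracle = oracle_am, fun = predict_am),
    GSI = list(rand = rand_gsi_params, oracle = oracle_gsi, fun = predict_gsi))
  for (name in names(models)) {
    m <- models[[name]]
    for (k in seq_len(cases_per_model)) {
      s <- pool[[1 + (k %% length(pool))]]
      y <- pool_year(s)
      params <- m$rand()
      got <- m$fun(s, params, y)$leafing_doy
      want <- m$oracle(s, params, y)
      expect_identical(as.integer(got), as.integer(want),
                       info = sprintf("%s case %d", name, k))
    }
  }
})

test_that("uniform warming never delays purely forcing-driven leafing", {
  # SW and TP are monotone in temperature outright. AM is monotone only
  # when its chilling feedback is off (no chill-day gate and b >= 0):
  # warming slows chill-day accumulation, so a chill gate or a decaying
  # forcing requirement (b < 0) can legitimately delay AM leafing.
  set.seed(7)
  pool <- series_pool()
  warm <- function(s, dT) {
    d <- s$data
    d$tmean <- d$tmean + dT
    d$tmin <- d$tmin + dT
    station_series(s$station_id, s$latitude, s$longitude, s$elevation, d)
  }
  for (k in seq_len(100)) {
    s <- pool[[1 + (k %% length(pool))]]
    y <- pool_year(s)
    dT <- runif(1, 0.1, 4)
    sw <- rand_sw_params(); tp <- rand_tp_params()
    am <- am_params(T_b = runif(1, 0, 10), C_star = 0,
                    a = runif(1, 20, 500), b = runif(1, 0, 0.05))
    s2 <- warm(s, dT)
    for (case in list(list(predict_sw, sw), list(predict_tp, tp),
                      list(predict_am, am))) {
      base <- case[[1]](s, case[[2]], y)$leafing_doy
      warmer <- case[[1]](s2, case[[2]], y)$leafing_doy
      if (!is.na(base)) {
        expect_false(is.na(warmer))
        expect_lte(warmer, base)
      }
    }
  }
})

test_that("added precipitation never delays TP; raising P_crit never advances it", {
  set.seed(8)
  pool <- series_pool()
  for (k in seq_len(50)) {
    s <- pool[[1 + (k %% length(pool))]]
    y <- pool_year(s)
    params <- rand_tp_params()
    base <- predict_tp(s, params, y)$leafing_doy
    d <- s$data
    wetter_day <- sample(nrow(d), 1)
    d$precip[wetter_day] <- d$precip[wetter_day] + runif(1, 1, 30)
    s_wet <- station_series(s$station_id, s$latitude, s$longitude,
                            s$elevation, d)
    wet <- predict_tp(s_wet, params, y)$leafing_doy
    if (!is.na(base)) {
      expect_false(is.na(wet))
      expect_lte(wet, base)
    }
    stricter <- tp_params(params$T_b, params$F_star, params$k1, params$k2,
                          params$P_crit + runif(1, 1, 30))
    strict <- predict_tp(s, stricter, y)$leafing_doy
    if (!is.na(strict) && !is.na(base)) expect_gte(strict, base)
  }
})

test_that("TP with no water requirement reduces exactly to SW", {
  set.seed(9)
  pool <- series_pool()
  for (k in seq_len(20)) {
    s <- pool[[1 + (k %% length(pool))]]
    y <- pool_year(s)
    sw <- rand_sw_params()
    tp <- tp_params(sw$T_b, sw$F_star, k1 = 0, k2 = 0, P_crit = 0)
    expect_identical(predict_tp(s, tp, y)$leafing_doy,
                     predict_sw(s, sw, y)$leafing_doy)
  }
})

test_that("PM with K_m = 1 ignores all chilling parameters", {
  set.seed(10)
  pool <- series_pool()
  for (k in seq_len(20)) {
    s <- pool[[1 + (k %% length(pool))]]
    y <- pool_year(s)
    F_star <- runif(1, 50, 600)
    a <- predict_pm(s, pm_params(C_star = runif(1, 1, 90), F_star = F_star,
                                 K_m = 1, T_o = runif(1, 0, 9)), y)
    b <- predict_pm(s, pm_params(C_star = runif(1, 1, 90), F_star = F_star,
                                 K_m = 1, T_o = runif(1, 0, 9)), y)
    expect_identical(a$leafing_doy, b$leafing_doy)
  }
})

test_that("accumulated state straddles the threshold at the leafing day", {
  set.seed(11)
  pool <- series_pool()
  for (k in seq_len(25)) {
    s <- pool[[1 + (k %% length(pool))]]
    y <- pool_year(s)
    params <- rand_sw_params()
    doy <- predict_sw(s, params, y)$leafing_doy
    if (is.na(doy)) next
    t0 <- resolve_start_date(params$t0, y)
    leaf_date <- as.Date(sprintf("%d-01-01", y)) + (doy - 1L)
    gdd_until <- function(last) {
      days <- seq(t0, last, by = "day")
      sum(pmax(0, s$data$tmean[match(days, s$data$date)] - params$T_b))
    }
    expect_gte(gdd_until(leaf_date), params$F_star)
    if (leaf_date > t0) expect_lt(gdd_until(leaf_date - 1), params$F_star)
  }
})

test_that("GSI saturates, zeroes, and demands humidity", {
  # every ramp saturated from day one: tmin high, dry-air VPD ~ 0 at rh 100,
  # photoperiod bound set below the winter day length
  s_hi <- const_series(2001:2002, tmean = 20, rh = 100)
  p <- gsi_params(photo_lo = 1000, photo_hi = 2000)
  expect_equal(predict_gsi(s_hi, p, 2002)$leafing_doy, 1L)
  # tmin always at or below the lower ramp bound: indicator product is 0
  s_cold <- const_series(2001:2002, tmean = -10, rh = 50)
  expect_true(is.na(predict_gsi(s_cold, gsi_params(), 2002)$leafing_doy))
  # missing rh anywhere in the evaluation year is an error
  s_na <- const_series(2001:2002, tmean = 20, rh = 80)
  s_na$data$rh[400] <- NA
  expect_error(predict_gsi(s_na, gsi_params(), 2002),
               class = "phenoTP_data_error")
})

test_that("predictions demand weather coverage of their window", {
  s <- const_series(2001:2002, tmean = 10)
  expect_error(predict_sw(s, sw_params(0, 100), 2000),
               class = "phenoTP_coverage_error")   # before series start
  expect_error(predict_tp(s, tp_params(0, 100, 0.1, 1, 10), 2001),
               class = "phenoTP_coverage_error")   # needs full previous year
  expect_error(predict_sm(s, sm_params(0, 10, 100, 5), 2001),
               class = "phenoTP_coverage_error")   # needs Sep 1 of 2000
})
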