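# Statistics, the odd/even protocol, the objective, and both optimizers.

test_that("rmse matches its formula and rejects bad input", {
  expect_equal(rmse(c(10, 12), c(10, 12)), 0)
  expect_equal(rmse(c(12, 10), c(10, 12)), 2)
  set.seed(21)
  p <- sample(80:160, 20, replace = TRUE)
  o <- sample(80:160, 20, replace = TRUE)
  expect_equal(rmse(p, o), sqrt(sum((p - o)^2) / 20))
  expect_error(rmse(1:3, 1:4), class = "phenoTP_input_error")
  expect_error(rmse(numeric(0), numeric(0)), class = "phenoTP_input_error")
})

test_that("r_squared is squared Pearson correlation", {
  o <- c(100, 110, 120, 135, 150)
  expect_equal(r_squared(o + 7, o), 1)
  expect_equal(r_squared(c(-1, 0, 1), c(1, 0, 1)), 0)  # orthogonal
  set.seed(22)
  p <- rnorm(15, 120, 10); q <- rnorm(15, 120, 10)
  expect_equal(r_squared(p, q),
               (sum((p - mean(p)) * (q - mean(q))) /
                  sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2)))^2)
  expect_error(r_squared(rep(5, 4), 1:4), class = "phenoTP_undefined_error")
  expect_error(r_squared(1:2, 1:2), class = "phenoTP_input_error")
})

test_that("r_squared is affine-invariant but rmse is not", {
  set.seed(23)
  p <- rnorm(12, 130, 8); o <- p + rnorm(12, 0, 3)
  expect_equal(r_squared(2 * p + 5, o), r_squared(p, o))
  expect_false(isTRUE(all.equal(rmse(2 * p + 5, o), rmse(p, o))))
})

test_that("f_statistic follows F = r2 (n-2) / (1 - r2)", {
  expect_identical(f_statistic(0.5, 12), 10)
  expect_identical(f_statistic(0, 25), 0)
  expect_equal(f_statistic(0.28, 13), 0.28 * 11 / 0.72)
  expect_error(f_statistic(1, 10), class = "phenoTP_undefined_error")
  expect_error(f_statistic(0.5, 2), class = "phenoTP_input_error")
})

test_that("odd/even split partitions by calendar-year parity", {
  obs <- leafing_observations(data.frame(
    station_id = "s", species = "sp", year = 1981:1984, leafing_doy = 120))
  sets <- split_odd_even(obs)
  expect_equal(sets$calibration$year, c(1981, 1983))
  expect_equal(sets$validation$year, c(1982, 1984))

  all_odd <- leafing_observations(data.frame(
    station_id = "s", species = "sp", year = c(1981, 1983), leafing_doy = 120))
  expect_equal(nrow(split_odd_even(all_odd)$validation), 0L)

  span <- leafing_observations(data.frame(
    station_id = "s", species = "sp", year = 1981:2005, leafing_doy = 120))
  sets <- split_odd_even(span)
  expect_equal(nrow(sets$calibration), 13L)
  expect_equal(nrow(sets$validation), 12L)
})

test_that("objective composes prediction and rmse with the penalty policy", {
  s <- generate_weather(climate_config(), 1990, 8, seed = 61)
  truth <- tp_params(T_b = 5, F_star = 120, k1 = 0.05, k2 = 0.5, P_crit = 20)
  obs <- generate_leafing(s, truth_spec(truth, noise_sd = 0), seed = 62)
  # exact generating parameters reproduce every date
  expect_equal(objective(s, truth, obs), 0)
  # a parameter set that never leafs is charged the full penalty
  none <- sw_params(T_b = 15, F_star = 1e6)
  expect_equal(objective(s, none, obs, penalty_days = 400), 400)
  # composition oracle: objective == rmse of per-year predictions
  other <- tp_params(T_b = 3, F_star = 150, k1 = 0.1, k2 = 0.6, P_crit = 25)
  pred <- predict_years(s, other, obs$year)$predicted_doy
  expect_equal(objective(s, other, obs),
               rmse(ifelse(is.na(pred), 400, pred), obs$leafing_doy))
  # coverage failures name the offending years
  expect_error(objective(s, truth, leafing_observations(data.frame(
    station_id = "s", species = "sp", year = c(1990, 1995),
    leafing_doy = 140))), class = "phenoTP_coverage_error", regexp = "1990")
})

test_that("annealer is reproducible, respects fixed parameters, and its trace never rises", {
  s <- generate_weather(climate_config(), 1990, 10, seed = 63)
  obs <- generate_leafing(
    s, truth_spec(sw_params(4, 150), noise_sd = 1), seed = 64)
  cfg <- anneal_config(seed = 7, epochs = 8, steps_per_epoch = 40)

  f1 <- fit_simulated_annealing(s, obs, "SW", config = cfg)
  f2 <- fit_simulated_annealing(s, obs, "SW", config = cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace) <= 0))
  for (seed in c(1, 99)) {
    f <- fit_simulated_annealing(s, obs, "SW",
                                 config = anneal_config(seed = seed,
                                                        epochs = 6,
                                                        steps_per_epoch = 30))
    expect_true(all(diff(f$trace) <= 0))
  }

  # all parameters fixed: returned unchanged, objective evaluated once
  sp <- default_parameter_space("SW")
  sp$fixed <- c(4, 150)
  ff <- fit_simulated_annealing(s, obs, "SW", space = sp, config = cfg)
  expect_equal(unname(ff$par), c(4, 150))
  expect_equal(ff$n_eval, 1L)
  expect_equal(ff$objective, objective(s, sw_params(4, 150), obs))

  expect_error(fit_simulated_annealing(s, obs[0, ], "SW", config = cfg),
               class = "phenoTP_input_error")
})

test_that("grid search enumerates exhaustively and finds planted optima", {
  s <- generate_weather(climate_config(), 1990, 10, seed = 65)
  truth <- sw_params(5, 120)
  obs <- generate_leafing(s, truth_spec(truth, noise_sd = 0), seed = 66)

  expect_error(fit_grid(s, obs, "TP"), class = "phenoTP_guard_error")

  # grid containing the generating parameters recovers a zero objective
  sp5 <- parameter_space(c("T_b", "F_star"), c(5, 20), c(15, 520))
  fit5 <- fit_grid(s, obs, "SW", space = sp5, resolution = 26)
  expect_equal(fit5$objective, 0)
  expect_equal(unname(fit5$par), c(5, 120))

  # brute-force re-enumeration oracle on a small instance
  g_tb <- seq(0, 15, length.out = 4); g_fs <- seq(50, 350, length.out = 4)
  best <- Inf; best_x <- NULL
  for (tb in g_tb) for (fs in g_fs) {
    f <- objective(s, sw_params(tb, fs), obs)
    if (f < best) { best <- f; best_x <- c(tb, fs) }
  }
  sp2 <- parameter_space(c("T_b", "F_star"), c(0, 50), c(15, 350))
  fit2 <- fit_grid(s, obs, "SW", space = sp2, resolution = 4)
  expect_equal(fit2$objective, best)
  expect_equal(unname(fit2$par), best_x)

  # monotone single-parameter objective returns the favourable endpoint
  sp1 <- parameter_space(c("T_b", "F_star"), c(0, 20), c(15, 520),
                         fixed = c(5, NA))
  fit1 <- fit_grid(s, obs, "SW", space = sp1, resolution = 6)
  expect_equal(unname(fit1$par["F_star"]), 120)
})

test_that("validation metrics behave under perfect and shifted prediction", {
  s <- generate_weather(climate_config(), 1990, 12, seed = 67)
  truth <- sw_params(4, 150)
  obs <- generate_leafing(s, truth_spec(truth, noise_sd = 0), seed = 68)
  sets <- split_odd_even(obs)
  val <- validate_model(s, truth, sets$validation)
  expect_equal(val$rmse, 0)
  expect_equal(val$r2, 1)
  expect_gt(val$f_stat, 1e6)   # effectively infinite at r2 = 1
  # shifting every observation by 3 days: rmse 3, r2 still 1
  shifted <- sets$validation
  shifted$leafing_doy <- shifted$leafing_doy + 3L
  val3 <- validate_model(s, truth, shifted)
  expect_equal(val3$rmse, 3)
  expect_equal(val3$r2, 1)
  expect_error(validate_model(s, truth, obs[0, ]),
               class = "phenoTP_input_error")
})

test_that("noiseless truth inside the space is fit to under a day", {
  s <- generate_weather(climate_config(), 1992, 14, seed = 69)
  truth <- sw_params(5, 150)
  obs <- generate_leafing(s, truth_spec(truth, noise_sd = 0), seed = 70)
  fit <- fit_simulated_annealing(
    s, split_odd_even(obs)$calibration, "SW",
    config = anneal_config(seed = 3, epochs = 20, steps_per_epoch = 100))
  expect_lte(fit$calibration$rmse, 1)
})

test_that("parameterized starting dates are searched as day offsets", {
  s <- generate_weather(climate_config(), 1992, 12, seed = 71)
  truth <- sw_params(5, 80, t0 = start_date_spec("parameterized", offset = 60))
  obs <- generate_leafing(s, truth_spec(truth, noise_sd = 0), seed = 72)
  sp <- default_parameter_space("SW", start = "parameterized")
  expect_true("t0_offset" %in% sp$name)
  fit <- fit_simulated_annealing(
    s, obs, "SW", space = sp,
    config = anneal_config(seed = 5, epochs = 25, steps_per_epoch = 120))
  expect_lte(fit$calibration$rmse, 1.5)
  expect_equal(fit$params$t0$mode, "parameterized")
})
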