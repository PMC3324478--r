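# Goodness-of-fit statistics and the odd/even-year protocol.

#' Root mean square error between predicted and observed leafing days
#'
#' @param predicted,observed numeric vectors of equal non-zero length; any
#'   failed predictions must already have been replaced under the caller's
#'   penalty policy.
#' @return RMSE in days.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L) {
    ptp_stop("phenoTP_input_error",
             "predicted and observed must have equal non-zero length")
  }
  if (any(is.na(predicted)) || any(is.na(observed))) {
    ptp_stop("phenoTP_input_error", "rmse inputs must not contain NA")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param predicted,observed numeric vectors of equal length >= 3; neither
#'   may be constant.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L) {
    ptp_stop("phenoTP_input_error",
             "r_squared requires equal lengths of at least 3")
  }
  if (any(is.na(predicted)) || any(is.na(observed))) {
    ptp_stop("phenoTP_input_error", "r_squared inputs must not contain NA")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    ptp_stop("phenoTP_undefined_error",
             "r_squared is undefined for constant vectors")
  }
  cor(predicted, observed)^2
}

#' Regression F statistic from R-squared
#'
#' `F = r2 * (n - 2) / (1 - r2)`, the F statistic of the simple linear
#' regression of observed on predicted, with (1, n - 2) degrees of freedom.
#'
#' @param r2 coefficient of determination in \[0, 1).
#' @param n number of year observations (>= 3).
#' @return F statistic (>= 0).
#' @export
f_statistic <- function(r2, n) {
  if (is.na(r2) || r2 < 0 || r2 > 1) {
    ptp_stop("phenoTP_input_error", "r2 must lie in [0, 1]")
  }
  if (r2 == 1) {
    ptp_stop("phenoTP_undefined_error", "F is infinite at r2 = 1")
  }
  if (n < 3) ptp_stop("phenoTP_input_error", "n must be >= 3")
  r2 * (n - 2) / (1 - r2)
}

#' Split observations into odd-year calibration and even-year validation sets
#'
#' Model parameters are estimated on odd calendar years and tested on the
#' independent even years.
#'
#' @param observations a [leafing_observations()] data.frame.
#' @return list with elements `calibration` (odd years) and `validation`
#'   (even years); their union is the input and intersection empty.
#' @export
split_odd_even <- function(observations) {
  odd <- observations$year %% 2 == 1
  list(calibration = observations[odd, , drop = FALSE],
       validation = observations[!odd, , drop = FALSE])
}

# RMSE + R2 + F for one set of per-year predictions. RMSE substitutes
# `penalty_days` of absolute error for failed (NA) predictions; R2/F are
# computed over the successfully predicted pairs only (NA, with a warning,
# if fewer than 3 pairs remain or either vector is constant).
compute_metrics <- function(predicted, observed, penalty_days) {
  err <- ifelse(is.na(predicted), penalty_days, predicted - observed)
  out <- list(rmse = sqrt(mean(err^2)), r2 = NA_real_, f_stat = NA_real_,
              n = length(observed), n_predicted = sum(!is.na(predicted)))
  ok <- !is.na(predicted)
  if (sum(ok) >= 3L) {
    r2 <- tryCatch(r_squared(predicted[ok], observed[ok]),
                   phenoTP_undefined_error = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NA_real_
                   })
    out$r2 <- r2
    if (!is.na(r2) && r2 < 1) out$f_stat <- f_statistic(r2, sum(ok))
    if (!is.na(r2) && r2 == 1) out$f_stat <- Inf
  } else {
    warning("fewer than 3 successful predictions; R2 and F are NA",
            call. = FALSE)
  }
  out
}
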