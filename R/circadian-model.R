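#' Circadian RR-interval regression coefficients
#'
#' Container for the coefficients of the circadian RR model
#'
#' \deqn{\log RR = \beta_0 + \beta_1 Sex + \beta_2 Age + \beta_3 Age^2 +
#'   \beta_4 \sin(2\pi Hour/24) + \beta_5 \cos(2\pi Hour/24) +
#'   \beta_6 \sin(2\pi Hour/24) Sex + \beta_7 \cos(2\pi Hour/24) Sex +
#'   \varepsilon, \quad \varepsilon \sim N(0, \sigma)}
#'
#' with RR in milliseconds, Sex coded 1 for males and 0 for females, Age in
#' years, and Hour the clock time of day (the model is periodic with period
#' 24 h, so any real hour is accepted and reduced mod 24).
#'
#' @param beta0,beta1,beta2,beta3,beta4,beta5,beta6,beta7 Regression
#'   coefficients on the log-millisecond scale: intercept; sex; age; age
#'   squared; sine; cosine; sine-by-sex; cosine-by-sex.
#' @param sigma Standard deviation of the regression error on the log scale
#'   (non-negative; zero gives a deterministic model).
#'
#' @return An object of class `circadian_coefficients`: a named list with
#'   elements `beta` (named numeric vector of length 8) and `sigma`.
#' @seealso [circadian_defaults()] for the reference adult estimates shipped
#'   with the package, [predict_rr()] to evaluate the model.
#' @export
#' @examples
#' cc <- circadian_coefficients(7, 0.1, -0.02, 0.0002, 0.1, 0.06, -0.02, 0.06, sigma = 0.15)
#' predict_rr(cc, sex = 0, age = 30, hour = 0:23)
circadian_coefficients <- function(beta0, beta1, beta2, beta3, beta4, beta5,
                                   beta6, beta7, sigma) {
  beta <- c(
    intercept = unname(beta0), sex = unname(beta1), age = unname(beta2),
    age2 = unname(beta3), sin_t = unname(beta4), cos_t = unname(beta5),
    sin_sex = unname(beta6), cos_sex = unname(beta7)
  )
  assert_finite(beta, "beta")
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be a single finite non-negative number")
  }
  structure(list(beta = beta, sigma = sigma), class = "circadian_coefficients")
}

#' Reference circadian coefficients for healthy adults
#'
#' The coefficient set estimated from 24-hour Holter RR recordings of 18
#' healthy adults (5 males aged 26--45, 13 females aged 20--50), shipped so
#' the model can be evaluated and simulated without refitting:
#' intercept 7.163, sex 0.0961, age -0.0243, age^2 0.00027, sin 0.1055,
#' cos 0.0664, sin-by-sex -0.0155, cos-by-sex 0.0608, sigma 0.15
#' (log-millisecond scale).
#'
#' @return A [circadian_coefficients] object.
#' @export
#' @examples
#' circadian_defaults()
circadian_defaults <- function() {
  circadian_coefficients(
    beta0 = 7.163, beta1 = 0.0961, beta2 = -0.0243, beta3 = 0.00027,
    beta4 = 0.1055, beta5 = 0.0664, beta6 = -0.0155, beta7 = 0.0608,
    sigma = 0.15
  )
}

#' @export
print.circadian_coefficients <- function(x, ...) {
  cat("Circadian RR model coefficients (log-ms scale)\n")
  print(round(x$beta, 5))
  cat("sigma:", format(x$sigma), "\n")
  invisible(x)
}

assert_coefficients <- function(coefs) {
  if (!inherits(coefs, "circadian_coefficients")) {
    abort("`coefs` must be a `circadian_coefficients` object (see `circadian_coefficients()`)")
  }
  invisible(coefs)
}

#' Evaluate the circadian RR model
#'
#' `predict_log_rr()` returns the model mean of log RR (log-milliseconds);
#' `predict_rr()` exponentiates it to the millisecond scale. All covariate
#' arguments are vectorised and recycled against each other. The model is
#' exactly periodic in `hour` with period 24.
#'
#' @param coefs A [circadian_coefficients] object.
#' @param sex 0 (female) or 1 (male).
#' @param age Age in years (non-negative real).
#' @param hour Clock time of day in hours; any finite real, reduced mod 24.
#'
#' @return Numeric vector: log RR (log ms) for `predict_log_rr()`, RR in ms
#'   (strictly positive) for `predict_rr()`.
#' @export
#' @examples
#' predict_log_rr(circadian_defaults(), sex = 0, age = 30, hour = 0) # 6.7434
#' predict_rr(circadian_defaults(), sex = 1, age = 30, hour = c(0, 12))
predict_log_rr <- function(coefs, sex, age, hour) {
  assert_coefficients(coefs)
  assert_sex(sex)
  assert_age(age)
  assert_finite(hour, "hour")
  a <- recycle_args(sex = sex, age = age, hour = hour)
  b <- coefs$beta
  w <- 2 * pi * hour_mod(a$hour) / 24
  s <- sin(w)
  co <- cos(w)
  b[["intercept"]] + b[["sex"]] * a$sex + b[["age"]] * a$age +
    b[["age2"]] * a$age^2 + b[["sin_t"]] * s + b[["cos_t"]] * co +
    b[["sin_sex"]] * s * a$sex + b[["cos_sex"]] * co * a$sex
}

#' @rdname predict_log_rr
#' @export
predict_rr <- function(coefs, sex, age, hour) {
  exp(predict_log_rr(coefs, sex, age, hour))
}

#' Prediction band for the circadian RR model
#'
#' Two-sided normal-theory prediction band on the log scale, exponentiated to
#' milliseconds: `exp(predict_log_rr +/- z * sigma)` with `z` the standard
#' normal quantile for the requested coverage. The band is multiplicatively
#' symmetric around the point prediction and uses the marginal regression
#' `sigma` (it does not account for autocorrelation of residuals; see the
#' package vignette).
#'
#' @inheritParams predict_log_rr
#' @param level Coverage probability, strictly between 0 and 1 (default 0.95).
#'
#' @return A tibble with columns `fit`, `lwr`, `upr` (RR in ms), one row per
#'   recycled covariate combination.
#' @export
#' @examples
#' prediction_band(circadian_defaults(), sex = 0, age = 30, hour = 0)
prediction_band <- function(coefs, sex, age, hour, level = 0.95) {
  assert_coefficients(coefs)
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level) ||
      level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly between 0 and 1")
  }
  mu <- predict_log_rr(coefs, sex, age, hour)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    fit = exp(mu),
    lwr = exp(mu - z * coefs$sigma),
    upr = exp(mu + z * coefs$sigma)
  )
}

#' Attach model predictions to an RR data frame
#'
#' Pipe-friendly wrapper: adds the model prediction (and optionally a
#' prediction band) as columns to a data frame holding `sex`, `age` and
#' `hour` columns.
#'
#' @param data A data frame with columns `sex`, `age`, `hour`.
#' @param coefs A [circadian_coefficients] object.
#' @param level If non-`NULL`, also add `rr_lwr` / `rr_upr` band columns at
#'   this coverage level.
#'
#' @return `data` as a tibble with an added `rr_pred` column (ms), plus
#'   `rr_lwr`/`rr_upr` when `level` is given.
#' @export
#' @examples
#' tibble::tibble(sex = 0, age = 30, hour = c(0, 6, 12, 18)) |>
#'   add_rr_prediction(circadian_defaults(), level = 0.95)
add_rr_prediction <- function(data, coefs, level = NULL) {
  assert_cols(data, c("sex", "age", "hour"))
  out <- tibble::as_tibble(data)
  out$rr_pred <- predict_rr(coefs, out$sex, out$age, out$hour)
  if (!is.null(level)) {
    band <- prediction_band(coefs, out$sex, out$age, out$hour, level = level)
    out$rr_lwr <- band$lwr
    out$rr_upr <- band$upr
  }
  out
}

#' Peak-to-trough circadian amplitude on the log scale
#'
#' For a fixed sex the oscillatory part of the model is a single 24 h
#' harmonic, so its half peak-to-trough amplitude on the log scale is
#' `sqrt((beta4 + beta6 * sex)^2 + (beta5 + beta7 * sex)^2)`.
#'
#' @inheritParams predict_log_rr
#' @return Half-amplitude of the log-RR oscillation (log-ms units).
#' @export
circadian_amplitude <- function(coefs, sex) {
  assert_coefficients(coefs)
  assert_sex(sex)
  b <- coefs$beta
  sqrt((b[["sin_t"]] + b[["sin_sex"]] * sex)^2 +
         (b[["cos_t"]] + b[["cos_sex"]] * sex)^2)
}

#' Read or write circadian coefficients as a flat key-value file
#'
#' The on-disk format is a flat YAML mapping with keys `beta0` .. `beta7`
#' and `sigma`, readable by any YAML parser and by eye.
#'
#' @param coefs A [circadian_coefficients] object.
#' @param path File path.
#'
#' @return `read_coefficients()` returns a [circadian_coefficients] object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
write_coefficients <- function(coefs, path) {
  assert_coefficients(coefs)
  vals <- c(as.list(unname(coefs$beta)), list(coefs$sigma))
  names(vals) <- c(paste0("beta", 0:7), "sigma")
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  vals <- yaml::read_yaml(path)
  needed <- c(paste0("beta", 0:7), "sigma")
  missing <- setdiff(needed, names(vals))
  if (length(missing) > 0) {
    abort(sprintf("coefficient file %s is missing key(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  do.call(circadian_coefficients, vals[needed])
}
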