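#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted circadian model
#'
#' @param x A `circadian_fit` object.
#' @param conf.int Add cluster-robust confidence bounds (t quantiles with
#'   G-1 degrees of freedom)?
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term, estimate, std.error, statistic,
#'   p.value` (std. errors and p-values are cluster-robust by subject),
#'   plus `conf.low`/`conf.high` if requested.
#' @export
tidy.circadian_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p_values)
  )
  if (isTRUE(conf.int)) {
    tq <- qt(1 - (1 - conf.level) / 2, x$df)
    out$conf.low <- out$estimate - tq * out$std.error
    out$conf.high <- out$estimate + tq * out$std.error
  }
  out
}

#' Glance at a fitted circadian model
#'
#' @param x A `circadian_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared` (log scale), `sigma` (residual SD,
#'   log scale), `rmse_ms`, `mape_percent`, `nobs`, `n_subjects`, `df`.
#' @export
glance.circadian_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$diagnostics$r_squared,
    sigma = sqrt(sum(residuals(x$lm)^2) / (x$n_obs - length(x$estimates))),
    rmse_ms = x$diagnostics$rmse_ms,
    mape_percent = x$diagnostics$mape_percent,
    nobs = x$n_obs,
    n_subjects = x$n_subjects,
    df = x$df
  )
}

#' Augment RR observations with fitted values and residuals
#'
#' @param x A `circadian_fit` object.
#' @param ... Unused.
#' @return The model frame as a tibble with `.fitted` (RR in ms) and
#'   `.resid` (log scale) columns appended.
#' @export
augment.circadian_fit <- function(x, ...) {
  out <- x$frame
  out$.fitted <- exp(fitted(x$lm))
  out$.resid <- unname(residuals(x$lm))
  tibble::as_tibble(out)
}

#' Tidy an AR residual model
#'
#' @param x An `ar_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` (`lag_1` ...) and `estimate`.
#' @export
tidy.ar_model <- function(x, ...) {
  tibble::tibble(
    term = if (x$order > 0) sprintf("lag_%d", seq_len(x$order)) else character(0),
    estimate = x$alphas
  )
}

#' Glance at an AR residual model
#'
#' @param x An `ar_model`.
#' @param ... Unused.
#' @return A one-row tibble: `order`, `tau`, `marginal_sd` (stationary SD
#'   from the Yule-Walker equations; `NA` if non-stationary), `stationary`.
#' @export
glance.ar_model <- function(x, ...) {
  stat <- ar_is_stationary(x)
  tibble::tibble(
    order = x$order,
    tau = x$tau,
    marginal_sd = if (stat) ar_marginal_sd(x) else NA_real_,
    stationary = stat
  )
}
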