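# model frame shared by all fitters: explicit harmonic columns so fitted
# coefficients map one-to-one onto circadian_coefficients slots
build_model_frame <- function(data) {
  assert_cols(data, c("subject_id", "sex", "age", "hour", "rr_ms"))
  if (nrow(data) == 0) abort("no observations supplied")
  assert_sex(data$sex)
  assert_age(data$age)
  assert_finite(data$hour, "hour")
  if (any(!is.finite(data$rr_ms) | data$rr_ms <= 0)) {
    abort("`rr_ms` must be finite and strictly positive")
  }
  w <- 2 * pi * hour_mod(data$hour) / 24
  tibble::tibble(
    subject_id = as.character(data$subject_id),
    log_rr = log(data$rr_ms),
    hour = hour_mod(data$hour),
    sex = data$sex, age = data$age, age2 = data$age^2,
    sin_t = sin(w), cos_t = cos(w),
    hour_bin = factor(floor(hour_mod(data$hour)), levels = 0:23)
  )
}

final_formula <- log_rr ~ sex + age + age2 + sin_t + cos_t + sin_t:sex + cos_t:sex

# map lm coefficient names of the final form onto beta0..beta7
final_coef_order <- c(
  "(Intercept)", "sex", "age", "age2", "sin_t", "cos_t", "sex:sin_t", "sex:cos_t"
)

check_design_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf(
      "design matrix is rank deficient; inestimable (collinear) term(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Cluster-robust (sandwich) covariance for a fitted regression
#'
#' Repeated observations from the same subject are correlated, so classical
#' OLS standard errors are too small. The cluster-robust sandwich estimator
#' aggregates scores within each cluster (subject) before forming the meat:
#' `V = c * (X'X)^-1 (sum_g X_g' e_g e_g' X_g) (X'X)^-1` with the CR1
#' small-sample factor `c = G/(G-1) * (n-1)/(n-k)`. With clusters of size
#' one it reduces to the heteroscedasticity-robust (HC1) form.
#'
#' @param fit An `lm` fit or a [fit_circadian_model()] result.
#' @param clusters Cluster labels, one per observation (defaults to the
#'   subject ids stored in a `circadian_fit`).
#' @param type `"CR1"` (sandwich with the standard small-sample factor) or
#'   `"CR3"` (cluster jackknife: refit leaving out one cluster at a time,
#'   via downdated normal equations). With few clusters CR1 is known to
#'   undercover for cluster-level covariates; CR3 is the conservative
#'   current recommendation and is the default used by
#'   [fit_circadian_model()].
#'
#' @return Symmetric covariance matrix over the model coefficients. Warns
#'   when there is a single cluster or fewer clusters than coefficients
#'   (inference unreliable).
#' @export
cluster_robust_covariance <- function(fit, clusters = NULL,
                                      type = c("CR1", "CR3")) {
  type <- match.arg(type)
  if (inherits(fit, "circadian_fit")) {
    clusters <- clusters %||% fit$clusters
    fit <- fit$lm
  }
  if (!inherits(fit, "lm")) abort("`fit` must be an `lm` or `circadian_fit` object")
  if (is.null(clusters)) abort("`clusters` must be supplied for a bare `lm` fit")
  X <- model.matrix(fit)
  e <- residuals(fit)
  if (length(clusters) != nrow(X)) abort("`clusters` must have one label per observation")
  cl <- factor(clusters)
  G <- nlevels(cl)
  n <- nrow(X)
  k <- ncol(X)
  if (G == 1) warn("only one cluster: cluster-robust inference is unreliable")
  if (G > 1 && G < k) warn(sprintf("fewer clusters (%d) than coefficients (%d): inference unreliable", G, k))
  XtX <- crossprod(X)
  if (type == "CR1") {
    bread <- solve(XtX)
    scores <- rowsum(X * e, cl) # G x k matrix of cluster score sums
    meat <- crossprod(scores)
    corr <- if (G > 1) (G / (G - 1)) * ((n - 1) / (n - k)) else 1
    V <- corr * bread %*% meat %*% bread
  } else {
    if (G < 2) abort("CR3 requires at least 2 clusters")
    y <- e + fitted(fit)
    Xty <- crossprod(X, y)
    beta_full <- coef(fit)
    idx <- split(seq_len(n), cl)
    deltas <- vapply(idx, function(i) {
      Xg <- X[i, , drop = FALSE]
      yg <- y[i]
      bg <- solve(XtX - crossprod(Xg), Xty - crossprod(Xg, yg))
      drop(bg) - beta_full
    }, numeric(k))
    V <- tcrossprod(deltas) * (G - 1) / G
    dimnames(V) <- list(names(beta_full), names(beta_full))
  }
  (V + t(V)) / 2
}

# robust Wald p-value for a set of coefficients (F reference with G-1 denom df)
robust_term_p <- function(est, V, idx, G) {
  b <- est[idx]
  Vi <- V[idx, idx, drop = FALSE]
  W <- as.numeric(t(b) %*% solve(Vi, b))
  q <- length(idx)
  pf(W / q, q, max(G - 1, 1), lower.tail = FALSE)
}

new_circadian_fit <- function(lmfit, frame, form, coefs = NULL,
                              vcov_type = "CR1") {
  clusters <- frame$subject_id
  G <- length(unique(clusters))
  V <- cluster_robust_covariance(lmfit, clusters, type = vcov_type)
  est <- coef(lmfit)
  se <- sqrt(diag(V))
  stat <- est / se
  df <- max(G - 1, 1)
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  n <- length(residuals(lmfit))
  k <- length(est)
  sigma <- sqrt(sum(residuals(lmfit)^2) / (n - k))
  rr_obs <- exp(frame$log_rr)
  rr_pred <- exp(fitted(lmfit))
  gof <- goodness_of_fit(rr_obs, rr_pred)
  structure(
    list(
      form = form,
      coefficients = coefs,
      estimates = est, se = se, statistic = stat, p_values = p,
      vcov = V, df = df,
      n_subjects = G, n_obs = n,
      diagnostics = list(
        r_squared = gof$r_squared_log,
        rmse_ms = gof$rmse_ms,
        mape_percent = gof$mape_percent
      ),
      lm = lmfit, frame = frame, clusters = clusters,
      vcov_type = vcov_type
    ),
    class = "circadian_fit"
  )
}

#' Fit the final circadian RR model
#'
#' Fits the log-linear circadian regression (one 24 h sine/cosine harmonic,
#' sex, age, age squared, and sex-by-harmonic interactions) by maximum
#' likelihood (least squares under Gaussian errors) on the log-transformed
#' RR intervals of a multi-subject cohort, and attaches cluster-robust
#' (by-subject) covariance, t-statistics with G-1 degrees of freedom, and
#' goodness-of-fit diagnostics (R-squared on the log scale, RMSE and MAPE on
#' the millisecond scale).
#'
#' @param data A tibble with columns `subject_id, sex, age, hour, rr_ms`
#'   (long format, >= 2 subjects).
#' @param vcov_type Covariance estimator for inference: `"CR3"` (cluster
#'   jackknife, default — reliable at the small subject counts typical of
#'   Holter databases) or `"CR1"` (classical sandwich factor); see
#'   [cluster_robust_covariance()].
#'
#' @return An object of class `circadian_fit` with, among others, elements
#'   `coefficients` (a [circadian_coefficients] with the fitted sigma),
#'   `vcov`, `p_values`, `n_subjects`, `n_obs`, `diagnostics`. Supports
#'   [generics::tidy()], [generics::glance()], [generics::augment()] and
#'   `autoplot()`.
#' @export
fit_circadian_model <- function(data, vcov_type = c("CR3", "CR1")) {
  vcov_type <- match.arg(vcov_type)
  frame <- build_model_frame(data)
  if (length(unique(frame$subject_id)) < 2) {
    abort("at least 2 subjects are required to fit the circadian model")
  }
  X <- model.matrix(final_formula, frame)
  check_design_rank(X)
  lmfit <- lm(final_formula, data = frame)
  est <- coef(lmfit)[final_coef_order]
  n <- nrow(frame)
  sigma <- sqrt(sum(residuals(lmfit)^2) / (n - length(est)))
  coefs <- circadian_coefficients(
    est[1], est[2], est[3], est[4], est[5], est[6], est[7], est[8],
    sigma = sigma
  )
  new_circadian_fit(lmfit, frame, "final", coefs, vcov_type = vcov_type)
}

#' Fit the preliminary hourly-dummy model
#'
#' The model-building path starts from a deliberately over-parameterised
#' specification: a dummy variable for each of the 24 clock hours, sex, age
#' and age squared, and pairwise interactions (hour-by-sex, hour-by-age,
#' sex-by-age, sex-by-age-squared). Non-significant terms are then removed
#' with [backward_eliminate()]; the hourly dummy profile that survives is
#' what motivates the parsimonious single-harmonic final form.
#'
#' @inheritParams fit_circadian_model
#' @param rhs Optional right-hand side (character) overriding the full
#'   preliminary specification, e.g. `"1"` for an intercept-only fit.
#'
#' @return A `circadian_fit` (without a `circadian_coefficients` mapping,
#'   since the dummy parameterisation has no beta0..beta7 form).
#' @export
fit_preliminary_model <- function(data, rhs = NULL) {
  frame <- build_model_frame(data)
  if (length(unique(frame$subject_id)) < 2) {
    abort("at least 2 subjects are required to fit the preliminary model")
  }
  rhs <- rhs %||% paste(
    "hour_bin + sex + age + age2",
    "+ hour_bin:sex + hour_bin:age + sex:age + sex:age2"
  )
  form <- stats::as.formula(paste("log_rr ~", rhs))
  X <- model.matrix(form, frame)
  check_design_rank(X)
  lmfit <- lm(form, data = frame)
  new_circadian_fit(lmfit, frame, "preliminary")
}

#' Backward elimination of non-significant terms
#'
#' Starting from a fitted model, repeatedly removes the single least
#' significant term: at each step every term gets a cluster-robust Wald
#' p-value (F reference with G-1 denominator degrees of freedom); among
#' terms with p above `alpha` that are *eligible* — a main effect is never
#' removed while an interaction containing it survives — the one with the
#' largest p is dropped and the model refitted. Stops when every remaining
#' term is significant at `alpha` (or only the intercept remains).
#'
#' @param fit A `circadian_fit` (typically from [fit_preliminary_model()]).
#' @param alpha Significance threshold (default 0.05). `alpha = 1` removes
#'   nothing.
#'
#' @return A `circadian_fit` for the reduced model, with attribute
#'   `"dropped"` listing the removed terms in drop order.
#' @export
backward_eliminate <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "circadian_fit")) abort("`fit` must be a `circadian_fit` object")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1]")
  }
  frame <- fit$frame
  G <- fit$n_subjects
  vt <- fit$vcov_type %||% "CR1"
  current <- fit
  dropped <- character(0)
  repeat {
    tl <- attr(terms(current$lm), "term.labels")
    if (length(tl) == 0) break
    asg <- attr(model.matrix(current$lm), "assign")
    est <- coef(current$lm)
    V <- cluster_robust_covariance(current$lm, frame$subject_id, type = vt)
    pvals <- vapply(seq_along(tl), function(i) {
      robust_term_p(est, V, which(asg == i), G)
    }, numeric(1))
    # a main effect is protected while any surviving interaction contains it
    comps <- strsplit(tl, ":", fixed = TRUE)
    is_inter <- lengths(comps) > 1
    protected <- vapply(seq_along(tl), function(i) {
      !is_inter[i] && any(vapply(comps[is_inter], function(cp) tl[i] %in% cp, logical(1)))
    }, logical(1))
    candidates <- which(pvals > alpha & !protected)
    if (length(candidates) == 0) break
    worst <- candidates[which.max(pvals[candidates])]
    dropped <- c(dropped, tl[worst])
    new_form <- stats::reformulate(
      if (length(tl) > 1) tl[-worst] else "1",
      response = "log_rr"
    )
    lmfit <- lm(new_form, data = frame)
    current <- new_circadian_fit(lmfit, frame, current$form, vcov_type = vt)
  }
  attr(current, "dropped") <- dropped
  current
}

#' Robust (Huber M-estimation) refit of the final model
#'
#' Maximum-likelihood estimates are sensitive to outliers; as a stability
#' check the final model is re-estimated with Huber M-estimation (tuning
#' constant 1.345, 95% Gaussian efficiency) via [MASS::rlm()]. On clean data
#' the estimates should be virtually identical to the ML ones.
#'
#' @inheritParams fit_circadian_model
#' @param maxit Iteration cap for the IWLS algorithm (default 100);
#'   non-convergence is an error.
#'
#' @return A [circadian_coefficients] object; `sigma` is the robust scale
#'   estimate.
#' @export
robust_refit <- function(data, maxit = 100) {
  frame <- build_model_frame(data)
  X <- model.matrix(final_formula, frame)
  check_design_rank(X)
  rfit <- MASS::rlm(final_formula, data = frame, psi = MASS::psi.huber,
                    k = 1.345, maxit = maxit)
  if (!rfit$converged) {
    abort(sprintf("robust M-estimation did not converge within %d iterations", maxit))
  }
  est <- coef(rfit)[final_coef_order]
  circadian_coefficients(
    est[1], est[2], est[3], est[4], est[5], est[6], est[7], est[8],
    sigma = rfit$s
  )
}

#' Goodness-of-fit metrics for RR predictions
#'
#' RMSE and MAPE are computed on the millisecond scale (the scale on which
#' RR is measured); the coefficient of determination is computed on the log
#' scale (the modelling scale), which makes it invariant to multiplicative
#' rescaling of RR.
#'
#' @param observed,predicted Equal-length vectors of positive RR values (ms).
#' @return A one-row tibble with columns `rmse_ms`, `mape_percent`,
#'   `r_squared_log`.
#' @export
#' @examples
#' goodness_of_fit(c(100, 200), c(110, 190)) # RMSE 10 ms
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length")
  }
  if (length(observed) == 0) abort("empty input")
  if (any(!is.finite(observed) | observed <= 0)) {
    abort("`observed` must be finite and strictly positive")
  }
  if (any(!is.finite(predicted) | predicted <= 0)) {
    abort("`predicted` must be finite and strictly positive")
  }
  lo <- log(observed)
  lp <- log(predicted)
  ss_tot <- sum((lo - mean(lo))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((lo - lp)^2) / ss_tot
  tibble::tibble(
    rmse_ms = sqrt(mean((observed - predicted)^2)),
    mape_percent = 100 * mean(abs(observed - predicted) / observed),
    r_squared_log = r2
  )
}

#' Per-subject residuals of a fitted circadian model
#'
#' @param fit A `circadian_fit`.
#' @return A tibble with columns `subject_id`, `hour_bin`, `resid`
#'   (log-scale residuals in within-subject order), ready for
#'   [fit_ar_residuals()].
#' @export
circadian_residuals <- function(fit) {
  if (!inherits(fit, "circadian_fit")) abort("`fit` must be a `circadian_fit` object")
  tibble::tibble(
    subject_id = fit$frame$subject_id,
    hour_bin = fit$frame$hour_bin,
    resid = unname(residuals(fit$lm))
  )
}

#' @export
print.circadian_fit <- function(x, ...) {
  cat(sprintf("Circadian RR model (%s form): %d obs, %d subjects\n",
              x$form, x$n_obs, x$n_subjects))
  d <- x$diagnostics
  cat(sprintf("sigma = %.4f | R2(log) = %.3f | RMSE = %.1f ms | MAPE = %.1f%%\n",
              sqrt(sum(residuals(x$lm)^2) / (x$n_obs - length(x$estimates))),
              d$r_squared, d$rmse_ms, d$mape_percent))
  cat("cluster-robust SEs (by subject); use tidy() for the coefficient table\n")
  invisible(x)
}

#' Visual predictive check table
#'
#' Compares per-hour quantiles of observed RR with those of data simulated
#' from the fitted model (circadian mean + AR residual process): for each
#' clock-hour bin the 5th/50th/95th percentiles of the observations and of
#' `n_sim` simulated replicates of the full cohort (same covariates and
#' sampling times) are tabulated.
#'
#' @param data Observed RR tibble (`subject_id, sex, age, hour, rr_ms`).
#' @param coefs A [circadian_coefficients] object.
#' @param ar An [ar_model].
#' @param n_sim Number of simulated cohort replicates (>= 2).
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `rr_vpc` with columns `hour_bin`, `obs_p5`,
#'   `obs_p50`, `obs_p95`, `sim_p5`, `sim_p50`, `sim_p95` (ms). Has an
#'   `autoplot()` method.
#' @export
visual_predictive_check <- function(data, coefs, ar, n_sim = 100, seed = NULL) {
  if (!is.numeric(n_sim) || length(n_sim) != 1 || n_sim < 2) {
    abort("`n_sim` must be at least 2")
  }
  frame <- build_model_frame(data)
  mu <- predict_log_rr(coefs, frame$sex, frame$age, frame$hour)
  subjects <- split(seq_len(nrow(frame)), frame$subject_id)
  sims <- with_seed_or_not(seed, {
    purrr::map(seq_len(n_sim), function(r) {
      eps <- numeric(nrow(frame))
      for (idx in subjects) eps[idx] <- simulate_ar_noise(ar, length(idx))
      exp(mu + eps)
    })
  })
  sim_all <- unlist(sims, use.names = FALSE)
  hb <- rep(frame$hour_bin, n_sim)
  qs <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  obs_tab <- tibble::tibble(hour_bin = frame$hour_bin, rr = exp(frame$log_rr)) |>
    dplyr::group_by(.data$hour_bin) |>
    dplyr::summarise(
      obs_p5 = qs(.data$rr)[1], obs_p50 = qs(.data$rr)[2], obs_p95 = qs(.data$rr)[3],
      .groups = "drop"
    )
  sim_tab <- tibble::tibble(hour_bin = hb, rr = sim_all) |>
    dplyr::group_by(.data$hour_bin) |>
    dplyr::summarise(
      sim_p5 = qs(.data$rr)[1], sim_p50 = qs(.data$rr)[2], sim_p95 = qs(.data$rr)[3],
      .groups = "drop"
    )
  out <- dplyr::inner_join(obs_tab, sim_tab, by = "hour_bin")
  class(out) <- c("rr_vpc", class(out))
  out
}
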