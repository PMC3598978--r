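test_that("noise-free data are interpolated exactly and rank problems are named", {
  cohort <- small_cohort(10, seed = 2)
  grid <- hour_grid(step_min = 30)
  noiseless <- ar_model(numeric(0), 0)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), noiseless, grid, seed = 3)
  f <- fit_circadian_model(d)
  expect_equal(unname(f$coefficients$beta), unname(circadian_defaults()$beta),
               tolerance = 1e-8)
  expect_lt(glance(f)$sigma, 1e-10)

  # a single 30-year-old female leaves sex and the age terms inestimable
  solo <- tibble::tibble(subject_id = "s1", sex = 0, age = 30,
                         hour = grid, rr_ms = 800 + 50 * sin(2 * pi * grid / 24))
  expect_error(fit_circadian_model(dplyr::bind_rows(solo, solo)),
               "at least 2 subjects")
  two <- dplyr::bind_rows(solo, dplyr::mutate(solo, subject_id = "s2"))
  expect_error(fit_circadian_model(two), "collinear")
})

test_that("cluster-robust covariance has the right limits", {
  # clusters of size one reduce CR1 to the HC form ~ classical OLS covariance
  withr::with_seed(5, {
    n <- 5000
    x <- rnorm(n)
    y <- 1 + 2 * x + rnorm(n)
  })
  lmfit <- lm(y ~ x)
  V_cr <- cluster_robust_covariance(lmfit, clusters = seq_len(n), type = "CR1")
  V_ols <- vcov(lmfit)
  expect_true(all(abs(V_cr / V_ols - 1) < 0.1))

  # duplicating every subject's rows shrinks naive SEs by sqrt(2) but leaves
  # cluster-robust SEs essentially unchanged
  cohort <- small_cohort(8, seed = 6)
  d <- simulate_cohort_rr(cohort, circadian_defaults(),
                          ar_model(0.5, 0.1), hour_grid(step_min = 15), seed = 7)
  f1 <- fit_circadian_model(d, vcov_type = "CR1")
  d2 <- dplyr::bind_rows(d, d)
  f2 <- fit_circadian_model(d2, vcov_type = "CR1")
  expect_equal(unname(f2$se / f1$se), rep(1, 8), tolerance = 0.01)
  naive1 <- summary(f1$lm)$coefficients[, 2]
  naive2 <- summary(f2$lm)$coefficients[, 2]
  expect_equal(unname(naive2 / naive1), rep(1 / sqrt(2), 8), tolerance = 0.01)

  # single cluster warns
  one <- data.frame(y = rnorm(20), x = rnorm(20))
  expect_warning(
    cluster_robust_covariance(lm(y ~ x, one), clusters = rep(1, 20)),
    "one cluster"
  )
})

test_that("CR3 jackknife covariance equals explicit leave-one-cluster-out refits", {
  cohort <- small_cohort(10, seed = 8)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar_model(0.4, 0.1),
                          hour_grid(step_min = 60), seed = 9)
  f <- fit_circadian_model(d, vcov_type = "CR3")
  frame <- f$frame
  G <- length(unique(frame$subject_id))
  beta_full <- coef(f$lm)
  deltas <- sapply(unique(frame$subject_id), function(s) {
    coef(lm(formula(f$lm), data = frame[frame$subject_id != s, ])) - beta_full
  })
  V_oracle <- tcrossprod(deltas) * (G - 1) / G
  expect_equal(unname(f$vcov), unname(V_oracle), tolerance = 1e-8)
})

test_that("preliminary hourly-dummy model traces the harmonic cycle", {
  cohort <- training_cohort(seed = 10)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar_model(numeric(0), 0.15),
                          hour_grid(step_min = 5), seed = 11)
  prelim <- suppressWarnings(fit_preliminary_model(d)) # 75 terms vs 18 clusters
  final <- fit_circadian_model(d)
  # the dummy model nests the harmonic: its R2 can exceed the final model's
  # by at most a sliver if the single sin/cos pair is the true structure
  expect_gte(prelim$diagnostics$r_squared, final$diagnostics$r_squared - 1e-9)
  expect_lt(prelim$diagnostics$r_squared - final$diagnostics$r_squared, 0.01)
  # intercept-only degenerate request is a valid fit
  flat <- fit_preliminary_model(d, rhs = "1")
  expect_equal(length(flat$estimates), 1L)
  # hour coverage: with a single represented hour the dummies are inestimable
  one_hour <- dplyr::filter(d, floor(hour) == 3)
  expect_error(fit_preliminary_model(one_hour), "collinear")
})

test_that("backward elimination drops null interactions and respects hierarchy", {
  # generating model has no sex-by-harmonic interaction; a largish cohort
  # keeps the cluster-robust Wald tests well calibrated under the null
  cc0 <- circadian_coefficients(7.163, 0.0961, -0.0243, 0.00027,
                                0.1055, 0.0664, 0, 0, sigma = 0.15)
  drops <- sapply(1:10, function(r) {
    cohort <- generate_virtual_cohort(40, 0.5, 20, 50, seed = 100 + r)
    d <- simulate_cohort_rr(cohort, cc0, ar_model(numeric(0), 0.15),
                            hour_grid(step_min = 10), seed = 200 + r)
    f <- fit_circadian_model(d) # default CV3 inference
    red <- backward_eliminate(f, alpha = 0.05)
    kept <- attr(stats::terms(red$lm), "term.labels")
    c(
      inter_gone = !any(c("sex:sin_t", "sex:cos_t", "sin_t:sex", "cos_t:sex") %in% kept),
      mains_kept = all(c("sex", "sin_t", "cos_t") %in% kept)
    )
  })
  expect_gte(sum(drops["inter_gone", ]), 9)
  expect_gte(sum(drops["mains_kept", ]), 9)

  # alpha = 1 never drops; an already-significant fit is a fixed point
  cohort <- training_cohort(seed = 42)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar_model(numeric(0), 0.15),
                          hour_grid(step_min = 10), seed = 43)
  f <- fit_circadian_model(d, vcov_type = "CR1")
  expect_identical(attr(backward_eliminate(f, alpha = 1), "dropped"), character(0))
  if (all(f$p_values <= 0.05)) {
    expect_identical(attr(backward_eliminate(f, alpha = 0.05), "dropped"), character(0))
  }

  # a main effect is never removed while its interaction survives
  red <- backward_eliminate(f, alpha = 0.05)
  kept <- attr(stats::terms(red$lm), "term.labels")
  for (tt in kept[grepl(":", kept)]) {
    for (comp in strsplit(tt, ":")[[1]]) expect_true(comp %in% kept)
  }
})

test_that("robust M-estimation agrees on clean data and resists outliers", {
  cohort <- training_cohort(seed = 20)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar_model(numeric(0), 0.15),
                          hour_grid(step_min = 1), seed = 21)
  ml <- fit_circadian_model(d)$coefficients$beta
  rob <- robust_refit(d)$beta
  # agreement: 0.5% relative for sizeable betas, 1e-3 absolute for the
  # near-zero curvature terms
  expect_true(all(abs(rob - ml) < pmax(0.005 * abs(ml), 1e-3)))

  # contaminate 1% of observations with RR x 10
  d_bad <- d
  idx <- withr::with_seed(22, sample(nrow(d), round(0.01 * nrow(d))))
  d_bad$rr_ms[idx] <- d_bad$rr_ms[idx] * 10
  rob_bad <- robust_refit(d_bad)$beta
  ml_bad <- fit_circadian_model(d_bad)$coefficients$beta
  expect_lt(abs(rob_bad[["intercept"]] - ml[["intercept"]]) / abs(ml[["intercept"]]), 0.02)
  expect_gt(abs(ml_bad[["intercept"]] - ml[["intercept"]]),
            abs(rob_bad[["intercept"]] - ml[["intercept"]]))

  expect_error(robust_refit(d[0, ]), "no observations")
})

test_that("goodness_of_fit computes the printed-scale metrics", {
  expect_equal(goodness_of_fit(c(100, 200), c(110, 190))$rmse_ms, 10)
  expect_equal(goodness_of_fit(c(100, 200), c(110, 180))$mape_percent, 10)
  perfect <- goodness_of_fit(c(100, 200, 300), c(100, 200, 300))
  expect_equal(perfect$rmse_ms, 0)
  expect_equal(perfect$mape_percent, 0)
  expect_equal(perfect$r_squared_log, 1)
  # log-scale R2 is invariant to multiplicative rescaling
  obs <- c(700, 800, 900, 1000); pred <- c(720, 790, 950, 980)
  expect_equal(goodness_of_fit(obs, pred)$r_squared_log,
               goodness_of_fit(10 * obs, 10 * pred)$r_squared_log,
               tolerance = 1e-12)
  expect_error(goodness_of_fit(1:3, 1:4), "length")
  expect_error(goodness_of_fit(c(1, -1), c(1, 1)), "positive")
})

test_that("visual predictive check is self-consistent for model-generated data", {
  cohort <- small_cohort(6, seed = 30)
  ar <- ar_model(0.5, 0.1)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar,
                          hour_grid(step_min = 20), seed = 31)
  vpc <- visual_predictive_check(d, circadian_defaults(), ar, n_sim = 20, seed = 32)
  expect_s3_class(vpc, "rr_vpc")
  inside <- vpc$obs_p50 >= vpc$sim_p5 & vpc$obs_p50 <= vpc$sim_p95
  expect_gte(mean(inside), 0.9)
  expect_error(visual_predictive_check(d, circadian_defaults(), ar, n_sim = 1), "n_sim")
  # deterministic world with identical covariates: all quantiles coincide
  twins <- tibble::tibble(subject_id = c("a", "b", "c"), sex = 0, age = 30)
  d0 <- simulate_cohort_rr(twins, circadian_defaults(), ar_model(numeric(0), 0),
                           hour_grid(step_min = 60), seed = 33)
  vpc0 <- visual_predictive_check(d0, circadian_defaults(),
                                  ar_model(numeric(0), 0), n_sim = 2)
  expect_equal(vpc0$obs_p5, vpc0$obs_p95, tolerance = 1e-9)
  expect_equal(vpc0$obs_p50, vpc0$sim_p50, tolerance = 1e-9)
})

test_that("tidy/glance/augment expose the fit in broom conventions", {
  cohort <- small_cohort(9, seed = 40)
  d <- simulate_cohort_rr(cohort, circadian_defaults(), ar_model(numeric(0), 0.1),
                          hour_grid(step_min = 30), seed = 41)
  f <- fit_circadian_model(d)
  ti <- tidy(f, conf.int = TRUE)
  expect_named(ti, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(ti), 8)
  expect_true(all(ti$p.value >= 0 & ti$p.value <= 1))
  gl <- glance(f)
  expect_true(all(is.finite(unlist(gl))))
  au <- augment(f)
  expect_equal(nrow(au), nrow(d))
  expect_equal(au$.fitted, exp(fitted(f$lm)), ignore_attr = TRUE)
  # covariance is symmetric PSD
  expect_equal(f$vcov, t(f$vcov))
  expect_true(all(eigen(f$vcov, only.values = TRUE)$values > -1e-12))
})
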