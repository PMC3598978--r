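#' Uniform time-of-day sampling grid
#'
#' @param start Start clock hour (default 0).
#' @param step_min Grid step in minutes (> 0; default 1, the resolution the
#'   default AR residual model is calibrated for).
#' @param duration_h Grid span in hours (default 24).
#' @return Numeric vector of hours (not reduced mod 24; model evaluation
#'   reduces internally).
#' @export
#' @examples
#' length(hour_grid()) # 1440 one-minute points over 24 h
hour_grid <- function(start = 0, step_min = 1, duration_h = 24) {
  if (step_min <= 0) abort("`step_min` must be positive")
  if (duration_h <= 0) abort("`duration_h` must be positive")
  n <- floor(duration_h * 60 / step_min)
  start + (seq_len(n) - 1) * step_min / 60
}

#' Simulate an RR series for one subject
#'
#' The generation algorithm has three steps: (1) draw a stationary sequence
#' from the AR residual process, one step per requested time point; (2)
#' evaluate the circadian model mean of log RR at the time points; (3) add
#' the two and exponentiate. With `tau = 0` and all alphas zero the output
#' equals [predict_rr()] exactly.
#'
#' The AR transition is taken once per grid point regardless of spacing; the
#' default AR model is calibrated for a 1-minute grid (see the vignette).
#'
#' @param coefs A [circadian_coefficients] object.
#' @param ar An [ar_model].
#' @param sex,age Subject covariates (scalars; sex 0 = female, 1 = male).
#' @param hours Time points in clock hours (e.g. [hour_grid()]).
#' @param subject_id Label for the output column (default `"s1"`).
#' @param seed Optional integer seed (same seed, same series).
#'
#' @return A tibble with columns `subject_id, sex, age, hour` (clock time in
#'   `[0, 24)`) and `rr_ms` (strictly positive).
#' @export
#' @examples
#' simulate_subject_rr(circadian_defaults(), ar_model(numeric(0), 0),
#'                     sex = 0, age = 30, hours = c(0, 6, 12, 18))
simulate_subject_rr <- function(coefs, ar, sex, age, hours,
                                subject_id = "s1", seed = NULL) {
  assert_coefficients(coefs)
  if (length(hours) == 0) abort("`hours` must be non-empty")
  eps <- simulate_ar_noise(ar, length(hours), seed = seed)
  mu <- predict_log_rr(coefs, sex, age, hours)
  tibble::tibble(
    subject_id = subject_id,
    sex = sex, age = age,
    hour = hour_mod(hours),
    rr_ms = exp(mu + eps)
  )
}

#' Generate a virtual cohort of subject profiles
#'
#' Sex counts are deterministic — `round(n * sex_ratio)` males, the rest
#' female — and ages are drawn uniformly on `[age_low, age_high]`, so a
#' 20-subject cohort at ratio 0.5 always contains exactly 10 males and 10
#' females.
#'
#' @param n Number of subjects (>= 1).
#' @param sex_ratio Fraction of males in `[0, 1]` (default 0.5).
#' @param age_low,age_high Age range in years (`age_low <= age_high`).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `subject_id, sex, age`.
#' @export
#' @examples
#' generate_virtual_cohort(20, 0.5, 20, 50, seed = 1)
generate_virtual_cohort <- function(n, sex_ratio = 0.5, age_low, age_high,
                                    seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  n <- as.integer(n)
  if (sex_ratio < 0 || sex_ratio > 1) abort("`sex_ratio` must be in [0, 1]")
  assert_age(c(age_low, age_high))
  if (age_low > age_high) abort("`age_low` must not exceed `age_high`")
  n_male <- as.integer(round(n * sex_ratio))
  with_seed_or_not(seed, {
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      sex = c(rep(1, n_male), rep(0, n - n_male)),
      age = runif(n, age_low, age_high)
    )
  })
}

#' Simulate RR series for every subject of a cohort
#'
#' Each subject gets an independent child RNG stream derived from the root
#' seed by a stable per-index rule, so cohort simulations are reproducible
#' and per-subject series do not depend on evaluation order.
#'
#' @param cohort A tibble with columns `subject_id, sex, age` (e.g. from
#'   [generate_virtual_cohort()]).
#' @inheritParams simulate_subject_rr
#' @param seed Root seed; `NULL` draws per-subject seeds from the current
#'   RNG stream.
#'
#' @return A long tibble: one [simulate_subject_rr()] block per subject.
#' @export
simulate_cohort_rr <- function(cohort, coefs, ar, hours, seed = NULL) {
  assert_cols(cohort, c("subject_id", "sex", "age"), "cohort")
  root <- seed %||% sample.int(2^31 - 2, 1)
  purrr::pmap_dfr(
    list(cohort$subject_id, cohort$sex, cohort$age, seq_len(nrow(cohort))),
    function(id, sex, age, i) {
      simulate_subject_rr(coefs, ar, sex, age, hours,
                          subject_id = id, seed = child_seed(root, i))
    }
  )
}
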