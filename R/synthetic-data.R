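# beat-level stream for one subject: cumulative-time advance, next beat
# onset = current onset + current RR, circadian mean evaluated at the
# running clock time, one AR transition per beat
simulate_beat_stream <- function(coefs, ar, sex, age, duration_h = 24,
                                 start_hour = 0, seed = NULL) {
  b <- coefs$beta
  # generous upper bound on beat count: RR rarely below ~550 ms here
  n_max <- as.integer(ceiling(duration_h * 3600 * 1000 / 450))
  eps <- simulate_ar_noise(ar, n_max, seed = seed)
  hours <- numeric(n_max)
  rr <- numeric(n_max)
  t_h <- start_hour
  bsex <- b[["sex"]] * sex
  bage <- b[["age"]] * age + b[["age2"]] * age^2
  s_amp <- b[["sin_t"]] + b[["sin_sex"]] * sex
  c_amp <- b[["cos_t"]] + b[["cos_sex"]] * sex
  base <- b[["intercept"]] + bsex + bage
  i <- 0L
  end_h <- start_hour + duration_h
  while (t_h < end_h) {
    i <- i + 1L
    w <- 2 * pi * (t_h %% 24) / 24
    rr_i <- exp(base + s_amp * sin(w) + c_amp * cos(w) + eps[i])
    hours[i] <- t_h %% 24
    rr[i] <- rr_i
    t_h <- t_h + rr_i / 3600000
  }
  tibble::tibble(hour = hours[seq_len(i)], rr_ms = rr[seq_len(i)])
}

#' Generate a dense beat-level synthetic cohort
#'
#' Emulates a 24-hour Holter-style data set: by default 18 subjects (5
#' males aged 26--45, 13 females aged 20--50), each a beat-by-beat RR stream
#' built by cumulative-time advance (the next beat onset is the current
#' onset plus the current RR, with the circadian mean evaluated at the
#' running clock time and one AR residual transition per beat), giving
#' roughly 1e5 beats per subject per 24 h. The returned manifest records
#' the exact generating model and seed, so the data can be reproduced and
#' fits can be checked against ground truth.
#'
#' @param n Number of subjects (default 18).
#' @param n_males Number of males (default 5; must not exceed `n`).
#' @param age_range_male,age_range_female Uniform age ranges in years
#'   (defaults 26--45 and 20--50).
#' @param coefs Generating [circadian_coefficients] (default
#'   [circadian_defaults()]).
#' @param ar Generating [ar_model] (default [default_ar_model()]; note the
#'   AR step is reinterpreted as per-beat here — this is a test fixture,
#'   not a physiological claim).
#' @param duration_h Recording length in hours (default 24).
#' @param seed Root seed (child streams per subject).
#' @param dir If non-`NULL`, write one `rr_<id>.csv` per subject plus
#'   `manifest.yaml` into this directory.
#'
#' @return A list with `data` (long beat-level tibble
#'   `subject_id, sex, age, hour, rr_ms`), `cohort` (subject profiles) and
#'   `manifest` (generating model, cohort description, seed).
#' @export
make_dense_cohort <- function(n = 18, n_males = 5,
                              age_range_male = c(26, 45),
                              age_range_female = c(20, 50),
                              coefs = circadian_defaults(),
                              ar = default_ar_model(),
                              duration_h = 24, seed = NULL, dir = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  if (n_males < 0 || n_males > n) abort("`n_males` must be between 0 and `n`")
  n <- as.integer(n); n_males <- as.integer(n_males)
  root <- seed %||% sample.int(2^31 - 2, 1)
  cohort <- with_seed_or_not(child_seed(root, 0), {
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      sex = c(rep(1, n_males), rep(0, n - n_males)),
      age = c(
        runif(n_males, age_range_male[1], age_range_male[2]),
        runif(n - n_males, age_range_female[1], age_range_female[2])
      )
    )
  })
  data <- purrr::map_dfr(seq_len(n), function(i) {
    stream <- simulate_beat_stream(
      coefs, ar, cohort$sex[i], cohort$age[i],
      duration_h = duration_h, seed = child_seed(root, i)
    )
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      sex = cohort$sex[i], age = cohort$age[i],
      hour = stream$hour, rr_ms = stream$rr_ms
    )
  })
  manifest <- list(
    kind = "dense_beat_level",
    coefficients = c(as.list(unname(coefs$beta)), list(coefs$sigma)) |>
      stats::setNames(c(paste0("beta", 0:7), "sigma")),
    ar = list(order = ar$order, tau = ar$tau, alphas = ar$alphas),
    cohort = list(
      n = n, n_males = n_males,
      age_range_male = age_range_male, age_range_female = age_range_female
    ),
    duration_h = duration_h,
    seed = root
  )
  if (!is.null(dir)) write_cohort_files(data, cohort, manifest, dir, "rr")
  list(data = data, cohort = cohort, manifest = manifest)
}

#' Generate a sparse ambulatory-style synthetic cohort
#'
#' Emulates an ambulatory blood-pressure-monitor validation data set: by
#' default 67 subjects (34 males) aged 17--72, with heart-rate readings on
#' the clinical schedule of one reading every 15 minutes from 08:00 to
#' 22:00 and every 30 minutes from 22:00 to 08:00 (76 ticks per 24 h). RR
#' is drawn from the circadian simulator at the tick times and reported as
#' HR = 60000/RR. Random per-reading missingness thins the schedule to a
#' target mean number of readings (default 71); subjects falling outside
#' the admissible count range (default 35--99) are redrawn.
#'
#' @param n Number of subjects (default 67).
#' @param n_males Number of males (default 34).
#' @param age_range Uniform age range in years (default 17--72).
#' @inheritParams make_dense_cohort
#' @param target_mean_readings Mean readings per subject after missingness
#'   (default 71; set to 76 for a complete schedule with no missingness).
#' @param reading_range Admissible per-subject reading counts (default
#'   `c(35, 99)`).
#'
#' @return A list with `data` (`subject_id, sex, age, hour, hr_bpm`),
#'   `cohort` and `manifest`.
#' @export
make_sparse_cohort <- function(n = 67, n_males = 34, age_range = c(17, 72),
                               coefs = circadian_defaults(),
                               ar = default_ar_model(),
                               target_mean_readings = 71,
                               reading_range = c(35, 99),
                               seed = NULL, dir = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  if (n_males < 0 || n_males > n) abort("`n_males` must be between 0 and `n`")
  n <- as.integer(n); n_males <- as.integer(n_males)
  # acquisition order starting 08:00: day ticks every 15 min to 21:45,
  # then night ticks every 30 min through midnight to 07:30 (76 total)
  ticks <- c(seq(8, 21.75, by = 0.25), seq(22, 31.5, by = 0.5))
  keep_p <- min(target_mean_readings / length(ticks), 1)
  root <- seed %||% sample.int(2^31 - 2, 1)
  cohort <- generate_virtual_cohort(n, n_males / n, age_range[1], age_range[2],
                                    seed = child_seed(root, 0))
  # deterministic sex counts are exact here by construction of the ratio
  data <- purrr::map_dfr(seq_len(n), function(i) {
    rr <- simulate_subject_rr(
      coefs, ar, cohort$sex[i], cohort$age[i], ticks,
      subject_id = cohort$subject_id[i], seed = child_seed(root, i)
    )
    keep <- with_seed_or_not(child_seed(root, 100000 + i), {
      k <- runif(length(ticks)) < keep_p
      tries <- 0L
      while ((sum(k) < reading_range[1] || sum(k) > reading_range[2]) && tries < 1000L) {
        k <- runif(length(ticks)) < keep_p
        tries <- tries + 1L
      }
      k
    })
    rr[keep, ] |>
      dplyr::mutate(hr_bpm = 60000 / .data$rr_ms) |>
      dplyr::select("subject_id", "sex", "age", "hour", "hr_bpm")
  })
  manifest <- list(
    kind = "sparse_ambulatory",
    coefficients = c(as.list(unname(coefs$beta)), list(coefs$sigma)) |>
      stats::setNames(c(paste0("beta", 0:7), "sigma")),
    ar = list(order = ar$order, tau = ar$tau, alphas = ar$alphas),
    cohort = list(n = n, n_males = n_males, age_range = age_range),
    schedule = list(
      day = "every 15 min 08:00-22:00", night = "every 30 min 22:00-08:00",
      target_mean_readings = target_mean_readings, reading_range = reading_range
    ),
    seed = root
  )
  if (!is.null(dir)) write_cohort_files(data, cohort, manifest, dir, "hr")
  list(data = data, cohort = cohort, manifest = manifest)
}

write_cohort_files <- function(data, cohort, manifest, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in cohort$subject_id) {
    readr::write_csv(
      data[data$subject_id == id, , drop = FALSE],
      file.path(dir, sprintf("%s_%s.csv", prefix, id))
    )
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 15)
  invisible(dir)
}
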