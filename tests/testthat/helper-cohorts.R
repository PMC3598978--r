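# cohort mirroring the reference training population:
# 18 subjects, 5 males aged 26-45, 13 females aged 20-50
training_cohort <- function(seed) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("s%03d", 1:18),
    sex = c(rep(1, 5), rep(0, 13)),
    age = c(runif(5, 26, 45), runif(13, 20, 50))
  ))
}

# small fast cohort for unit tests
small_cohort <- function(n = 6, seed = 1) {
  generate_virtual_cohort(n, 0.5, 20, 50, seed = seed)
}

# independent transcription of the circadian regression used as the oracle
# for deterministic model evaluation (kept deliberately separate from the
# package's vectorised implementation)
oracle_log_rr <- function(b, sex, age, hour) {
  h <- hour %% 24
  b[1] + b[2] * sex + b[3] * age + b[4] * age * age +
    b[5] * sin(2 * pi * h / 24) + b[6] * cos(2 * pi * h / 24) +
    b[7] * sin(2 * pi * h / 24) * sex + b[8] * cos(2 * pi * h / 24) * sex
}

eq_defaults_beta <- c(7.163, 0.0961, -0.0243, 0.00027, 0.1055, 0.0664, -0.0155, 0.0608)

write_rr_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
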