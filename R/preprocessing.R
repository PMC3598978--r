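#' Convert heart rate to RR interval length
#'
#' Ambulatory monitors report heart rate in beats per minute; the model works
#' on the RR interval, so sparse validation-style data are converted with
#' `rr = 60000 / hr` (ms).
#'
#' @param hr Heart rate in beats/min (positive, vectorised).
#' @return RR interval length in milliseconds.
#' @export
#' @examples
#' hr_to_rr(c(60, 75, 120)) # 1000, 800, 500
hr_to_rr <- function(hr) {
  assert_finite(hr, "hr")
  if (any(hr <= 0)) abort("`hr` must be strictly positive (beats/min)")
  60000 / hr
}

# shared CSV reader: enforces column presence and a positivity constraint,
# reporting offending rows by file line number (header = line 1)
read_series_csv <- function(path, value_col, col_types) {
  required <- c("subject_id", "sex", "age", "hour", value_col)
  data <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  p <- readr::problems(data)
  if (nrow(p) > 0) {
    abort(sprintf(
      "malformed rows in %s at line(s) %s",
      path, paste(unique(p$row + 1L), collapse = ", ")
    ))
  }
  assert_cols(data, required, sprintf("file %s", path))
  if (nrow(data) == 0) {
    warn(sprintf("%s contains a header but no data rows", path))
    return(tibble::as_tibble(data[required]))
  }
  bad_cov <- which(!is.finite(data$sex) | !(data$sex %in% c(0, 1)) |
                     !is.finite(data$age) | data$age < 0 | !is.finite(data$hour))
  if (length(bad_cov) > 0) {
    abort(sprintf(
      "invalid covariates (sex must be 0/1, age >= 0, hour finite) in %s at line(s) %s",
      path, paste(bad_cov + 1L, collapse = ", ")
    ))
  }
  v <- data[[value_col]]
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive %s in %s at line(s) %s",
      value_col, path, paste(bad + 1L, collapse = ", ")
    ))
  }
  dup <- duplicated(data[c("subject_id", "hour")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (subject_id, hour) row(s) in %s; kept as-is", sum(dup), path))
  }
  tibble::as_tibble(data[required])
}

#' Read RR-interval series from CSV
#'
#' Canonical interchange format: comma-separated, header row, UTF-8, `.`
#' decimal separator, columns `subject_id, sex, age, hour, rr_ms`. Multiple
#' subjects live in one file; the result is a long tibble that downstream
#' functions group by `subject_id`. Hours are clock time; recordings that
#' cross midnight simply wrap (see [resample_every_minute()]).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id, sex, age, hour, rr_ms`.
#'   Malformed rows, missing columns, invalid covariates, or non-positive
#'   RR values raise errors naming the offending file lines; duplicate
#'   (subject, hour) rows are kept with a warning; a header-only file
#'   returns an empty tibble with a warning.
#' @export
read_rr_csv <- function(path) {
  read_series_csv(
    path, "rr_ms",
    readr::cols(
      subject_id = readr::col_character(), sex = readr::col_double(),
      age = readr::col_double(), hour = readr::col_double(),
      rr_ms = readr::col_double(), .default = readr::col_guess()
    )
  )
}

#' Read sparse ambulatory heart-rate series from CSV
#'
#' Same contract as [read_rr_csv()] but with an `hr_bpm` column (beats/min).
#' The expected (not enforced) acquisition schedule is one reading every
#' 15 min from 08:00 to 22:00 and every 30 min from 22:00 to 08:00.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id, sex, age, hour, hr_bpm`.
#' @export
read_ambulatory_csv <- function(path) {
  read_series_csv(
    path, "hr_bpm",
    readr::cols(
      subject_id = readr::col_character(), sex = readr::col_double(),
      age = readr::col_double(), hour = readr::col_double(),
      hr_bpm = readr::col_double(), .default = readr::col_guess()
    )
  )
}

# unwrap clock hours (recordings crossing midnight) to a monotone elapsed axis
unwrap_hours <- function(hour) {
  if (length(hour) == 0) return(hour)
  jumps <- c(0, cumsum(diff(hour) < 0))
  hour + 24 * jumps
}

#' Down-sample a dense beat-level RR series to one value per minute
#'
#' Beat-level 24 h Holter exports contain on the order of 1e5 RR values per
#' subject; model fitting uses one RR per whole minute of recording. For
#' each minute tick (1, 2, ... minutes after each subject's first beat) the
#' selected value is the RR interval whose beat onset time is closest to the
#' tick, with ties resolved in favour of the earlier beat. Every output
#' value therefore appears in the input; nothing is interpolated.
#'
#' @param data A tibble as returned by [read_rr_csv()] (beat-level; `hour`
#'   is the beat onset clock time, recordings crossing midnight wrap).
#' @return A tibble with the same columns, at most one row per recorded
#'   minute per subject. Empty input gives an empty output.
#' @export
resample_every_minute <- function(data) {
  assert_cols(data, c("subject_id", "hour", "rr_ms"))
  if (nrow(data) == 0) return(tibble::as_tibble(data))
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      t_h <- unwrap_hours(d$hour)
      elapsed_s <- (t_h - t_h[1]) * 3600
      # the recording extends to the end of the final RR interval
      duration_s <- elapsed_s[length(elapsed_s)] + d$rr_ms[nrow(d)] / 1000
      n_min <- floor(duration_s / 60 + 1e-9)
      if (n_min < 1) return(d[0, , drop = FALSE])
      ticks <- 60 * seq_len(n_min)
      # nearest beat onset per tick, earlier beat on ties; findInterval gives
      # the last onset <= tick (>= 1 because the first onset is elapsed 0)
      lo <- findInterval(ticks, elapsed_s)
      hi <- pmin(lo + 1L, length(elapsed_s))
      idx <- ifelse(ticks - elapsed_s[lo] > elapsed_s[hi] - ticks, hi, lo)
      d[idx, , drop = FALSE]
    }) |>
    dplyr::ungroup()
}
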