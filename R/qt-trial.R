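#' Hill-equation channel inhibition factor
#'
#' Fractional inhibition of an ionic current at a given free drug
#' concentration: `1 / (1 + (IC50 / C)^n)`. Zero at zero concentration,
#' 0.5 exactly at `C = IC50` (any `n`), strictly increasing in `C` and
#' approaching 1 at high concentration.
#'
#' @param concentration Free drug concentration in uM (>= 0, vectorised).
#' @param ic50 Concentration producing 50% inhibition, in uM (> 0).
#' @param hill_n Hill slope exponent (> 0, default 1).
#'
#' @return Inhibition fraction in `[0, 1)`.
#' @export
#' @examples
#' hill_inhibition(3.8, 29) # moxifloxacin at Cmax on IKr: 0.11585
hill_inhibition <- function(concentration, ic50, hill_n = 1) {
  a <- recycle_args(concentration = concentration, ic50 = ic50, hill_n = hill_n)
  assert_finite(a$concentration, "concentration")
  assert_finite(a$ic50, "ic50")
  assert_finite(a$hill_n, "hill_n")
  if (any(a$concentration < 0)) abort("`concentration` must be >= 0")
  if (any(a$ic50 <= 0)) abort("`ic50` must be > 0")
  if (any(a$hill_n <= 0)) abort("`hill_n` must be > 0")
  ifelse(a$concentration == 0, 0, 1 / (1 + (a$ic50 / a$concentration)^a$hill_n))
}

#' Moxifloxacin channel-inhibition specification
#'
#' IC50 values for the three cardiac currents measurably blocked by
#' moxifloxacin (IKr 29 uM, INa 127.2 uM, ICa 168.9 uM; Hill slope 1), at a
#' default operating concentration of 3.8 uM — the average maximum free
#' plasma concentration after a 400 mg oral dose. At that concentration INa
#' and ICa inhibition are negligible, so the default QT engine uses only
#' IKr.
#'
#' @param conc_um Free drug concentration in uM (default 3.8).
#' @return A tibble with columns `channel, ic50_um, hill_n, conc_um` — the
#'   drug specification accepted by [run_virtual_trial()].
#' @export
moxifloxacin_channels <- function(conc_um = 3.8) {
  tibble::tibble(
    channel = c("IKr", "INa", "ICa"),
    ic50_um = c(29, 127.2, 168.9),
    hill_n = 1,
    conc_um = conc_um
  )
}

# per-channel inhibition map from a drug spec tibble
drug_inhibition_map <- function(drug) {
  assert_cols(drug, c("channel", "ic50_um", "hill_n", "conc_um"), "drug spec")
  inh <- hill_inhibition(drug$conc_um, drug$ic50_um, drug$hill_n)
  stats::setNames(inh, drug$channel)
}

#' Fridericia heart-rate correction of the QT interval
#'
#' `QTcF = QT / (RR / 1000)^(1/3)` with QT and RR in milliseconds; at
#' RR = 1000 ms (60 bpm) the correction is the identity.
#'
#' @param qt_ms QT interval in ms (> 0, vectorised).
#' @param rr_ms RR interval in ms (> 0, vectorised).
#' @return QTcF in ms.
#' @export
#' @examples
#' fridericia_qtc(400, 800) # 430.9 ms
fridericia_qtc <- function(qt_ms, rr_ms) {
  a <- recycle_args(qt_ms = qt_ms, rr_ms = rr_ms)
  assert_finite(a$qt_ms, "qt_ms")
  assert_finite(a$rr_ms, "rr_ms")
  if (any(a$qt_ms <= 0) || any(a$rr_ms <= 0)) {
    abort("`qt_ms` and `rr_ms` must be strictly positive")
  }
  a$qt_ms / (a$rr_ms / 1000)^(1 / 3)
}

#' Surrogate QT engine
#'
#' A QT engine maps an RR interval and a per-channel inhibition map to a QT
#' interval; the full biophysical route (a ventricular-fibre cell model read
#' out as a pseudo-ECG) is out of scope and pluggable behind this contract.
#' The shipped surrogate is `qt = qtc0 * (rr/1000)^(1/3) + drug_gain *
#' inh_IKr + offset`: by construction its drug-free QTcF equals `qtc0`
#' (plus the subject offset scaled back by the Fridericia factor), QT grows
#' monotonically with IKr inhibition, and only IKr feeds the response.
#'
#' @param qtc0 Drug-free QTcF in ms (> 0; default 400, a typical adult
#'   value).
#' @param drug_gain QT prolongation in ms per unit IKr inhibition (>= 0;
#'   default 50 — at moxifloxacin Cmax inhibition 0.116 this yields ~5.8 ms,
#'   a clinically typical individualised delta-QTcF).
#' @param subject_sd SD of the additive between-subject QT offset in ms
#'   (default 10); offsets are drawn by [run_virtual_trial()], fixed per
#'   subject per trial, and passed via the engine's `offset` argument.
#' @param rr_exponent Exponent of the engine's intrinsic QT--RR relation
#'   (default 1/3). At 1/3 the drug-free QTcF is exactly `qtc0` at any heart
#'   rate; any other value (e.g. 1/2, a Bazett-like relation, as biophysical
#'   fibre engines effectively exhibit) makes Fridericia mis-correct the
#'   baseline, so drug-free QTcF drifts with the circadian heart rate — the
#'   mechanism behind the single-point-baseline artifact.
#' @param hr_independent_gain If `TRUE` the drug term is added on the QTcF
#'   scale (i.e. `drug_gain * inh * (rr/1000)^(1/3)` in QT units), making
#'   the drug effect on QTcF independent of heart rate; default `FALSE`,
#'   the plain additive-QT form.
#'
#' @return A function of class `qt_engine` with signature
#'   `(rr_ms, inhibition, offset = 0)` returning QT in ms, carrying
#'   `subject_sd` as an attribute.
#' @export
#' @examples
#' eng <- surrogate_qt_engine(qtc0 = 400, drug_gain = 50, subject_sd = 0)
#' eng(1000, c(IKr = 0.11585)) # 405.79 ms
surrogate_qt_engine <- function(qtc0 = 400, drug_gain = 50, subject_sd = 10,
                                rr_exponent = 1 / 3,
                                hr_independent_gain = FALSE) {
  if (qtc0 <= 0) abort("`qtc0` must be positive")
  if (drug_gain < 0) abort("`drug_gain` must be non-negative")
  if (subject_sd < 0) abort("`subject_sd` must be non-negative")
  f <- function(rr_ms, inhibition = numeric(0), offset = 0) {
    inh_ikr <- if ("IKr" %in% names(inhibition)) inhibition[["IKr"]] else 0
    drug_term <- if (hr_independent_gain) {
      drug_gain * inh_ikr * (rr_ms / 1000)^(1 / 3)
    } else {
      drug_gain * inh_ikr
    }
    qtc0 * (rr_ms / 1000)^rr_exponent + drug_term + offset
  }
  structure(f, class = c("qt_engine", "function"), subject_sd = subject_sd)
}

#' Virtual thorough-QT trial design
#'
#' Default: triplicate trials of 20 subjects each (60 in total, 10 males and
#' 10 females per trial), sampled at clock hours 4, 8, 12, 16, 20 and 24
#' (hour 24 is evaluated as hour 0 by periodicity but reported as 24).
#'
#' @param times_of_day Sampling hours (non-empty).
#' @param n_per_trial Subjects per trial replicate (>= 1, default 20).
#' @param n_trials Number of trial replicates (default 3).
#' @param sex_ratio Fraction of males (default 0.5).
#' @param age_range Two-element age range in years for cohort generation
#'   (default 20--50, the span of the model's training population).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(times_of_day = c(4, 8, 12, 16, 20, 24),
                         n_per_trial = 20, n_trials = 3,
                         sex_ratio = 0.5, age_range = c(20, 50)) {
  if (length(times_of_day) == 0) abort("`times_of_day` must be non-empty")
  if (n_per_trial < 1) abort("`n_per_trial` must be >= 1")
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  structure(
    list(
      times_of_day = times_of_day,
      n_per_trial = as.integer(n_per_trial),
      n_trials = as.integer(n_trials),
      sex_ratio = sex_ratio, age_range = age_range
    ),
    class = "trial_design"
  )
}

#' Run a virtual thorough-QT trial
#'
#' For each trial replicate a fresh cohort is generated; each subject's RR
#' at the design time points is drawn from the circadian simulator, and QT
#' is computed twice from the same RR realisation — once drug-free
#' (zero concentration baseline) and once at the drug's operating
#' concentration — then Fridericia-corrected. Per-subject QT offsets are
#' drawn once per subject per trial from the engine's `subject_sd`.
#'
#' @param design A [trial_design()].
#' @param engine A `qt_engine` (default [surrogate_qt_engine()]).
#' @param drug Drug channel-inhibition tibble (default
#'   [moxifloxacin_channels()]).
#' @param coefs A [circadian_coefficients] (default [circadian_defaults()]).
#' @param ar An [ar_model] (default [default_ar_model()]).
#' @param seed Optional root seed.
#'
#' @return A tibble of class `qt_trial` with one row per (trial, subject,
#'   hour, arm): columns `trial, subject_id, sex, age, hour, rr_ms, qt_ms,
#'   qtcf_ms, arm` (`arm` is `"baseline"` or `"drug"`). The default design
#'   yields 3 x 20 x 6 x 2 = 720 rows.
#' @seealso [delta_qtcf_single_baseline()], [delta_qtcf_individualized()]
#' @export
run_virtual_trial <- function(design = trial_design(),
                              engine = surrogate_qt_engine(),
                              drug = moxifloxacin_channels(),
                              coefs = circadian_defaults(),
                              ar = default_ar_model(),
                              seed = NULL) {
  if (!inherits(design, "trial_design")) abort("`design` must be a `trial_design` object")
  if (!inherits(engine, "qt_engine")) abort("`engine` must be a `qt_engine` (see surrogate_qt_engine())")
  inh_drug <- drug_inhibition_map(drug)
  inh_zero <- stats::setNames(rep(0, length(inh_drug)), names(inh_drug))
  subject_sd <- attr(engine, "subject_sd") %||% 0
  root <- seed %||% sample.int(2^31 - 2, 1)
  out <- purrr::map_dfr(seq_len(design$n_trials), function(tr) {
    cohort <- generate_virtual_cohort(
      design$n_per_trial, design$sex_ratio,
      design$age_range[1], design$age_range[2],
      seed = child_seed(root, 1000 + tr)
    )
    offsets <- with_seed_or_not(
      child_seed(root, 2000 + tr),
      rnorm(nrow(cohort), 0, subject_sd)
    )
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      rr <- simulate_subject_rr(
        coefs, ar, cohort$sex[i], cohort$age[i], design$times_of_day,
        subject_id = cohort$subject_id[i],
        seed = child_seed(root, 10000 * tr + i)
      )$rr_ms
      qt_base <- engine(rr, inh_zero, offsets[i])
      qt_drug <- engine(rr, inh_drug, offsets[i])
      tibble::tibble(
        trial = tr,
        subject_id = sprintf("t%d_%s", tr, cohort$subject_id[i]),
        sex = cohort$sex[i], age = cohort$age[i],
        hour = rep(design$times_of_day, 2),
        rr_ms = rep(rr, 2),
        qt_ms = c(qt_base, qt_drug),
        qtcf_ms = fridericia_qtc(c(qt_base, qt_drug), rep(rr, 2)),
        arm = rep(c("baseline", "drug"), each = length(rr))
      )
    })
  })
  class(out) <- c("qt_trial", class(out))
  out
}

check_trial_obs <- function(obs) {
  assert_cols(obs, c("subject_id", "hour", "qtcf_ms", "arm"), "trial observations")
  if (!any(obs$arm == "baseline")) abort("no baseline records in trial observations")
  if (!any(obs$arm == "drug")) abort("no on-drug records in trial observations")
  invisible(obs)
}

new_qtcf_summary <- function(tab, correction) {
  class(tab) <- c("qtcf_summary", class(tab))
  attr(tab, "correction") <- correction
  tab
}

#' Single-point baseline-corrected delta QTcF
#'
#' The single-point correction subtracts one number — the average baseline
#' QTcF pooled over all subjects and all baseline time points — from every
#' on-drug QTcF. Because this pooled constant ignores the circadian drift of
#' QTcF through heart rate and the per-subject offsets, the resulting
#' delta-QTcF profile inherits circadian structure even for a drug effect
#' that does not vary with time of day.
#'
#' @param obs A `qt_trial` tibble (needs both arms).
#' @return A tibble of class `qtcf_summary` with columns `hour`,
#'   `mean_delta_ms`, `sd_delta_ms`, `n`. Has an `autoplot()` method.
#' @export
delta_qtcf_single_baseline <- function(obs) {
  check_trial_obs(obs)
  base_mean <- mean(obs$qtcf_ms[obs$arm == "baseline"])
  tab <- obs |>
    dplyr::filter(.data$arm == "drug") |>
    dplyr::mutate(delta = .data$qtcf_ms - base_mean) |>
    dplyr::group_by(hour = .data$hour) |>
    dplyr::summarise(
      mean_delta_ms = mean(.data$delta),
      sd_delta_ms = sd(.data$delta),
      n = dplyr::n(), .groups = "drop"
    )
  new_qtcf_summary(tab, "single_point")
}

#' Individualised baseline-corrected delta QTcF
#'
#' Pairs each on-drug record with the same subject's drug-free record at the
#' same time of day and takes the within-pair difference, so additive
#' per-subject QT offsets cancel exactly. Unpaired records are an error
#' naming the offending (subject, hour).
#'
#' @inheritParams delta_qtcf_single_baseline
#' @return A tibble of class `qtcf_summary` (`hour`, `mean_delta_ms`,
#'   `sd_delta_ms`, `n`).
#' @export
delta_qtcf_individualized <- function(obs) {
  check_trial_obs(obs)
  base <- obs |>
    dplyr::filter(.data$arm == "baseline") |>
    dplyr::select("subject_id", "hour", qtcf_base = "qtcf_ms")
  on_drug <- obs |>
    dplyr::filter(.data$arm == "drug")
  paired <- dplyr::full_join(on_drug, base, by = c("subject_id", "hour"))
  bad <- is.na(paired$qtcf_ms) | is.na(paired$qtcf_base)
  if (any(bad)) {
    miss <- paired[bad, c("subject_id", "hour")]
    abort(sprintf(
      "unpaired baseline/drug record(s): %s",
      paste(sprintf("(%s, h=%g)", miss$subject_id, miss$hour), collapse = ", ")
    ))
  }
  tab <- paired |>
    dplyr::mutate(delta = .data$qtcf_ms - .data$qtcf_base) |>
    dplyr::group_by(hour = .data$hour) |>
    dplyr::summarise(
      mean_delta_ms = mean(.data$delta),
      sd_delta_ms = sd(.data$delta),
      n = dplyr::n(), .groups = "drop"
    )
  new_qtcf_summary(tab, "individualized")
}
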