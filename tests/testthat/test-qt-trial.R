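test_that("Hill inhibition has its defining identities", {
  for (n in c(0.5, 1, 2.7)) expect_equal(hill_inhibition(29, 29, n), 0.5)
  expect_equal(hill_inhibition(0, 29), 0)
  expect_equal(hill_inhibition(3.8, 29, 1), 3.8 / 32.8, tolerance = 1e-12)
  expect_equal(hill_inhibition(3.8, 29, 1), 0.11585, tolerance = 1e-4)
  # strictly increasing in concentration, decreasing in IC50, bounded in [0,1)
  conc <- seq(0, 200, by = 5)
  v <- hill_inhibition(conc, 29, 1.3)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
  expect_true(hill_inhibition(10, 20) > hill_inhibition(10, 40))
  expect_error(hill_inhibition(-1, 29), "concentration")
  expect_error(hill_inhibition(1, 0), "ic50")
  # the shipped moxifloxacin table: INa and ICa inhibition are negligible
  inh <- cardiocirc:::drug_inhibition_map(moxifloxacin_channels())
  expect_equal(unname(inh["IKr"]), 0.11585, tolerance = 1e-4)
  expect_lt(inh[["INa"]], 0.03)
  expect_lt(inh[["ICa"]], 0.03)
})

test_that("Fridericia correction matches hand arithmetic and scales linearly", {
  expect_equal(fridericia_qtc(400, 1000), 400)
  expect_equal(fridericia_qtc(400, 800), 400 / 0.8^(1 / 3), tolerance = 1e-12)
  expect_equal(fridericia_qtc(400, 800), 430.9, tolerance = 1e-4)
  # cube root of 1.331 is exactly 1.1
  expect_equal(fridericia_qtc(400, 1331), 400 / 1.1, tolerance = 1e-12)
  expect_equal(fridericia_qtc(3 * 417, 912), 3 * fridericia_qtc(417, 912),
               tolerance = 1e-12)
  expect_error(fridericia_qtc(-1, 800), "positive")
  expect_error(fridericia_qtc(400, 0), "positive")
})

test_that("surrogate engine reproduces its derived values and contract", {
  eng <- surrogate_qt_engine(qtc0 = 400, drug_gain = 0, subject_sd = 0)
  for (rr in c(600, 800, 1000, 1200)) {
    expect_equal(fridericia_qtc(eng(rr, c(IKr = 0)), rr), 400, tolerance = 1e-12)
  }
  eng50 <- surrogate_qt_engine(qtc0 = 400, drug_gain = 50, subject_sd = 0)
  expect_equal(eng50(1000, c(IKr = 0.11585)), 405.7925, tolerance = 1e-4)
  # delta QTcF_i at rr = 848.4: 50 * 0.11585 / 0.8484^(1/3)
  d_i <- fridericia_qtc(eng50(848.4, c(IKr = 0.11585)), 848.4) -
    fridericia_qtc(eng50(848.4, c(IKr = 0)), 848.4)
  expect_equal(d_i, 50 * 0.11585 / 0.8484^(1 / 3), tolerance = 1e-10)
  expect_equal(d_i, 6.12, tolerance = 1e-3)
  # monotone non-decreasing in IKr inhibition, positive QT
  inh_grid <- seq(0, 0.9, by = 0.1)
  qts <- vapply(inh_grid, function(i) eng50(900, c(IKr = i)), numeric(1))
  expect_true(all(diff(qts) >= 0) && all(qts > 0))
})

test_that("virtual trial has the designed dimensions and sharing structure", {
  obs <- run_virtual_trial(seed = 1)
  expect_equal(nrow(obs), 720) # 3 trials x 20 subjects x 6 times x 2 arms
  expect_equal(sort(unique(obs$hour)), c(4, 8, 12, 16, 20, 24))
  expect_equal(length(unique(obs$subject_id)), 60)
  # each (subject, hour) pair shares one RR realisation across arms
  paired <- tidyr::pivot_wider(obs[, c("subject_id", "hour", "arm", "rr_ms")],
                               names_from = "arm", values_from = "rr_ms")
  expect_equal(paired$baseline, paired$drug)

  tiny <- run_virtual_trial(
    trial_design(times_of_day = 12, n_per_trial = 1, n_trials = 1), seed = 2
  )
  expect_equal(nrow(tiny), 2)

  # zero drug concentration: on-drug records equal baseline records
  zero <- run_virtual_trial(drug = moxifloxacin_channels(conc_um = 0), seed = 3)
  pz <- tidyr::pivot_wider(zero[, c("subject_id", "hour", "arm", "qt_ms")],
                           names_from = "arm", values_from = "qt_ms")
  expect_equal(pz$baseline, pz$drug)
})

test_that("hour 24 is evaluated as hour 0 but reported as 24", {
  eng <- surrogate_qt_engine(subject_sd = 0)
  noiseless <- ar_model(numeric(0), 0)
  obs <- run_virtual_trial(
    trial_design(times_of_day = c(0, 24), n_per_trial = 2, n_trials = 1),
    engine = eng, coefs = circadian_defaults(), ar = noiseless, seed = 4
  )
  expect_setequal(unique(obs$hour), c(0, 24))
  w <- tidyr::pivot_wider(obs[obs$arm == "baseline", c("subject_id", "hour", "rr_ms")],
                          names_from = "hour", values_from = "rr_ms")
  expect_equal(w[["0"]], w[["24"]])
})

test_that("single-point baseline correction behaves per contract", {
  # no drug, no variability of any kind -> exactly zero at all hours
  eng0 <- surrogate_qt_engine(drug_gain = 0, subject_sd = 0)
  still <- ar_model(numeric(0), 0)
  obs0 <- run_virtual_trial(engine = eng0, coefs = circadian_defaults(),
                            ar = still, seed = 5)
  s0 <- delta_qtcf_single_baseline(obs0)
  expect_equal(s0$mean_delta_ms, rep(0, 6), tolerance = 1e-12)

  # circadian RR on, gain 0, subject offsets on: the pooled baseline
  # misspecifies the per-hour baseline, so delta varies with hour
  eng_g0 <- surrogate_qt_engine(drug_gain = 0, subject_sd = 10)
  obs_g0 <- run_virtual_trial(engine = eng_g0, seed = 6)
  s_g0 <- delta_qtcf_single_baseline(obs_g0)
  expect_gt(max(abs(s_g0$mean_delta_ms)), 0)
  expect_false(all(s_g0$mean_delta_ms == s_g0$mean_delta_ms[1]))

  # permutation invariance: duplicating all subjects leaves means unchanged
  obs <- run_virtual_trial(seed = 7)
  dup <- dplyr::bind_rows(obs, dplyr::mutate(obs, subject_id = paste0(subject_id, "_bis")))
  expect_equal(delta_qtcf_single_baseline(dup)$mean_delta_ms,
               delta_qtcf_single_baseline(obs)$mean_delta_ms, tolerance = 1e-12)

  expect_error(delta_qtcf_single_baseline(obs[obs$arm == "drug", ]), "baseline")
})

test_that("individualised correction cancels subject offsets exactly", {
  # deterministic RR, arbitrary offsets: paired differences are identical
  # across subjects at a fixed hour
  eng <- surrogate_qt_engine(drug_gain = 50, subject_sd = 25)
  still <- ar_model(numeric(0), 0)
  # fixed age so that, within a sex, every subject has the same RR profile
  obs <- run_virtual_trial(trial_design(age_range = c(30, 30)),
                           engine = eng, ar = still, seed = 8)
  drug <- obs[obs$arm == "drug", ]
  base <- obs[obs$arm == "baseline", ]
  merged <- dplyr::inner_join(drug, base, by = c("subject_id", "hour", "sex", "age"))
  merged$delta <- merged$qtcf_ms.x - merged$qtcf_ms.y
  spread <- tapply(merged$delta, list(merged$sex, merged$hour), function(x) diff(range(x)))
  expect_true(all(spread < 1e-10)) # same sex+hour (hence same RR profile shape) cancel
  ind <- delta_qtcf_individualized(obs)
  expect_equal(nrow(ind), 6)
  expect_true(all(ind$mean_delta_ms > 0))

  # gain 0 -> exactly zero everywhere
  eng0 <- surrogate_qt_engine(drug_gain = 0, subject_sd = 25)
  obs0 <- run_virtual_trial(engine = eng0, seed = 9)
  expect_equal(delta_qtcf_individualized(obs0)$mean_delta_ms, rep(0, 6),
               tolerance = 1e-12)
  expect_equal(delta_qtcf_individualized(obs0)$sd_delta_ms, rep(0, 6),
               tolerance = 1e-12)

  # consistent relabelling leaves the summary unchanged
  obs_rl <- dplyr::mutate(obs, subject_id = paste0("x_", subject_id))
  expect_equal(delta_qtcf_individualized(obs_rl), delta_qtcf_individualized(obs))

  # unpaired records are refused with the offending subject named
  broken <- obs[-1, ]
  expect_error(delta_qtcf_individualized(broken), "unpaired")
})

test_that("single-point correction inherits circadian structure the
           individualised correction removes", {
  # engine with a non-Fridericia intrinsic QT-RR relation (the mechanism
  # behind the artifact) and an HR-independent drug effect on the QTcF scale
  eng <- surrogate_qt_engine(qtc0 = 400, drug_gain = 50, subject_sd = 10,
                             rr_exponent = 1 / 2, hr_independent_gain = TRUE)
  obs <- run_virtual_trial(engine = eng, seed = 10)
  v_single <- var(delta_qtcf_single_baseline(obs)$mean_delta_ms)
  v_indiv <- var(delta_qtcf_individualized(obs)$mean_delta_ms)
  expect_lt(v_indiv, v_single)
  # individualised deltas are exactly flat here (drug effect is the same
  # QTcF shift at every heart rate)
  expect_lt(v_indiv, 1e-20)
})
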