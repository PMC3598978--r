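---
title: "Modelling the circadian rhythm of the RR interval and its use in virtual QT trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the circadian rhythm of the RR interval and its use in virtual QT trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocirc)
```

## The problem

Heart rate follows a pronounced circadian rhythm: RR intervals (the time
between consecutive QRS onsets, inversely proportional to heart rate)
lengthen at night and shorten during the day, and the shape and level of
this oscillation depend on age and sex. Any in-silico assessment of
drug-induced QT prolongation that samples a virtual population at different
times of day needs a generative, subject-specific model of this rhythm —
a fixed heart rate misrepresents both the QT baseline and its apparent
drug response.

`cardiocirc` implements such a model end to end: a cosinor-type regression
for the circadian mean of log RR, a high-order autoregressive (AR) process
for the strong within-subject temporal dependence of the residuals, a
reproducible simulator for virtual subjects and cohorts, and a virtual
thorough-QT (TQT) trial layer with Hill-equation channel inhibition,
Fridericia QTc correction and both common baseline-correction schemes.

## The regression model

For subject covariates Sex (1 = male, 0 = female) and Age (years), and
clock time Hour:

$$\log RR = \beta_0 + \beta_1\,\mathrm{Sex} + \beta_2\,\mathrm{Age} +
\beta_3\,\mathrm{Age}^2 + \beta_4 \sin\!\tfrac{2\pi h}{24} +
\beta_5 \cos\!\tfrac{2\pi h}{24} + \beta_6 \sin\!\tfrac{2\pi h}{24}\mathrm{Sex} +
\beta_7 \cos\!\tfrac{2\pi h}{24}\mathrm{Sex} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma)$$

RR is modelled on the log scale because beat-interval distributions are
right-skewed; a single 24 h sine/cosine pair is the parsimonious
representation that hourly dummy variables collapse onto (the package's
`fit_preliminary_model()` + `backward_eliminate()` reproduce that
model-building path). The reference coefficient set estimated from 18
healthy adults' 24 h Holter recordings ships as `circadian_defaults()`
(intercept 7.163 log-ms, σ = 0.15), so the published model can be
evaluated, plotted and simulated without refitting:

```{r, eval = FALSE}
plot_circadian_profile(circadian_defaults(), sex = c(0, 1), age = 35)
```

`predict_rr()` exponentiates the linear predictor; `prediction_band()`
returns `exp(mu ± z σ)`. The band uses the *marginal* σ — it does not
condition on the AR structure below, which would narrow short-horizon
bands. This matches how such bands are usually drawn for new subjects; the
alternative (AR-conditional bands) is deliberately out of scope.

## The residual process

Within a subject, residuals are strongly serially dependent at the 1-minute
sampling scale. The package models them as a stationary AR(P) process
$\varepsilon_t = \sum_{p=1}^{P} \alpha_p \varepsilon_{t-p} + \eta_t$,
$\eta_t \sim N(0, \tau)$, with the reference values P = 180 (three hours of
1-minute lags) and τ = 0.096.

Only P and τ are published, not the 180 coefficients, so the package must
choose a coefficient *profile*. `default_ar_model()` uses hyperbolically
decaying weights $\alpha_p = k\,p^{-2}$ with $k$ solved exactly — the
stationary variance comes from the Yule–Walker equations, a single linear
solve — so that the process's marginal SD equals the regression σ (0.15)
at τ = 0.096. Two points about this choice:

* **Why the marginal SD must equal σ.** σ and τ were estimated from the
  same residuals; if the AR process had a different stationary SD, the
  pair would be mutually inconsistent. `ar_marginal_sd()` exposes the
  exact Yule–Walker value so this consistency can be asserted (the test
  suite flags fitted σ/τ pairs that disagree by more than 25%).
* **Why decay exponent 2 rather than 1.** σ is, operationally, the
  residual SD *within* a subject's ≈1440-point daily record. A $1/p$
  profile calibrated to the same marginal SD is so persistent
  (spectral mass concentrated at zero frequency) that daily window means
  wander with SD ≈ 0.23 log-units — more than σ itself — and the
  within-record residual SD would re-estimate near 0.105, contradicting
  the measured σ. With $1/p^2$ the window-mean SD is ≈ 0.02 and the
  within-record SD re-estimates at ≈ 0.147. The exponent is therefore
  pinned by self-consistency with how σ was measured, not tuned.

`fit_ar_residuals()` estimates the process by conditional least squares
with a lag design built strictly within subjects (lagged predictors never
cross subject boundaries), pooling one α vector across subjects.
Yule–Walker estimation is the documented alternative; conditional LS was
chosen because it extends naturally to the pooled multi-subject layout.

## Simulation

`simulate_subject_rr()` follows a three-step recipe: draw a stationary AR
sequence (one transition per grid point, burn-in of 10 P steps), add the
circadian mean of log RR at the requested times, exponentiate. The default
AR model is calibrated for a 1-minute grid; on other grids the process is
still stepped once per grid point, which is a declared convention, not a
time rescaling. Cohorts use one root seed with per-subject child streams
derived by a fixed rule, so results are reproducible and independent of
evaluation order.

Consequences worth knowing: at a fixed time the simulated RR is log-normal,
so its median equals `predict_rr()` while its mean carries the usual
$e^{\sigma^2/2}$ correction; the empirical coverage of the 95% prediction
band is ≈95% because the AR marginal SD equals σ.

## Fitting and inference

`fit_circadian_model()` estimates the final form by least squares
(maximum likelihood under Gaussian errors) on log RR. Because each subject
contributes ~1440 correlated observations, naive standard errors are
drastically optimistic; inference is cluster-robust by subject. Two
estimators are provided:

* **CR1** — the classical sandwich with the standard small-sample factor
  $\frac{G}{G-1}\frac{n-1}{n-k}$; it reduces to HC1 with singleton
  clusters. It drives the robust Wald tests of the preliminary-model
  backward elimination.
* **CV3** (default for the final fit) — the cluster jackknife: refit
  leaving out one subject at a time via downdated normal equations. With
  the ~18 subjects typical of Holter databases, CR1 confidence intervals
  undercover for subject-level covariates (roughly 92–93% at nominal
  95%); the jackknife is the currently recommended, slightly
  conservative remedy. p-values and intervals use t quantiles with G − 1
  degrees of freedom.

Backward elimination drops one term per refit — the largest-p term above
the threshold — and never removes a main effect while an interaction
containing it survives; hour is binned to 24 integer dummies in the
preliminary model. Robust (Huber, k = 1.345) M-estimation via `MASS::rlm`
is provided as `robust_refit()` purely as a stability check; on clean data
it reproduces the ML estimates to a fraction of a percent.

Goodness of fit follows the conventions the reference values are printed
in: RMSE and MAPE on the millisecond scale, R² on the log (modelling)
scale, which also makes R² invariant to rescaling RR. On synthetic cohorts
generated from the shipped defaults the pipeline lands near the published
training-set metrics (RMSE ≈ 128 ms, MAPE ≈ 12%, σ ≈ 0.15): with a
log-normal error of SD 0.15 one expects MAPE ≈ 100·√(2/π)·0.15 ≈ 12% and
RMSE ≈ 0.15 × mean RR. R² re-estimates at ≈ 0.33–0.36 against the published
0.39; R² depends on the between-subject covariate spread, and a uniform-age
synthetic cohort is somewhat more homogeneous than the real panel.

## The drug layer

Channel inhibition follows the Hill equation
$\mathrm{inh} = 1/(1 + (\mathrm{IC}_{50}/C)^n)$; the shipped moxifloxacin
table (IKr 29 µM, INa 127.2 µM, ICa 168.9 µM, n = 1) at the free-plasma
Cmax of 3.8 µM gives IKr inhibition 0.116 with negligible INa/ICa block,
which is why the default QT engine consumes only IKr.

The biophysical route from inhibition to QT (a ventricular-fibre cell model
read out as a pseudo-ECG; fibre conventions recorded for engine authors:
Δx = 0.01 mm, Δt = 0.01 ms, D = 0.0016 cm²/ms, 50:30:20
endo/mid/epicardial, 10,000 ms runs, first/last QRS discarded) is *out of
scope* and hidden behind a one-function engine contract:
`engine(rr_ms, inhibition, offset)` → QT (ms), positive and non-decreasing
in IKr inhibition. The shipped surrogate is

$$QT = qtc_0\,(RR/1000)^{e} + g \cdot \mathrm{inh}_{IKr} + b_i$$

with defaults $qtc_0$ = 400 ms (typical adult QTcF), gain $g$ = 50 ms per
unit inhibition (so moxifloxacin at Cmax prolongs by ≈ 5.8 ms, the
clinically reported individualised ΔQTcF scale), between-subject offset
SD 10 ms, and exponent $e = 1/3$, which makes drug-free QTcF exactly
$qtc_0$. Two optional switches exist because real fibre engines do *not*
obey Fridericia exactly: `rr_exponent` ≠ 1/3 (e.g. 1/2, Bazett-like) gives
the engine an intrinsic QT–RR relation that Fridericia mis-corrects, so
drug-free QTcF drifts with the circadian heart rate; `hr_independent_gain`
adds the drug term on the QTcF scale. These are what make the
baseline-correction contrast below structural rather than accidental.

`run_virtual_trial()` mirrors the standard design: triplicate trials of 20
subjects (10 male / 10 female), sampled at 04:00–24:00 every 4 h, each
record simulated drug-free (zero concentration) and on-drug from the same
RR realisation. Two estimands are computed:

* **ΔQTcF (single-point baseline)** — on-drug QTcF minus the *one* pooled
  mean of all baseline QTcF values (all subjects, all times). Pooling over
  times is a documented reading; with a circadian QTcF baseline this
  correction inherits the circadian structure.
* **ΔQTcF\_i (individualised baseline)** — on-drug minus the same
  subject's drug-free QTcF at the same time of day. Additive per-subject
  offsets cancel exactly; with an HR-independent drug effect the profile
  is flat across the day.

The variance-across-hours contrast between the two is the package's
qualitative stand-in for the published trial figures; the published
absolute values (ΔQTcF 10.75/15.87 ms at 08:00/12:00) are not reproducible
here because they depend on the external fibre engine and
population-physiology generator.

## Synthetic data: what it does and does not establish

`make_dense_cohort()` builds beat-level 24 h streams by cumulative-time
advance (next onset = onset + RR, circadian mean evaluated at the running
clock time, one AR transition per *beat*), ≈ 0.7–1.2 × 10⁵ beats per
subject; `make_sparse_cohort()` emulates the ambulatory validation
schedule (every 15 min 08:00–22:00, every 30 min overnight, 76 ticks) with
per-reading missingness thinning to a mean of 71 readings within 35–99.
Both return a manifest (model, seed, cohort description) that exactly
reproduces the data.

These generators share the statistical structure of the model, so green
round-trip tests establish *internal* consistency — correct estimators,
correct simulator, correct plumbing — not external validity. They contain
no ectopy, no measurement artifacts, no non-sinusoidal rhythm shape, and
the per-beat AR reinterpretation in the dense generator means the
minute-scale memory of resampled fixtures is weaker than in real Holter
data (the minute-scale AR refit is therefore checked on 1-minute-grid
simulations, where τ re-estimates at ≈ 0.096).

## Numerical choices and edge cases

* Hours are reduced mod 24 everywhere (the model is periodic by
  construction); hour 24 in a trial design is evaluated at 0 but reported
  as 24. Recordings crossing midnight are unwrapped onto a monotone
  elapsed-time axis before minute resampling.
* Minute resampling picks the beat whose onset is nearest each minute
  tick, earlier beat on ties; ticks run from one minute after the first
  onset to the end of the last RR interval. The rule is pinned by a
  brute-force oracle test.
* Stationarity is checked via companion-matrix eigenvalues
  (`polyroot()` is numerically unreliable at order 180). Non-stationary
  fits warn; simulation from a non-stationary model is refused.
* Age enters as raw (uncentred) years, matching the printed coefficient
  scale; ages are accepted as reals.
* Degenerate inputs: σ = 0 collapses prediction bands; τ = 0 gives
  deterministic simulations; AR order 0 is pure noise; empty CSVs return
  empty tibbles with a warning.

## Known limitations

The AR coefficient profile is an informed convention, not an estimate of
the unpublished one; only its order, innovation SD and marginal SD are
pinned. Prediction bands ignore residual autocorrelation. The surrogate QT
engine is a placeholder with the right interface and qualitative
behaviour, not an electrophysiological model. No mixed-effects extension
is provided: between-subject dependence is handled solely by cluster-robust
inference and the AR process, mirroring the reference methodology.
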