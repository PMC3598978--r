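# cardiocirc

Age- and sex-dependent circadian modelling of the RR interval (heart
rate), with a virtual thorough-QT trial layer for drug proarrhythmia
simulation.

Heart rate oscillates over the 24-hour day, and the oscillation's level
and shape depend on age and sex. In-silico assessment of drug-induced QT
prolongation samples virtual subjects at different times of day, so it
needs a *generative*, subject-specific model of that rhythm. `cardiocirc`
provides one, for pharmacometricians, safety pharmacologists and
biostatisticians building virtual-population cardiac simulations.

## The model

log RR (RR in ms) is a cosinor-type regression with a single 24 h
harmonic:

```
logRR = b0 + b1 Sex + b2 Age + b3 Age^2
      + b4 sin(2*pi*h/24) + b5 cos(2*pi*h/24)
      + b6 sin(2*pi*h/24) Sex + b7 cos(2*pi*h/24) Sex + eps,  eps ~ N(0, sigma)
```

with Sex = 1 for males, Age in years, h the clock hour. Within-subject
residuals follow a stationary AR(P) process
`eps_t = sum_p alpha_p eps_{t-p} + eta_t`, `eta ~ N(0, tau)`, with
reference order P = 180 (three hours of one-minute lags) and tau = 0.096.
A reference coefficient set for healthy adults (intercept 7.163,
sigma = 0.15) ships as `circadian_defaults()`; random RR series are
generated by drawing the AR sequence, adding the circadian mean of log RR,
and exponentiating.

The drug layer computes Hill-equation channel inhibition
`1/(1 + (IC50/C)^n)`, converts QT to QTcF by the Fridericia cube-root
correction, runs triplicate virtual trials of 20 subjects at six times of
day through a pluggable QT engine (a surrogate is shipped; a biophysical
fibre model can be plugged in behind the same contract), and summarises
drug effect with both single-point and individualised delta-QTcF baseline
corrections.

## Worked example

```r
library(cardiocirc)

# evaluate the shipped model: a 30-year-old woman at midnight vs noon
predict_rr(circadian_defaults(), sex = 0, age = 30, hour = c(0, 12))
#> [1] 848.4405 742.9286        # RR in ms; longer intervals (slower HR) at night

prediction_band(circadian_defaults(), 0, 30, 0)
#> # A tibble: 1 x 3
#>     fit   lwr   upr
#>   <dbl> <dbl> <dbl>
#> 1  848.  632. 1138.            # 95% prediction band, ms

# simulate a synthetic 18-subject Holter-style cohort, resample to 1/min,
# and refit the model
dense <- make_dense_cohort(seed = 1)
rs    <- resample_every_minute(dense$data)
fit   <- fit_circadian_model(rs)
glance(fit)
#> # A tibble: 1 x 7
#>   r.squared sigma rmse_ms mape_percent  nobs n_subjects    df
#>       <dbl> <dbl>   <dbl>        <dbl> <int>      <int> <dbl>
#> 1     0.349 0.150    126.         12.0 25920         18    17
```

`sigma` is the residual SD of log RR; RMSE/MAPE are prediction errors on
the millisecond scale; inference in `tidy(fit)` is cluster-robust by
subject (cluster-jackknife by default).

```r
# a virtual moxifloxacin TQT trial at free-plasma Cmax (3.8 uM)
obs <- run_virtual_trial(seed = 7)
delta_qtcf_individualized(obs)
#> # A tibble: 6 x 4
#>    hour mean_delta_ms sd_delta_ms     n
#>   <dbl>         <dbl>       <dbl> <int>
#> 1     4          5.97       0.293    60
#> 2     8          6.15       0.254    60
#> 3    12          6.39       0.296    60
#> 4    16          6.56       0.321    60
#> 5    20          6.34       0.336    60
#> 6    24          6.00       0.327    60
```

A ~6 ms individualised delta-QTcF at moxifloxacin Cmax is the clinically
familiar positive-control scale; the single-point correction
(`delta_qtcf_single_baseline()`) has larger SDs because it ignores
between-subject baseline differences.

See `vignette("circadian-rr-model")` (source under `vignettes/`) for the
model assumptions, the AR-profile calibration, inference choices and
limitations.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — generating the dense synthetic cohort, resampling it to one
observation per minute, fitting the circadian regression and its AR(180)
residual process, exercising the sparse ambulatory validation pathway,
and running the default virtual trial with both baseline corrections —
and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Using real Holter exports

The package reads plain-CSV RR series (`subject_id, sex, age, hour,
rr_ms`). Annotation files from public RR databases can be converted with
any WFDB text exporter (e.g. `ann2rr -r <rec> -a atr -i s -V s`) and fed
through `read_rr_csv()` + `resample_every_minute()`; no binary parsing is
done in-package.
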