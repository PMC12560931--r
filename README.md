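# meatrelax

Meat-quality phenotyping from time-domain NMR relaxometry, handheld NIRS
and consumer sensory panels, with a fully seeded synthetic-cohort
generator for validating every estimator by parameter recovery.

## The problem

Rapid, non-destructive prediction of pork eating quality rests on three
instrument/assay layers that have to be linked statistically:

1. **CPMG relaxometry.** A Carr–Purcell–Meiboom–Gill echo train measures
   transverse (T2) relaxation of muscle water. The decay envelope is
   decomposed into three compartments,

   `I(t) = scale · (p_2f e^(−t/T_2f) + p_21 e^(−t/T_21) + p_22 e^(−t/T_22))`,

   where the fast pool (macromolecule-associated water, fat-linked
   amplitude `p_2f`) relaxes at a fixed `T_2f = 10 ms` to stabilise the
   fit, and the two free pools correspond to intra-myofibrillar
   (`T_21` ≈ tens of ms) and inter-myofibrillar (`T_22` ≈ 100–200 ms)
   water. Scans are signal-averaged until the train's SNR exceeds 200.
2. **NIRS.** A handheld device emits a predicted-IMF scalar; three
   replicate readings per muscle are summarised by mean, geometric mean
   and highest value and regressed against chemical intramuscular fat.
3. **Sensory panels.** Untrained consumers score tenderness, juiciness,
   flavor and overall liking (0–100), plus off-flavor, purchase intent
   (1–5) and quality grade (1–4). Chemistry and instrument outputs are
   linked to these scores through linear mixed models with random
   intercepts for session, participant nested in session, and carcass,
   and through logit-link binomial mixed models for the success
   probabilities.

Because the underlying study data are not deposited, the package ships a
first-class synthetic-cohort generator whose defaults encode the study
conditions (60 carcasses, two muscles — loin `LTL` and topside `SM` —
trait distributions, cross-muscle dependence, acquisition noise, panel
design), plus analytic calibration helpers that invert any published
`(slope, R², RMSE)` caption into an exact generating mechanism. Every
estimator is validated by recovering known injected structure.

## Worked example

```r
library(meatrelax)

# acquire one measurement with adaptive signal averaging, then decompose it
params <- default_nmr_params()
train  <- acquire_with_averaging(params, acquisition_config(),
                                 scale = 1000, seed = 101)
attr(train, "n_scans_averaged")   # 9 scans to pass SNR 200
compute_snr(train)                # 204.1
fit <- fit_triexponential(train)
fit
#> Tri-exponential CPMG fit
#>   amplitudes: p_2f = 0.0475, p_21 = 0.8479, p_22 = 0.1046
#>   time constants: T_2f = 10 ms (fixed), T_21 = 39.65 ms, T_22 = 147.69 ms
#>   scale = 1000, residual RMS = 4.721, converged = TRUE
```

The fitted amplitudes are fractions of the t = 0 signal: here ~4.8% of
the proton signal relaxes with the fixed fast pool, ~84.8% with the
intra-myofibrillar pool near 40 ms and ~10.5% with the
inter-myofibrillar pool near 148 ms — close to the generating values
(0.05 / 0.85 / 0.10 at 40 and 150 ms) at this SNR. `tidy(fit)` and
`glance(fit)` give broom-style tables; `autoplot(fit, train)` overlays
the components on the decay.

```r
# a synthetic cohort with NIRS readings, analysed like the field does
cfg    <- cohort_config(n_carcasses = 60, seed = 2026)
cohort <- generate_cohort(cfg) |> generate_nirs(cfg) |> aggregate_nirs()

ols_regression(cohort, nirs_mean, imf_pct)
#>   slope slope_se intercept    r2       p_value  rmse     n
#>   0.407   0.0636     0.697 0.258 0.00000000326 0.328   120

cross_muscle_regression(cohort)[, c("trait", "slope", "r2", "p_value")]
#>   pH                      0.437  0.160  0.00153
#>   collagen_mg_g           0.559  0.144  0.00274
#>   collagen_solubility_pct 0.371  0.166  0.00125
#>   imf_pct                 0.333  0.0676 0.0448
```

One pooled cohort of 120 samples reproduces the expected weak
NIRS-to-IMF association (R² ≈ 0.26) and weak cross-muscle
predictability of topside chemistry from loin chemistry. The
sensory layer is driven the same way: `generate_sensory()` produces the
panel responses and `fit_chemistry_slopes()`, `fit_single_predictor_slope()`
and `success_probability()` return the mixed-model slope and probability
tables. `run_pipeline()` chains every stage (simulate → acquire → fit →
chemometrics → sensory associations) deterministically under one seed
and writes all intermediate tables as CSV plus a JSON run report.

## Layout

- `R/` — generator (`cohort_config()`, `generate_*`, `link_nmr()`,
  calibration helpers), acquisition and tri-exponential fitting
  (`simulate_echo_train()`, `acquire_with_averaging()`,
  `fit_triexponential()`), chemometrics (`ols_regression()`,
  `pearson_matrix()`, `muscle_contrast()`, `cross_muscle_regression()`),
  mixed-model associations, validated CSV/YAML IO, pipeline.
- `vignettes/meat-quality-relaxometry.Rmd` — the model, its assumptions,
  calibration algebra, numerical choices and limitations.
- `inst/extdata/default_config.yaml` — every generator/acquisition/fit
  default, editable and re-loadable with `read_config_yaml()`.
- `tests/testthat/` — unit, property and acceptance suites.
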