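---
title: "Models and methods: CPMG decomposition, calibrated cohorts, and sensory mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CPMG decomposition, calibrated cohorts, and sensory mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meatrelax)
```

This vignette is the package's account of its science: the relaxation
model and its fitting algorithm, the statistical layer, how the
synthetic-cohort generator encodes the study conditions, the numerical
choices made where the design was genuinely open, and what the passing
tests do and do not establish about real data.

## 1. The three-compartment relaxation model

A CPMG sequence refocuses transverse magnetisation at echo times
$t_k = k\,\Delta t$ ($\Delta t$ = 0.3 ms, 2000 echoes by default, so the
train spans 600 ms). In chilled muscle the decay envelope is modelled as
three exponential pools,

$$I(t) \;=\; S\left(p_{2f}\,e^{-t/T_{2f}} + p_{21}\,e^{-t/T_{21}}
          + p_{22}\,e^{-t/T_{22}}\right),$$

with the conventions used throughout this package:

* **Amplitudes are fractions summing to one**, with the overall scale
  $S$ (the $t=0$ intensity) carried separately. The alternative —
  absolute amplitudes — is observationally equivalent, but the
  fractional convention makes the published regression slopes of
  chemistry on $p_{2f}$ dimensionally consistent (slopes of order 26 in
  %IMF per unit $p_{2f}$ imply $p_{2f}$ spanning a few hundredths).
* **$T_{2f}$ is fixed at 10 ms.** With only 600 ms of train and three
  pools, the fast pool's time constant is barely identifiable and
  letting it float destabilises the other five parameters; fixing it is
  the standard stabilisation and `fit_triexponential()` echoes the fixed
  value back exactly.
* The free pools are labelled so $T_{21} < T_{22}$ always
  (intra-myofibrillar before inter-myofibrillar water).

### Fitting by variable projection

For any candidate pair $(T_{21}, T_{22})$ the three component
amplitudes enter the model **linearly**, so the inner problem
$\min_{A \ge 0} \lVert y - E(T_{21},T_{22})\,A \rVert^2$ is nonnegative
linear least squares. With exactly three columns this is solved
*exactly* by enumerating the $2^3$ support sets and keeping the feasible
minimum — no iterative NNLS is needed. The outer problem is then a
two-dimensional bounded search over $(\log T_{21}, \log T_{22})$,
started from a log-spaced $4\times4$ grid (multi-exponential objectives
are multimodal; the multi-start is the standard guard), with bounds
$T_{21} \in (10, 100]$ ms and $T_{22} \in (100, 2000]$ ms keeping the
pools ordered and separated from the fixed fast pool.

This parameterisation was chosen over a logit-simplex parameterisation
of the amplitudes because it reduces a six-parameter nonconvex problem
to a two-parameter one with an exact inner solve: on noiseless trains
the fit recovers generating parameters to numerical precision, and the
test suite verifies agreement with an exhaustive grid search at 1 ms /
0.01-amplitude resolution.

Two degeneracies are surfaced rather than hidden. If the two fitted
time constants agree within 5% the fit is flagged `degenerate` and the
merged amplitude is reported under $p_{21}$ (the pair is not
identifiable). If all starts fail to converge, `converged = FALSE` is
returned with best-effort parameters.

### Noise, SNR and adaptive averaging

The acquisition model digitises `points_per_echo` points per echo, each
with independent Gaussian noise, and records their mean; averaging $k$
scans divides the per-echo noise SD by $\sqrt{k}$. SNR is defined —
no definition being standard for this instrument class — as the model
intensity extrapolated to $t=0$ divided by the per-echo noise SD. Where
no fit is available (inside the acquisition loop, where fitting every
candidate average would be wasteful) the $t=0$ intensity comes from a
log-quadratic fit to the early echoes and the noise SD from first
differences of the final 10% of echoes divided by $\sqrt 2$
(differencing removes the slowly varying decay and any constant
offset); both estimators are validated against injected truth in the
tests. `acquire_with_averaging()` adds scans until the estimated SNR
exceeds 200 and flags — instead of erroring — trains that cannot reach
the threshold within the scan cap. Noise is Gaussian and independent
across echoes and scans; the Rician floor at long echo times is ignored,
which is appropriate in the SNR > 200 regime the averaging rule
enforces.

Replicate handling follows the convention of averaging the **fitted
parameters** of the three measurements of a sample (arithmetic mean of
the five free parameters), not the echo trains; the alternative
(average the trains, then fit once) is available by fitting the
averaged train directly.

## 2. The statistical layer

* `ols_regression()` is closed-form simple least squares reporting
  slope ± SE, intercept, $R^2$, a two-sided $p$ from the $t$
  distribution on $n-2$ df, and RMSE. RMSE defaults to the **residual
  standard error** $\sqrt{SSE/(n-2)}$ — the convention of the
  regression summaries this field prints — with $\sqrt{SSE/n}$
  available by flag; the two differ by under 1% at $n = 60$.
* `pearson_matrix()` uses pairwise-complete observations and the $t$
  transform of $r$; no multiplicity correction is applied (none is
  applied in the tables it mirrors).
* `muscle_contrast()` implements the two-muscle comparison as an
  ordinary two-group linear model: the published table fits a REML
  model with muscle as the only fixed term and prints no random terms,
  and with no random terms the two are the same model.
* The sensory models are **Gaussian linear mixed models** for the 0–100
  scores — the scores are continuous, and the published slope scales
  (e.g. ~14 score points per pH unit) are on the identity scale — and
  **logit-link binomial mixed models** for off-flavor, purchase-intent
  and quality-grade success probabilities, with the inverse-link
  per-muscle probability and a delta-method SE. The random structure is
  one canonical specification used everywhere: intercepts for session,
  participant nested in session, and carcass (the source tables vary in
  how they write this structure; one consistent nesting is used and the
  tests verify nesting correctness by showing relabeling within session
  is inert while moving a participant across sessions is not).
* Mixed-model $p$-values use the residual-df $t$ approximation
  ($df = n - \mathrm{rank}(X)$). With hundreds of residual df at the
  study design the choice among df approximations is immaterial, and
  the null-simulation test confirms ~5% nominal rejection.
* Singular random-effects fits drop the smallest-variance term (with a
  warning), iterating; a fully degenerate structure reduces to OLS,
  which is also the correct limit analytically.

## 3. The synthetic-cohort generator

The generator's defaults *are* the study conditions; they are not
tuning knobs.

* **Traits.** Each trait–muscle distribution is a truncated normal with
  the published mean, SD reconstructed as SEM·√60, and truncation at
  the published observed ranges (only mean ± SEM and range are
  available). Because the published ranges are asymmetric around the
  means, the underlying location is solved so the *truncated*
  distribution's expectation equals the published mean exactly.
  Truncation mildly shrinks the realised SD below SEM·√60; this is
  accepted as the price of respecting the published ranges.
* **Cross-muscle dependence** is induced by a shared-carcass latent
  factor through a Gaussian copula: the two muscles' latent normals
  correlate at $\sqrt{R^2_{\text{target}}}$, and each maps through its
  own truncated marginal. This is the simplest mechanism consistent
  with the published cross-muscle regressions, and the empirical
  squared correlation matches the target within 0.03 at large $n$.
* **Instrument links.** NIRS: latent device value
  $= \alpha + \gamma\,\mathrm{IMF} +$ between-sample noise, three
  replicate readings each adding replicate noise. NMR:
  $p_{2f} = c + a(\mathrm{IMF}-\overline{\mathrm{IMF}})
  + b(\mathrm{pH}-\overline{\mathrm{pH}}) + \varepsilon$, after which
  the amplitude triplet is renormalised to sum to one *preserving the
  drawn $p_{2f}$ exactly* (the remainder is split between $p_{21}$ and
  $p_{22}$ in their drawn proportion). Defaults for the $p_{2f}$
  coefficients are the analytic inversions of the published marginal
  regressions; the spreads of $p_{21}$/$p_{22}$ were set so the
  single-predictor mixed model's slope SE at the design size matches
  the published SE (~31 tenderness points), i.e. the generator carries
  the same information content the study design did.
* **Sensory responses.** Score = muscle intercept + fixed chemistry
  slopes + session + participant-within-session + carcass random
  intercepts + residual, truncated to [0, 100] (a no-truncation switch
  exists for exact recovery simulations; truncation induces mild
  attenuation absorbed by the recovery tolerances). Intercepts are
  derived so the expected score at the trait means equals the published
  per-muscle mean score. The random-effect SDs (session 3,
  participant 10, carcass 5, residual 15 on the 0–100 scale) are
  **declared arbitrary** — no values are published — and are fully
  configurable. Binary/ordinal responses share logit-scale random
  intercepts; purchase intent and quality grade are ordinal cuts of a
  latent normal whose thresholds are placed so the marginal success
  probabilities default to the published values (0.298/0.351 and
  0.284/0.318). Panel design: three sessions per day over three days,
  twenty participants per session, ten consumers per sample. The
  Latin-square serving order of the real panel is *not* simulated;
  order effects are absorbed into the residual, since no order effect
  is analysed downstream.

### Calibration algebra

A published caption $(b, R^2, \mathrm{RMSE})$ for a simple regression of
$y$ on $x$ determines a bivariate-normal mechanism completely:
$\mathrm{Var}(y) = \mathrm{RMSE}^2/(1-R^2)$, and for the *inverse* link
($x = c + a(y - \mu_y) + \varepsilon$, the direction the instrument
works in): $a = R^2/b$, $\mathrm{Var}(x) = \mathrm{Var}(y)R^2/b^2$,
$\mathrm{Var}(\varepsilon) = \mathrm{Var}(x)(1-R^2)$. Regressing $y$ on
$x$ then recovers the caption in expectation because a bivariate normal
is linear in both directions. `calibrate_link()`,
`calibrate_regression()` and `calibrate_nirs()` implement these
inversions with feasibility checks, and a test verifies the round trip
to $10^{-10}$.

One consequence worth recording: the two published $p_{2f}$ captions
(IMF and pH) *jointly* overdetermine $\mathrm{Var}(p_{2f})$ when the
trait variances are taken from the published SEMs (the two implied
values differ by ~10%), so no single link configuration reproduces both
captions exactly at once. Each recovery experiment therefore calibrates
to its own caption; the default joint link uses both coefficients with
a compromise residual SD and reproduces both structures approximately.

## 4. Problem sizes and numerical choices

Recovery experiments use 200 cohorts for the simple-regression
structures (at $n = 120$ pooled or $n = 60$ per muscle, matching the
study) and 100–300 simulated studies for the mixed-model slopes at the
full design size (60 carcasses × 2 muscles × 10 consumers). These sizes
put the Monte-Carlo error of each averaged estimate a factor of several
below the tolerance it is checked against. Seeds fan out from one
global seed by fixed per-stage offsets so that disabling a pipeline
stage does not shift the random streams of later stages, and identical
configuration + seed gives byte-identical CSV output (verified in the
suite).

Other numerical decisions: the outer optimiser is `nlminb` with
relative tolerance $10^{-10}$; ties in multi-start objective keep the
first-best (start order is deterministic, so results are too); NIRS
readings are floored at a small positive value because the device
reports a nonnegative predicted-IMF; echo-train CSVs are validated for
strictly increasing positive times per measurement; cohort CSVs for
plausibility ranges (pH within [4.5, 7.5], nonnegative concentrations,
exact muscle labels).

## 5. What the tests show — and what they cannot

Passing recovery tests show the *estimators* are correct and unbiased
at the study's design size under the generator's assumptions: Gaussian
noise, linear links, truncated-normal traits, exchangeable random
intercepts. Real muscles violate several of these in known ways —
heterogeneous sampling volumes, freeze–thaw effects on water
compartments, outlying IMF values, non-Gaussian panel behaviour — so
agreement here does not certify field accuracy of the instruments; it
certifies that the analysis layer faithfully measures whatever
structure the data contain. The known limitations worth keeping in
mind:

* The per-scan SNR and scan counts of the real instrument are not
  published; acquisition-noise defaults are plausible guesses, and all
  scale-dependent checks are relative.
* Whether the published SEMs reflect exactly $n = 60$ after exclusions
  is unknown; the SD reconstruction inherits that uncertainty.
* The inverse-Laplace / continuous-$T_2$-distribution alternative to
  discrete tri-exponential fitting is out of scope, as are $T_1$
  recovery, diffusion editing and temperature correction.
* Sensory missingness (the real panel lost a handful of responses) is
  not emulated; the generator produces complete data.
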