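---
title: "Methods: diagnosing float pH bias with a synthetic Southern Ocean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosing float pH bias with a synthetic Southern Ocean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floatbias)
```

## What the pipeline does and what it assumes

Float-derived pCO2 is not measured: it is computed from sensor pH and
algorithm-estimated TA. A pH offset of −0.01 maps to roughly +9 µatm at
400 µatm, so even small calibration residuals matter for air–sea flux
budgets. The package's diagnostic rests on three assumptions, each of
which the pipeline tests rather than takes on faith:

* **Old subsurface water is stable.** Upper and Lower Circumpolar Deep
  Water (UCDW/LCDW) have been isolated from the atmosphere since
  preindustrial times; float and ship measurements taken there decades
  apart should agree if both are accurate. The screen that isolates such
  water is three-fold: depth > 200 m; potential temperature and potential
  density inside the UCDW (2.5 < θ < 3 °C, 27.4 < σ0 < 27.7) or LCDW
  (0 < θ < 2.5 °C, σ0 > 27.7) envelopes; and ship-based anthropogenic
  carbon below 10 µmol kg⁻¹. Only ship data enter the screen — float
  carbon values are the quantity under suspicion.
* **Two independent anthropogenic-carbon estimates bound the screening
  error.** ΔC* subtracts from measured DIC the equilibrium DIC of the
  water's preformed state (TA⁰ at 280 µatm, solved at θ and 0 dbar), the
  biological contribution (remineralization via AOU, carbonate
  dissolution via TA − TA⁰, an N* term for nitrogen-cycle anomalies) and
  an air–sea disequilibrium term. TrOCA needs only O2, DIC, TA and θ with
  published empirical constants. Agreement between the two (the pipeline
  reports their mean absolute difference) indicates the screen is not an
  artifact of either method's assumptions.
* **Surface and subsurface biases are linked.** The standard float
  calibration applies one profile-wide offset anchored at 1500 m, so a
  residual bias above the anchor should appear at the surface too. The
  surface is analysed by two independent routes: the CORS regression of
  ΔCO2 on ΔO2 per platform (a platform-specific intercept offset is a CO2
  measurement bias, because shared biology and physics move both gases
  along the same line), and a direct match against a gridded surface pCO2
  product.

## The synthetic ocean

The generator (`synth_config()`, `generate_dataset()`) emulates exactly
the statistical structure these methods assume, with known ground truth.

**Water column.** Five anchor depths (0, 150, 700, 1800, 2200 m) carry
(θ, S, TA, O2, NO3, ΔC_dis), linearly interpolated. The 700 m anchor
(θ = 2.7 °C, S = 34.55, σ0 ≈ 27.55) sits inside the UCDW envelope and the
1800 m anchor (θ = 1.5 °C, S = 34.72, σ0 ≈ 27.79) inside LCDW. Truth DIC
is *constructed through the back-calculation identity*

&nbsp;&nbsp;DIC(z) = C_280(TA⁰, θ) + ΔC_bio + ΔC_dis(z) + C_anth(z),

so the ΔC* estimate inverts the construction exactly on noise-free ship
data, and water-mass chemistry is consistent with the preformed-tracer
budget by design. Anthropogenic carbon is 45 µmol kg⁻¹ at the surface
with a 300 m e-folding decay (< 1 µmol kg⁻¹ below 1500 m): the deep water
is genuinely "old". The air–sea disequilibrium is −5 µmol kg⁻¹ in the
mixed layer and −15 µmol kg⁻¹ in the deep water masses — a realistic
Circumpolar Deep Water value, and necessary for the synthetic deep water
to be simultaneously consistent with the ΔC* budget and with TrOCA's
empirical preindustrial reference (TrOCA⁰ encodes the real ocean's
disequilibrium; a zero-disequilibrium ocean would make the two methods
disagree structurally by ~15–20 µmol kg⁻¹). The analysis side passes the
same scalar (−15) to ΔC*, mirroring the use of published disequilibrium
climatologies on real data.

The surface O2 anchor (333.4 µmol kg⁻¹) is the saturation concentration
at the default sea-level pressure of 0.98 atm: the mixed layer
equilibrates with the local atmosphere, which keeps the CORS ΔO2
distribution centred near zero so platform intercepts are interpolations,
not extrapolations.

**Per-site variability and noise.** Each ship site perturbs the anchors
(SDs: θ 0.05 °C, S 0.01, TA 1, O2 5, NO3 0.25 µmol kg⁻¹), standing in for
mesoscale variability; co-located floats (80% of floats, within 18 km of
a site) share the site's water column, expressing the assumption that
subsurface water is time-invariant between ship and float occupations.
Sensor noise SDs: float pH 0.01, O2 3, NO3 0.3, T 0.01 °C, S 0.005,
estimated TA 5.6 µmol kg⁻¹ (the published TA-algorithm uncertainty); ship
DIC and TA 2 µmol kg⁻¹, O2 1, NO3 0.2; gridded surface pCO2 14 µatm (the
published product uncertainty). Ship pH and pCO2 are *solved from the
noisy measured DIC and TA*, as in the reference dataset, so ship
carbonate variables are internally consistent by construction.

**Injected bias.** The float pH bias is piecewise-constant in depth with
half-open bands: surface (< 200 m), mid ([200, 1500) m), deep (≥ 1500 m),
defaulting to (−0.0213, −0.0213, 0). The bands are half-open so the
1500 m crossover anchor lies in the deep band: a residual bias measured
*after* a 1500-m-anchored calibration is zero at the anchor by
construction, and a pressure-independent sensor offset above the anchor
is the simplest mechanism consistent with a diagnosed ~15 µatm surface
equivalent. The truth table records, per float level, the pH bias applied
and the *effective* pCO2 bias: the full float processing chain (ideal
crossover, pH-dependent correction, carbonate solve) applied to the
noise-free biased profile, minus truth pCO2 — so recovery checks compare
like with like.

**What the generator does not emulate:** circulation, advection and
spatial covariance beyond per-site jitter; seasonal cycles (subsurface
seasonality is assumed negligible, which is also why matching ignores
time); sensor drift within a float's lifetime; the real algorithms behind
estimated TA (a noise channel with the published uncertainty stands in).
Passing tests therefore show the *pipeline* is correct and sensitive at
realistic noise levels — not that real float data contain a particular
bias.

## The carbonate solver

All carbonate computations use one solver (`carb_solve`) on the total
hydrogen-ion scale with the constant set used for float processing:
K1/K2 from Lueker et al. (2000), KSO4 from Dickson (1990), KF from
Perez & Fraga (1987), total borate from Lee et al. (2010); KB (Dickson
1990), KW, phosphate and silicate constants (Millero 1995) and the
Millero (1995) pressure-correction coefficients follow the conventions
bundled with the Lueker option in the CO2SYS family, as do the Weiss
(1974) solubility and the fugacity virial correction (reported pCO2 is a
partial pressure, fCO2/FugFac). Scale handling mirrors that family:
constants are converted to the seawater scale, pressure-corrected, and
converted back to total with pressure-corrected KS and KF.

Numerics: solving for pH from (DIC, TA) or (TA, pCO2) uses a vectorised
safeguarded Newton iteration on pH bracketed in [3, 12] (the alkalinity
residual is monotone in pH), converged to |ΔTA| < 10⁻⁴ µmol kg⁻¹, with
bisection fallback and a hard error after 200 iterations —
deterministic, no random starts. (pH, TA) → DIC is closed-form. The
solver was cross-checked against an independently written
implementation of the same published formulations (scipy/brentq; see
`inst/oracle/`) on a 100-state Latin hypercube spanning pH 7.2–8.3,
TA 2150–2450 µmol kg⁻¹, T −1.5–26 °C, S 30–37, P 0–4000 dbar: agreement
is better than 10⁻⁵ µatm in pCO2, against a test tolerance of 1 µatm.
Independent anchors against *published* numbers guard against shared
transcription error: the UNESCO potential-temperature and density check
values, the Garcia & Gordon O2 saturation value at (10 °C, 35), Weiss
K0 ≈ 0.0605 mol kg⁻¹ atm⁻¹ at (1 °C, 35), and the published conversion
of 0.84 µmol kg⁻¹ to ~14.1 µatm, which the package reproduces to 1.5%.

θ and σ0 use the EOS-80 formulations (Fofonoff & Millard potential
temperature; Millero & Poisson one-atmosphere density), the standard
companions of practical-salinity data.

## Design choices where the design was open

* **Where the pH-dependent correction is added.** The processing
  description says the per-profile correction (evaluated from the 1500 m
  pH at 25 °C, 0 dbar) is "added to each pH value in the profile" before
  computing pCO2. `float_pco2()` adds it to in-situ pH by default; a
  `correct_at = "ph25"` path re-expresses the corrected 25 °C pH at
  in-situ conditions instead. The two differ by < 0.1 µatm in practice.
* **Crossover reference level.** Floats rarely sample exactly 1500 m, so
  the reference level is the good level nearest 1500 m within
  [1400, 1600] m; profiles without one are unadjustable and excluded.
* **Reference algorithm form.** The deep-pH reference is a linear model
  in T, S, P, P² and O2 fitted to ship levels between 1000 and 2000 m.
  The quadratic pressure term matters: deep pH is not linear in depth,
  and a purely linear form leaves a ~10⁻³ curvature residual at the
  anchor depth that masquerades as a calibration offset.
* **N\* convention.** N* = 0.87 (NO3 − 16 PO4 + 2.90), with the anomaly
  taken against the mean over screened-candidate ship levels of the run.
* **C_280 conditions.** Equilibrium DIC is solved at (θ, 0 dbar) — the
  preformed state — with TA⁰ and 280 µatm.
* **Envelope temperature.** The water-mass envelopes are evaluated on
  potential temperature, standard water-mass practice.
* **Matching conventions.** Thresholds are inclusive (≤ 25 km,
  ≤ window); the depth window is chosen by the float level's depth with
  "shallower than 200 m" read strictly; one ship level may serve several
  float levels; equidistant casts tie-break to the earlier timestamp.
  Distances are haversine on a 6371.0 km sphere.
* **Deming details.** The error-variance ratio defaults to 1 (it is not
  fixed by the source material); the slope standard error is a
  leave-one-out jackknife; the regression standard error is the RMS
  residual in y-units weighted for the orthogonal direction,
  (y − a − bx)/√(1 + b²/δ). The closed-form slope uses an algebraically
  equivalent branch for large δ·s_xx to avoid catastrophic cancellation,
  so the δ → ∞ / δ → 0 limits reproduce the two OLS forms to 10⁻⁸.
* **Deviation-degree uncertainty.** SE = √((n_F+n_S)/(n_F n_S) +
  DD²/(2(n_F+n_S))), the large-sample Cohen's-d approximation. The
  denominator of DD is the root-sum-square of the two SDs — not the
  pooled SD — and a regression test enforces that.
* **Depth bins.** Half-open [k·100, (k+1)·100) m on float depth; a pair
  at exactly 300 m belongs to [300, 400).
* **Seeds.** All stochastic operations take explicit integer seeds
  (R's default generator); the pipeline derives its Monte Carlo seed
  from the dataset seed, so a (config, seed) pair reproduces the
  manifest bit for bit.

## Problem sizes and sensitivity

Default study conditions: 250 ship profiles, 400 float profiles, 25
levels each over 4–2000 m, giving ~8000 matched level pairs of which
~2900 survive the unacidified-water screen — sizes chosen so a full
pipeline run completes in well under a minute on one CPU while keeping
estimator uncertainties small relative to the signals. At these sizes
the screened-subsurface mean ΔpH recovers the injected −0.0213 with a
standard error near 0.0006 (crossover noise dominates), and the
CORS-implied surface bias recovers the effective truth surface ΔpCO2
(~17.7 µatm under the defaults) with a relative spread of about 5%
across seeds — the per-profile crossover noise (pH SD 0.01 at one
reference level) is the limiting term, and the 10% recovery tolerance
used in the tests is therefore a ~2σ statement.

## Known limitations

* EOS-80 rather than TEOS-10 thermodynamics; differences are far below
  every tolerance used here but matter for Absolute-Salinity workflows.
* The solver implements only what the pipeline needs: total scale, one
  constant set, four input pairs; no saturation states, free/seawater
  scale output, or alternative constants.
* The TrOCA route and the vapor-pressure and fit conventions of the CORS
  analysis use fixed published formulations; the source processing
  chains do not print all of their conventions, so exact numerical
  parity with them on real data is not claimed.
* The flux implication is a stated linear scaling (0.21 Pg C yr⁻¹ per
  4 µatm), not a flux recomputation from wind products and transfer
  velocities.
* With all variability switched off the CORS regression is degenerate by
  construction (zero ΔO2 variance); the pipeline raises an explicit
  error rather than fitting through a point cloud of zero extent.
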