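---
title: "Optimal stomatal conductance modelling of citrus leaf gas exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal stomatal conductance modelling of citrus leaf gas exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscm)
```

## The model

`oscm` couples three standard pieces of leaf biophysics into a family of
optimal stomatal conductance-based models (OSCMs) for C3 leaves,
calibrated by default for orchard citrus:

1. **Fick's law of gas diffusion.** Transpiration `E = gs * D / P` and net
   CO2 uptake `A = gs / 1.6 * (ca - ci)`, where `gs` is stomatal
   conductance to water vapor (mol m-2 s-1), `D` the vapor pressure
   deficit (kPa), `P` air pressure (kPa), `ca` and `ci` the ambient and
   intercellular CO2 mole fractions (umol mol-1), and 1.6 the
   water-to-CO2 diffusivity ratio.

2. **FvCB photosynthesis.** Net assimilation is the minimum of the
   Rubisco-limited and RuBP-regeneration-limited branches,
   `Ac = Vcmax (ci - G*) / (ci + Km) - Rd` and
   `Aj = J (ci - G*) / (4 ci + 8 G*) - Rd`, with electron transport
   `J = alpha Q / sqrt(1 + alpha^2 Q^2 / Jmax^2)`. Triose-phosphate
   limitation is excluded by construction, and mesophyll conductance is
   treated as literally infinite so the chloroplast CO2 equals `ci`.
   `Vcmax` and `Jmax` follow a peaked Arrhenius temperature response
   around a 298 K reference; `G*`, `Kc` and `Ko` follow simple Arrhenius
   responses with fixed prefactors (42.75, 274.6, 419.8).

3. **Cowan–Farquhar optimality.** Stomata are assumed to keep the
   marginal water cost of carbon gain, `lambda = dE/dA` (mol H2O per mol
   CO2), constant over short timescales. Given a prescribed `lambda`, the
   three relations close: `lambda(ci)` is strictly increasing between the
   branch's assimilation compensation point and `ca`, and the forward
   solvers invert it by Brent bracketing.

The package provides the forward solvers (`forward()`,
`simulate_dataset()`), the analytic point estimator of `lambda` from gas
exchange records (`lambda_point()`), A-ci calibration of `Vcmax25`,
`Jmax25`, `Rd25` (`fit_aci()`), trimmed-median aggregation of `lambda`
(`characteristic_lambda()`), evaluation metrics and perturbation
sensitivity (`score()`, `sensitivity()`), and a synthetic-data generator
with known ground truth (`gen_meteo()`, `gen_gas_exchange()`,
`gen_aci()`).

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `Vcmax25` | 43.21 | umol m-2 s-1 | Rubisco capacity at 25 degC |
| `Jmax25` | 75.56 | umol m-2 s-1 | maximum electron transport at 25 degC |
| `Rd25` | 1.77 | umol m-2 s-1 | day respiration at 25 degC |
| `alpha` | 0.24 | – | quantum yield of electron transport |
| `O` | 210 | mmol mol-1 | intercellular O2 |
| `gmin` | 0.01 | mol m-2 s-1 | minimum conductance floor |
| `lambda` (co / Vc / Vj) | 1787.10 / 1478.51 / 2703.65 | mol mol-1 | characteristic marginal water cost |

The three rates are the averages of five per-curve A-ci calibrations for
orchard citrus; the `lambda` constants are the campaign-wide trimmed
medians of the analytic point estimates, pooled over all valid points
(`CITRUS_LAMBDA_CO`, `_VC`, `_VJ`). Both tables ship as plain-text
fixtures (`citrus_aci_parameters()`, `citrus_daily_lambda()`).

Unit conventions are fixed throughout: `A` in umol m-2 s-1, `E` in
mmol m-2 s-1, `gs` in mol m-2 s-1, CO2 as umol mol-1 mole fractions.
`lambda_point()` therefore carries a factor 10^3 on `E/A`, and the solver
objective carries 10^6 on `1.6 D / (P (ca - ci))`; the single test that
pins every unit choice simultaneously is the round trip
`lambda_point(forward(lambda)) == lambda` to 1e-6 relative.

## Numerical choices

* **Reference temperature.** The temperature responses use 298 (not
  298.15) in the exponents while `Tk = Tl + 273.15`; this 0.15 K
  mismatch is inherited from the calibrated constants and kept as
  printed. Leaf temperature defaults to leaf-surface air temperature.
* **Rd temperature response.** The calibration source cites the peaked
  Arrhenius correction for `Rd` but publishes no entropy/activation
  coefficients for it, so the default is a constant `Rd = Rd25`
  (`rd_temperature_mode = "constant"`); an optional simple-Arrhenius mode
  (Ea = 46390 J mol-1, a standard tobacco-derived value) is available.
  The choice matters for temperature sensitivity: with constant `Rd` the
  RuBP-limited form's response to air temperature is muted, and the
  "temperature dominates all other meteorological drivers" behaviour of
  the field study is reproduced only for the Rubisco-limited form (or for
  both forms under the Arrhenius mode).
* **Combined-form solver.** The combined OSC form solves the implicit
  optimality equation directly on the composite `min(Ac, Aj)`
  assimilation. The composite objective `lambda(ci)` is strictly
  increasing on each branch but jumps upward where the limitation
  switches; a prescribed `lambda` inside that jump has no root — the
  optimum sits at the crossover kink — and `forward()` then returns the
  kink state flagged `converged = FALSE` rather than silently claiming
  the target. (An alternative design, solving the two single branches and
  selecting a self-consistent one, was rejected: in darkness it returns a
  spurious unfloored Rubisco solution even though the realised
  `min(Ac, Aj)` is respiratory and negative.)
* **Conductance floor.** When no positive-assimilation solution exists
  (e.g. `Q = 0`), `gs` is pinned at `gmin = 0.01 mol m-2 s-1` and `ci`
  solved from the Fick supply line `A(ci) = gmin (ca - ci) / 1.6`; in
  darkness `ci` exceeds `ca` because the leaf effluxes respiratory CO2.
  Floored solutions still report `E` and `ci`, so downstream metrics see
  no holes. The printed closed form "gs = max{1.6 (ca - ci) A, gmin}" is
  dimensionally inconsistent with Fick's law and is implemented as
  `gs = max(1.6 A / (ca - ci), gmin)`, the unique consistent reading.
* **Root finding.** Brackets are `(ci_comp + 1e-6 ca, ca - 1e-6 ca)`,
  relative `ci` tolerance 1e-10, monotonicity guarded. A-ci fitting uses
  bounded `nlminb` least squares (bounds `Vcmax25` 1–300, `Jmax25` 1–500,
  `Rd25` 0.01–10 on the 25 degC scale), the point-wise `min(Ac, Aj)`
  inside the objective (no manual branch pre-assignment), data-driven
  starts (branch inversion at the ladder extremes) plus three jittered
  restarts under a fixed seed to escape the min() kink.
* **Limitation ties.** `Ac == Aj` is classified Rubisco-limited
  (`<=` in the min rule); a measure-zero convention.
* **Trimming.** "10–90%" trimming discards points outside the
  linear-interpolation (type 7) percentile band, inclusive at both
  bounds, within each group (day or pooled campaign) before the median.
  The long-term characteristic `lambda` is the pooled-point trimmed
  median, not a median of daily medians: the shipped daily table makes
  the two readings differ (the printed overall medians are inconsistent
  with median-of-medians).
* **Estimator validity.** `lambda_point()` classifies the limitation by
  the min rule at the observed `ci` (the field-estimation procedure). A
  single-branch forward solution whose forced branch is not the limiting
  one at its own `ci` is therefore not invertible by the estimator; the
  round-trip guarantee applies to branch-consistent solutions, which is
  every converged combined-form solution.

## What the synthetic generator does and does not emulate

`gen_meteo()` draws drivers uniformly within
`Q` 50–2000 umol m-2 s-1, `Ta` 15–42 degC, `D` 0.5–4.5 kPa, `ca` 380–420
umol mol-1, `P` 94–96 kPa — the envelope of a subtropical growing-season
field campaign at ~550 m altitude — with the default campaign shape of 17
measurement days and the reference per-day counts (1852 records).
`gen_gas_exchange()` runs the forward model at a known `lambda` and
applies mean-one multiplicative log-normal noise (default sd 5%) to `gs`,
re-deriving `A` and `E` through Fick's law at the solved `ci`
(conductance errors scale with magnitude, and instrument flux estimates
inherit them). `gen_aci()` evaluates the FvCB minimum on the 15-step
chamber CO2 ladder (400, 300, 200, 150, 100, 50, 400, 400, 600, 800,
1000, 1200, 1500, 1800, 2000) and takes `ci` equal to the set point.

None of this emulates real instrument behaviour: no chamber leaks or
firmware corrections, no boundary-layer or energy-balance coupling, no
diurnal autocorrelation in the drivers, no `lambda` drift within a day,
and synthetic `ci` is exact rather than inferred from conductance. A
green recovery test therefore establishes that the estimators invert the
package's own forward model under the stated noise — not that field data
of this shape would yield unbiased `lambda` or kinetic parameters.

## Known limitations

* Field-scale accuracy claims (R2, MAE, MBE of the original campaign)
  are out of scope: the raw measurements are not available, so the
  package verifies analytic identities, printed-table reproductions and
  self-consistency instead.
* Sensitivity coefficients use the model's own reference solution as the
  base state; published coefficients referenced an observed field point,
  so magnitudes are not directly comparable (the structural zeros —
  `Jmax25` under Rubisco limitation, `Vcmax25` under RuBP limitation —
  are exact and tested).
* Constant-`lambda` optimality degrades under heat or vapor-pressure
  extremes; the model family carries no hydraulic safety, soil moisture
  or stomatal-lag constraints.
* C4/CAM photosynthesis, finite mesophyll conductance and TPU limitation
  are excluded by design.
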