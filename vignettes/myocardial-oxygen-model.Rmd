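---
title: "Modelling myocardial oxygenation at maximal exercise at altitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling myocardial oxygenation at maximal exercise at altitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoxalt)
```

## The question

Maximal heart rate falls with prolonged altitude exposure, yet no
coronary event has ever been reported in climbers exercising above
8000 m. `myoxalt` implements a closed-form O₂-balance model of the
myocardium that asks: what would myocardial venous oxygenation look like
at maximal exercise if maximal heart rate did *not* fall, and how much
coronary reserve would be needed to make that survivable?

Myocardial venous PO₂ stands in for tissue PO₂ throughout: end-capillary
blood is assumed equilibrated with the tissue, so venous saturation and
pressure are the observable proxies for mitochondrial O₂ supply.

## The balance

Myocardial O₂ consumption equals mechanical power times an energetic
equivalent, and also (Fick) myocardial blood flow times the
arterio-venous O₂ content difference. Taking the ratio of the resulting
heart-rate expressions between maximal exercise in chronic hypoxia (`mh`)
and normoxia (`mn`):

$$
\frac{HR_{mh}}{HR_{mn}} =
\frac{\dot Q_{mh}}{\dot Q_{mn}} \cdot
\frac{Hb_{mh}}{Hb_{mn}} \cdot
\frac{S_{a,mh}-S_{v,mh}}{S_{a,mn}-S_{v,mn}} \cdot
\frac{A_{mh}}{A_{mn}}
$$

$A$ bundles the energetic equivalent, stroke volume and the summed
aortic + pulmonary ejection pressures. The model does not resolve those
terms individually: literature estimates suggest the fall in stroke
volume roughly offsets the rise in pulmonary ejection pressure, so the
$A$-ratio is taken as 1, and measured coronary flow shows little
headroom at maximal exercise, so the $\dot Q$-ratio defaults to 1 as
well. Both remain explicit parameters (`a_ratio`, `q_ratio`) so either
assumption can be relaxed.

Solving for venous saturation with the normoxic anchors
$S_{a,mn} = 98\,\%$, $S_{v,mn} = 30\,\%$ (difference 68 %):

$$
S_{v,mh} = S_{a,mh} - 68 \cdot
\frac{HR_{mh}/HR_{mn}}{(Hb_{mh}/Hb_{mn}) \cdot q \cdot a}
$$

`venous_saturation()` evaluates this directly. Negative results are
physiologically impossible; they are returned unclamped (they carry the
argument of the analysis) with a `feasible` attribute.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `sa_normoxia_pct` | 98 | % | arterial saturation, maximal exercise, sea level |
| `sv_normoxia_pct` | 30 | % | myocardial venous saturation, same conditions |
| `av_diff_normoxia_pct` | 68 | % | their difference; the balance's scale factor |
| `sv_min_pct` | 10 | % | minimal venous saturation compatible with adequate supply |
| `samh_intercept_pct`, `samh_slope_pct_per_m` | 107.6, −0.0066 | %, %/m | arterial-saturation-vs-altitude line |
| `p50_mmHg` | 29.11 | mmHg | dissociation-curve half-saturation pressure |
| `hill_exponent` | 0.3704 | — | dissociation-curve exponent |
| `venous_pH` | 7.32 | — | annotation only; baked into the two constants above |
| `q_ratio`, `a_ratio` | 1, 1 | — | coronary-flow and composite mechanical ratios |
| `hb_ratio_ref` | 1.2 | — | reference Hb ratio for the altitude-limit inversion |

All saturations are percent (0–100), pressures mmHg, altitudes meters;
there is no unit autodetection. The 10 % floor is treated as a sharp
threshold — no tolerance band is defined for it.

## The altitude limit and its constants

Under the no-regulation hypothesis (`HR ratio = 1`), setting
$S_v = 10\,\%$ and substituting the arterial line gives the maximal
tolerable altitude as a function of a percent increase $\Delta Q$ in
coronary reserve:

$$
\text{maxAlt}(\Delta Q) = \frac{107.6 - 10}{0.0066}
- \frac{68 / (1.2 \cdot 0.0066)}{1 + \Delta Q/100}
\approx 14788 - \frac{8586}{1+\Delta Q/100}
$$

A widely quoted closed form of this relation uses a second constant of
8445 instead of 8586, which corresponds to a reference Hb ratio of about
1.22 rather than 1.2 and shifts the zero-reserve limit from 6202 m to
6343 m. The package derives the curve from the parameters
(`hb_ratio_ref = 1.2` by default), because only that choice jointly
reproduces the headline results — 6200 m with no extra reserve, 7600 m
with +20 %, and a 44.5 % required increase for 8848 m. The rounded
closed form stays available via
`max_altitude(..., use_printed_constants = TRUE)`. `required_reserve()`
is the exact algebraic inverse; the two functions round-trip to 1e−6
over $\Delta Q \in [0, 100]$, and altitudes already tolerable return 0
with a `no_reserve_needed` flag rather than a negative reserve.

## The dissociation transform

$PO_2 = 29.11\,(S/(100-S))^{0.3704}$ is singular at $S = 100$, so the
domain is $[0, 100)$ and full saturation raises an error rather than
returning `Inf`; $S = 0$ maps to 0 mmHg. The inverse is closed-form, so
the round trip is exact to 1e−9 across the open interval. No
temperature, pCO₂ or 2,3-DPG corrections are applied: the two constants
already embody a venous pH of 7.32, which is why `venous_pH` is an
annotation rather than an input.

## The literature table and the regression discrepancy

The bundled table (`load_table1()`) transcribes 29 study-altitude
records between 3090 and 8848 m: heart-rate ratio in all rows, arterial
saturation in 17, Hb ratio in 18. Multi-altitude expeditions are split
one row per altitude, since each altitude is an independent model input.
Missing cells are `NA`, never 0 — a zero would be a (wrong) physiological
claim. The free-text `days` column is carried for provenance and never
computed on.

Refitting the arterial-saturation line by ordinary least squares on the
17 usable rows gives intercept 111.1 and slope −0.0070, *not* the
canonical (107.6, −0.0066). Nothing in the available record pins down
the subset, weighting or sea-level anchoring behind the canonical
constants, so the package does not guess: the canonical constants remain
the defaults everywhere downstream (they are what the headline results
require), and `fit_altitude_trend()` exposes the refit as a diagnostic.
The test suite asserts the refit's values against an independent
normal-equations oracle rather than forcing agreement with the defaults.

Scenario rows require heart-rate ratio, saturation and Hb ratio all
measured; no imputation of arterial saturation from the regression line
is performed for study rows, to keep model and data separate. The 13
incomplete rows are excluded and reported with reasons. Venous pressure
is left undefined (`NA`) when saturation is non-positive — a negative
pressure has no meaning under the transform.

## The synthetic generator

`generate_studies()` emulates the structure of the literature table:
altitudes uniform over a range, arterial saturation and heart-rate ratio
linear in altitude with Gaussian noise, Hb ratio uniform, and
missing-at-random cells. Defaults are the study conditions: the
canonical saturation line with noise sd 5 %, and a heart-rate trend
(intercept 1.1124, slope −4.808e−05, noise sd 0.048) taken from the
least-squares fit of the bundled table's heart-rate column. Values are
clipped into the physiological ranges ((30, 100) % and (0.5, 1.1))
rather than resampled; clipping is rare at the default noise levels and
every event is counted in the `n_clipped` attribute, so the
transparency-over-purity trade is auditable. One seed governs all draws
in a fixed order (altitudes, saturation noise, heart-rate noise, Hb,
missingness masks), giving bit-reproducible tables, and the caller's RNG
state is restored afterwards.

What the generator does *not* emulate: between-study methodological
differences, within-study subject variation, acclimatization
time-courses, or any correlation between missingness and altitude.
Passing parameter-recovery tests therefore show the fitting machinery is
unbiased under the stated sampling model — not that the literature data
meet those assumptions.

Recovery checks use tables of n = 200 over 100 seeds (mean recovered
slope within 2 % of truth, 95 % CI coverage within [90 %, 99 %]); the
whole suite runs in a few seconds.

## Numerical choices and edge cases

- The arterial line exceeds 100 % below ~1150 m; `samh_at_altitude()`
  caps at 100 and flags the affected elements (`clipped` attribute)
  instead of silently truncating.
- `max_altitude()` errors when the required arterial saturation exceeds
  the line's intercept (no feasible altitude ≥ 0), which happens only
  for large *decreases* in reserve.
- Altitude-rounding to the nearest 100 m is a reporting convention
  (`round_to_100m`, CLI `--round`); core functions always return full
  precision.
- Validation errors (parameters, generator config, study tables) collect
  every violation before failing, naming rows where applicable.

## Limitations

The model is a steady-state, population-level balance: no uncertainty
propagation (the source studies report none usable), no per-subject
modelling, no separate treatment of stroke volume, ejection pressures or
the energetic equivalent beyond the composite `a_ratio`, and a
dissociation curve frozen at one venous pH. Its outputs are best read as
the *consistency argument* they support — observed heart-rate blunting
keeps computed venous saturation above zero in every literature record,
while a fixed sea-level heart rate would not — rather than as patient- or
expedition-level predictions.
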