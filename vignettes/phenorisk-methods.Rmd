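---
title: "Model and methods in phenorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods in phenorisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

# The problem

Emerald ash borer (EAB, *Agrilus planipennis*) management — trap
deployment, girdled trap trees, timed parasitoid releases, quarantine
planning — depends on knowing when life-cycle events happen at a
location and whether the climate there permits establishment at all.
`phenorisk` couples a cohort-structured degree-day phenology model with
a thermal-stress suitability classifier over gridded daily Tmin/Tmax,
and ships the evaluation machinery (error summaries, equivalence tests,
trend tests) needed to confront predictions with field observations.

# The phenology model

## Thermal time

Development is driven by degree-days computed with the single-triangle
method with an upper horizontal cutoff: the day's temperature course is
idealized as a triangle from Tmin to Tmax and back, and the day's
degree-days are the area of that curve between the lower developmental
threshold (12.2 °C for all EAB stages) and the upper threshold (36 °C).
Heat above the upper threshold contributes nothing (horizontal cutoff),
bounding a single day's contribution by UDT − LDT = 23.8 DDC. A
degenerate day with Tmin = Tmax is treated as constant temperature
(`clamp(T, LDT, UDT) − LDT` if above the LDT), since the triangle
formula would otherwise divide by zero. The closed forms are verified in
the test suite against a 1-minute numerical integration of the
triangular diurnal curve to within 0.02 DDC over 10⁴ random days
spanning −45…50 °C.

Cold and heat stress units use the same triangle geometry — the area
below −31 °C and above 38 °C respectively. No upper cutoff is applied to
heat stress and no daily cap is applied to either accumulation: neither
is parameterized in the species table, so none is invented.

## Life cycle and events

The simulation starts 1 January with the overwintered J-larva (OL) and
assumes a univoltine year. The modeled line advances through
OL → P → A → E → L at cumulative within-stage requirements, each advance
recording one mapped event:

| event | stage completed | requirement (DD) |
|---|---|---|
| pupation | OL | cohort-specific (60–350) |
| adult emergence | pupa | 135 |
| oviposition | adult pre-oviposition | 72 |
| egg hatch | egg | 172 |
| J-larval formation | larva | 700 |

Two conventions deserve note:

* **Oviposition starts the egg stage.** The adult stage duration
  (145 DD, adult longevity) and the egg-laying event offset (72 DD) are
  distinct parameters. The offspring's egg stage begins when eggs are
  laid, not when the parent dies, so the egg-hatch chain runs from the
  oviposition event. At a constant 22.2 °C (exactly 10 DD/day) the
  cumulative event thresholds are therefore 200 / 335 / 407 / 579 / 1279
  for a 200-DD cohort, giving event days 20 / 34 / 41 / 58 / 128 — the
  package's hand-checkable arithmetic anchor. Adult longevity is still
  used for adult stage-presence summaries in `stage_snapshot()`.
* **Transition-day carryover.** Degree-days in excess of a requirement
  on the day it is met are credited to the next stage; otherwise every
  stage would lag by up to a day, biasing late-season events by several
  days in aggregate. Several transitions may fall on a single day.
* **Event day convention.** Events are recorded at integer day-of-year
  (1 Jan = 1), the first day the cumulative requirement is met; no
  sub-daily interpolation.

After J-larval formation the obligate diapause stops the trajectory — no
second generation, matching the single-year model structure. No
low-temperature diapause-completion requirement is imposed on J-larvae;
a within-winter chilling requirement cannot be represented in a
single-calendar-year simulation and is a known limitation (see below).

When all stages share one LDT/UDT pair (true for the packaged EAB
values) the engine uses an exact shortcut: events fall where the annual
cumulative degree-day curve crosses the summed requirements. The general
per-stage daily machine remains for stage-specific thresholds, and the
suite asserts both paths agree.

## Cohorts

Spring emergence at a site is spread over weeks. This is modeled by
seven cohorts whose J-larval completion requirements partition a
lognormal distribution with arithmetic mean 200 DDC and variance
15000 DDC² (log-space σ² = ln(1 + var/mean²), μ = ln(mean) − σ²/2),
truncated to [60, 350]. The truncated range is cut into seven
**equal-width** bins; cohort weight = the bin's (renormalized)
probability mass, cohort requirement = the density-weighted bin mean.
Equal-width binning with density-weighted representatives was chosen
because it reproduces the published 217–460 DDC adult-emergence window
(this package computes 218 and 463); equal-probability binning does not,
which was checked before freezing the design. `distro_var` is read as
the variance on the natural degree-day scale — 15000 against a mean of
200 is only sensible there.

Peak (50%) adult emergence is the weighted median: the earliest day by
which cohorts holding at least half the population weight have emerged.
`calibrate_cohort_params()` scores candidate (xdist1, mean, xdist2,
variance) tuples by the combined MAE of first and peak emergence over
site-years and returns them ranked; the suite verifies it recovers a
generating candidate planted among perturbed ones.

# The suitability model

Cold and heat stress units accumulate every day of the calendar year,
independent of life stage, and the year totals are classified per cell:
0 (no exclusion) up to the moderate limit, −1 above it, −2 above the
severe limit (cold 80/160, heat 75/150 units). **Boundary behavior is
strict**: a total exactly at a limit is not excluded — the source
material says limits "delimit" exclusion without fixing the boundary, so
the lenient reading was chosen and is pinned by tests (80 → class 0,
80.01 → −1). The combined class is the worse of the two, and class-0
cells constitute the potential distribution. Moderate exclusion is read
as "long-term establishment unlikely, favorable-year persistence
possible"; severe as "even one-year persistence unlikely" —
`presence_sensitivity()` therefore offers both the strict
(`both-levels`) and conservative (`severe-only`) inclusion rules.
`multi_year_agreement()` counts, per cell, years included in the
potential distribution. A `consecutive_days_below()` helper supports
exploring cold spells; it plays no role in classification, whose
thresholds enter as constants.

# Evaluation statistics

`error_summary()` reports MAE, bias (predicted − observed; negative =
too early), the sample (n−1) standard deviation — the source tables do
not state the denominator, and the sample SD is the defensible default —
and the error range.

`tost_equivalence()` implements the two-one-sided-tests procedure in the
Welch two-sample form (the reference analysis states unequal variances
*between groups*, so the unpaired formulation is the default; a paired
option is exposed). Equivalence at half-width δ is declared when both
one-sided 95% bounds `d̄ ∓ t₀.₉₅,df·SE` lie strictly inside (−δ, δ);
this is identical to max(p₁, p₂) < 0.05, which the suite verifies on
1000 random datasets, and the joint interval is equivalently a two-sided
90% CI — reported here in the one-sided framing. Default δ of 7 and
14 days mirror the reference analysis.

`mann_kendall()` is hand-implemented (no trend package in the dependency
set): tie-corrected variance, tau-b effect size (exclusion-class series
are heavily tied), ±1 continuity-corrected normal z, two-sided p,
significance at p ≤ 0.1. Exact-distribution p-values for very short
series are deliberately not implemented — the mapped use case is 20-year
stacks, where the normal approximation is standard. `trend_map()` masks
pixels with any missing year and, for class stacks, negates values so a
downward trend means relaxing stress; pixels with S = 0 get the explicit
no-trend label.

# Synthetic weather: what it does and does not emulate

`synth_weather()` generates one calendar year of daily Tmin/Tmax:

    Tmean(row, d) = base − gradient·(row − 1)
                    + amplitude·cos(2π(d − peak_day)/365) + ε,
    ε ~ N(0, noise_sd²),  Tmin/Tmax = Tmean ∓ diurnal_range/2

Defaults (base 10 °C, amplitude 14 °C peaking day 201, diurnal range
10 °C, noise SD 3 °C, 20 × 20 grid) describe a generic mid-latitude
temperate year: annual means around 10 °C, July means in the mid-20s,
day-to-day synoptic noise of a few degrees. These values were fixed once
as field-plausible and are not tuned to any test outcome. Noise is added
to the daily mean before the diurnal split, so Tmin ≤ Tmax always holds;
a positive per-row gradient cools cells with increasing row index (row 1
is the northernmost row — sign conventions are the user's choice). Leap
years carry 366 layers while the seasonal term keeps period 365; the
discrepancy is negligible at daily resolution.

What it does **not** emulate: spatial noise correlation, autocorrelated
cold spells and heat waves, asymmetric diurnal cycles, elevation,
coastlines, or missing-data structure of real products. A green property
suite on synthetic weather therefore establishes internal correctness
(orderings, monotonicities, conservation, calibration recovery) — not
real-world predictive skill, which requires the user's own climate data
through `read_daily_grids()` and observation files through
`run_validation()`. The published real-data error levels (MAE 3.7–13.7
days across events; 99.9% presence sensitivity) are reproducible with
those commands given the external datasets, and are deliberately not
asserted by tests here.

# Numerical and I/O choices

* Tolerances: stage-advance comparisons use a 1e-9 DDC slack so exact
  threshold hits (constant-temperature arithmetic) are not lost to
  floating-point error; cohort weights must sum to 1 within 1e-9;
  lognormal bin means use adaptive quadrature at rel.tol 1e-10.
* Missing data: any cell missing ≥1 day is masked from all outputs
  (phenology, stress, trends), separately from the
  insufficient-accumulation flag of warm-season shortfall.
* Cell lookup is half-open — [x, x + dx) × (y − dy, y] — so every point
  belongs to exactly one cell: a shared vertical edge to the cell whose
  west edge it is, a shared horizontal edge to the cell whose top it is.
* Rasters are exchanged as plain-text ESRI ASCII grids (and a stacked
  daily variant with `nbands`/`band_dates` header lines), chosen over
  GeoTIFF/NetCDF so the package runs with zero system raster
  dependencies; round-trips are exact at 15 significant digits. The CRS
  is carried as an uninterpreted label — no reprojection is offered, and
  inputs must be co-registered.
* Runs are deterministic given config + seed; the provenance JSON
  (parameters, cohort table, seed, input checksums) suffices to
  reproduce a run bit-identically, which the suite asserts.

# Known limitations

* Univoltine only: the two-year (semivoltine) cycle of cool-climate or
  low-density populations is outside the single-year structure.
* No chilling requirement for diapause completion, no under-bark
  microclimate correction, no host-tree condition effects, and constant
  (non-plastic) cold tolerance across the range.
* Stress thresholds/limits are constants; deriving them from presence
  climatologies is an upstream analysis, not a package feature.
* Mann-Kendall is applied without pre-whitening; serially correlated
  series can inflate significance.
* Host (*Fraxinus*) range overlays and city-polygon averaging of
  imprecise records are cartographic/data-cleaning steps left to the
  user.
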