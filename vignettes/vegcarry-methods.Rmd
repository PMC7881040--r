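---
title: "Quantifying vegetation growth carryover: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vegetation growth carryover: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcarry)
```

`vegcarry` estimates how much of the interannual variation and multi-year
trend of seasonal vegetation growth is inherited from the preceding season
or year (vegetation growth carryover, VGC) rather than forced by climate.
This vignette explains the statistical model behind each stage, the
parameters a user can turn, the synthetic systems used for validation, and
the design decisions taken where more than one defensible choice existed.

## 1. Data model

Everything moves through long-format data frames: biweekly series
(`cell_id`, `year`, `period` 1–24), monthly fields (`…, month, variable,
value`) and seasonal fields (`…, season, variable, value`). Composite
periods `2k − 1` and `2k` belong to month `k`. Cells are opaque
identifiers with optional latitude; no grid resolution is assumed.
Area weights default to the cosine of latitude, and every aggregation is
invariant to uniform weight rescaling. Missing data follow listwise
deletion over the years where *all* variables entering a statistic are
present, so sample sizes are identical across drivers within one test.

## 2. Season delineation

The climatological biweekly cycle (per-period multi-year mean, at least
two years per period) is interpolated to daily resolution with a cubic
spline fit over three concatenated annual cycles, which keeps the
derivative continuous across the calendar boundary. SOS and EOS are the
days of the largest and smallest first difference of the daily curve. A
cycle whose range falls below `min_amplitude` (default 0.05 index units)
is declared undetectable. The interpolation method is a package choice:
any smooth interpolant would do, but a spline gives a well-defined slope
everywhere, and on noise-free double-logistic curves the detected dates
sit within ~2 days of the true slope extrema — comfortably inside the
±8 day half-composite resolution bound the tests enforce.

Month assignment follows fixed rules: the peak growing season (PGS) is the
two consecutive months with the largest summed climatological index,
restricted to April–October, ties broken toward the earlier pair; with a
growing season of three months or fewer, PGS is the single maximum month.
Cells whose maximum-index month falls outside April–October are excluded,
as are cells whose growing-season maximum is below 0.1 index units
(non-vegetated; the threshold is ours, chosen at the conventional
sparse-vegetation cutoff). EGS runs from the SOS month to the month before
PGS, LGS from the month after PGS to the EOS month, and the remaining
months form the dormancy season (DS). Every emitted window is validated to
partition the twelve months with EGS < PGS < LGS.

**Dormancy-season year attachment.** DS spans the calendar boundary;
we attach it to the year whose EGS it precedes (months after EOS come from
year *t − 1*, months before SOS from year *t*). This makes the DS-to-EGS
legacy well defined: the dormancy climate controlling an early season is
always the winter immediately before it.

For daily site productivity the detector uses the second derivative of a
`smooth.spline` fit (`spar = 0.6` by default; smooth enough to suppress
synoptic noise without flattening the seasonal transitions — the value is
exposed because no single setting suits all series). SOS is the maximum of
the second derivative before the seasonal peak (accelerating growth), EOS
the minimum after it (onset of decline). Sites missing more than 20 % of
days are excluded.

## 3. Carryover statistics

The central quantity is the partial correlation of the seasonal vegetation
series with one driver while controlling the rest. Five drivers enter per
season: preceding-season vegetation (for EGS this is the *previous year's*
LGS; its preceding climate is the dormancy season), concurrent temperature
and precipitation, and preceding-season temperature and precipitation;
each driver's coefficient controls the other four. Two implementations are
kept deliberately: residualization (correlate the OLS residuals of both
variables on the controls) and the precision-matrix identity
r = −P₁₂/√(P₁₁P₂₂). They agree to 10⁻¹⁰ on random instances, and the test
suite asserts it; the residual route is the one used in pipelines.
Significance uses a two-sided *t* test with *n* − 2 − *k* degrees of
freedom — the simplest correct choice for a single coefficient, adopted
because the analysis framework only requires per-cell 95 % decisions.
Degenerate cases (a variable numerically constant after residualization,
tolerance 10⁻¹² relative) are flagged undefined rather than given a
number; an undefined driver does not poison the others.

At the annual scale, `lagged_pacf()` measures persistence unique to each
lead: lead 1 controls temperature and precipitation of the present and
preceding year; lead *j* additionally controls the series at leads
1…*j* − 1. All series are linearly detrended first (this keeps
satellite-index series comparable with standardized tree-ring indices,
whose construction already removes low-frequency trends); for the seasonal
profiles detrending is a flag, since both raw and anomaly variants are
meaningful. The climate controls for tree-ring series default to annual
means — the aggregation is configurable because growing-season means are
an equally defensible convention.

A caveat worth knowing: the lead-1 estimate carries the usual downward
finite-sample bias of autocorrelation estimators. With φ = 0.4, *n* = 100
and five controls, the median estimate sits near 0.37, not 0.40; the
acceptance checks account for this by testing within ±0.05.

## 4. Trend attribution

Sensitivities β come from one joint OLS regression of the seasonal series
on all five drivers; each driver's contribution to the observed trend is
β·(its own trend), lagged and concurrent climate pairs are summed, and the
residual term is the closure remainder. Because both the regression and
the least-squares trend operator are linear, the remainder equals the
trend of the regression residuals exactly — the package asserts the
identity both ways, and the closure error on synthetic cells is at machine
precision (≤10⁻¹²). Rank-deficient designs are flagged and excluded from
maps rather than silently pseudo-inverted. Percentage shares are reported
signed (opposing terms can push a share below 0 or above 100), relative to
the observed total trend by default; a flag switches the denominator to
the explained trend, since either convention is found in practice.

## 5. Tree-ring standardization

Ring-width series are standardized by a cubic smoothing spline with a 50 %
frequency-response cutoff at two-thirds of the series length (the
dendrochronological convention), implemented as a discrete
second-difference-penalty smoother whose penalty λ = (2 − 2cos(2π/nyrs))⁻²
gives exactly that cutoff for evenly spaced annual data. The index is the
ratio raw/fitted, so multiplying a series by a constant changes nothing;
a fit that goes nonpositive excludes the series. Series shorter than 25
years or containing gaps are excluded with reasons. Site chronologies are
Tukey biweight means (tuning constant 9 × MAD, iterated to convergence;
zero MAD falls back to the median) with per-year sample depth, missing
below a minimum depth of 2.

Two limitations are inherent and documented rather than hidden. First, the
stiff 67 % spline under-tracks steep juvenile growth: at the simulator's
default age trend (1.0·e^(−0.02·t) + 0.6 mm over 100 years) the noise-free
index deviates from 1 by at most ~2 %, but the deviation grows with the
decay rate and the series length (the cutoff wavelength scales with *n*).
Second, the biweight's robustness is the point of criterion-style checks:
19 unit series plus one 10× outlier yield a chronology within 0.02 of 1
where the arithmetic mean sits at 1.45.

## 6. Dominance classification

Each cell's profile collapses to three family scores: |r_p| of the
carryover driver, and for each climate family the maximum of its two
members' |r_p| (a root-sum-of-squares alternative is provided; the max is
the default because a family should win on the strength of its strongest
member, not its breadth). The label is the argmax; exact ties fall to the
fixed priority carryover > concurrent > preceding and are flagged.
Classification is invariant to common rescaling of all scores. An
alternative mode scores |trend contribution| from the attribution stage
instead of |r_p|.

One subtlety: a *perfectly* noise-free linear response saturates every
mutually-controlled partial correlation at ±1 and leaves dominance
undefined. Designed-recovery checks therefore give the dominant driver a
unit effect over a weak innovation floor (SD 0.25), under which labels are
recovered exactly.

## 7. Recursive path model

The vegetation–climate–soil network is declared as a DAG of observed
variables (cycles are rejected by a topological sort, naming the
offenders). All variables are standardized and each endogenous node is fit
by least squares on its parents, so coefficients are standardized partial
regression weights with per-equation *t*-test p-values. For recursive
models of observed variables these point estimates coincide with the
full-information maximum-likelihood ones; what is *not* reproduced are
likelihood-based fit indices (χ², RMSEA, AGFI) — in their place the
package reports the maximum absolute gap between the observed and the
model-implied correlation matrix, built by path-tracing in topological
order. Direct/indirect/total effects come from exhaustive path
enumeration, and total = direct + indirect holds to machine precision by
construction. The soil-moisture/vegetation edge is oriented by the sign of
their correlation — positive means moisture stimulates growth, negative
means growth depletes moisture — with a dead zone (default |r| < 0.05)
left undetermined. Whether observations are cells, years, or site-years is
the caller's framing; the fit records only *n*.

## 8. What the synthetic generators emulate — and what they do not

`simulate_biweekly_ndvi()` draws a double-logistic seasonal curve (the
standard smooth unimodal phenology model; defaults: baseline 0.15,
amplitude 0.55, green-up midpoint day 130, senescence day 280) sampled at
24 composites, with additive per-year anomalies (SD 0.02) and an optional
trend, and records the exact slope extrema of the noise-free curve as
ground truth.

`simulate_seasonal_system()` is the generative counterpart of the
carryover model: seasons are generated in order DS → EGS → PGS → LGS with
NDVI_s = γ·NDVI_{s−1} + β_T·TMP + β_P·PRE + lagged-climate terms + ε, EGS
chained to the previous LGS, and a soil-moisture state SM = a·SM_prev −
b·NDVI + c·PRE + η carried across seasons. Defaults describe a 35-year,
100-cell record with carryover 0.3–0.5 per transition, β_T = 0.02
index/°C, β_P = 0.001 index/mm, 0.3 °C/decade warming, and index noise
SD 0.03 — magnitudes a northern-hemisphere analyst would call moderate.
Ten burn-in years are discarded so recorded anomalies are stationary
(|γ| < 1 enforced). Dormancy-season vegetation is deliberately not
generated: dormant vegetation carries no usable index signal.

`simulate_annual_ar()` and `simulate_ring_widths()` provide the annual
fixtures: AR(1) anomalies with known φ, and widths = ageTrend × (1 +
common AR(1) signal + tree noise), positively clipped, with an optional
outlier tree.

What the generators do **not** emulate: sensor artifacts (orbital drift,
snow contamination), spatially correlated climate fields, non-Gaussian
precipitation, disturbance and recovery dynamics, or age-dependent climate
sensitivity in trees. Passing the recovery tests therefore demonstrates
that the estimators are correct and well-calibrated under the stated
model, not that real AVHRR or ITRDB data satisfy that model.

## 9. Validation sizes and determinism

Every generator is bit-reproducible given (config, seed) and stores the
truth needed to score its estimators. The shipped checks use: 100 cells
for decomposition closure, 1000 random instances for the dual
partial-correlation routes, 10⁴ null cells × 35 years for the empirical
type-I error (0.05 ± 0.01 band), 500 cells against a 10⁶-draw population
oracle for carryover recovery, 200 replicates of 100-year AR(1) series for
the lead-1..3 medians, ten noise-free phenology curves, and 10⁴
observations for path-coefficient recovery — sizes chosen so the whole
suite validates the estimators' operating regime in a few tens of seconds
on one CPU.
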