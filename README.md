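# vegcarry

Tools for quantifying **vegetation growth carryover (VGC)** — the legacy of
a preceding season's (or year's) vegetation state on subsequent growth —
and for separating it from the immediate and lagged effects of climate.

## The problem

Interannual variations of northern vegetation growth are usually explained
by concurrent climate. But the land surface has memory: a productive early
growing season leaves more leaf area, reserves, and altered soil moisture
behind, and those legacies shape the peak and late growing seasons, and
even the following year. Quantifying that biological carryover — and
deciding where it, rather than climate, dominates interannual variation —
requires statistics that control for the covarying climate signal at every
step. `vegcarry` packages that machinery for gridded vegetation-index
fields, site productivity records, and tree-ring chronologies, together
with synthetic-data generators so every estimator can be validated against
a known ground truth.

## Core statistics

**Season delineation.** Each cell's year is split into early (EGS), peak
(PGS), late growing season (LGS) and dormancy (DS) from its own
climatological cycle: SOS/EOS are the days of fastest green-up/senescence
of the spline-interpolated biweekly cycle; PGS is the two consecutive
months (April–October) with the largest summed index, one month when the
growing season spans three months or fewer.

**Carryover profiles.** For a target season, the partial correlation of
the vegetation index *Y* with each of five drivers — *Y*<sub>ps</sub>
(preceding-season vegetation), TMP, PRE (concurrent climate), and
TMP<sub>ps</sub>, PRE<sub>ps</sub> — each controlling the other four. At
the annual scale, lead-*j* partial autocorrelations control climate of the
present and preceding year plus the series at all smaller leads.

**Trend attribution.** The multi-year linear trend of seasonal growth is
decomposed exactly into

dY/dt = (∂Y/∂Y_ps)(dY_ps/dt) + (∂Y/∂TMP_ps)(dTMP_ps/dt) +
(∂Y/∂PRE_ps)(dPRE_ps/dt) + (∂Y/∂TMP)(dTMP/dt) + (∂Y/∂PRE)(dPRE/dt) + ε

with sensitivities from a joint multiple regression, temperature and
precipitation combined into lagged and concurrent climate terms, and ε the
closure remainder (identically the trend of the regression residuals).

**Tree rings.** Raw ring widths (Tucson/RWL or CSV) are standardized with
a cubic smoothing spline (50 % frequency cutoff at two-thirds of the
series length), averaged into site chronologies with a Tukey biweight
robust mean, and fed through the same lagged partial-autocorrelation
analysis, optionally grouped by wood porosity.

**Dominance maps and path models.** Cells are labeled by their strongest
driver family (carryover, concurrent climate, preceding climate), with
area-fraction summaries for observation–model comparison; a recursive path
model (equation-wise least squares on standardized variables) decomposes
direct and indirect vegetation–climate–soil pathways, with the
soil-moisture/vegetation edge oriented by the sign of their correlation.

## Worked example

```r
library(vegcarry)
cfg <- seasonal_system_config(n_cells = 200, n_years = 35, seed = 42)
fld <- simulate_seasonal_system(cfg)   # chained NDVI/TMP/PRE/SM field

prof <- seasonal_vgc_profile(fld, season = "PGS")
sign_frequency_summary(prof[prof$role == "carryover", ])
#>   group   n n_undefined pct_positive pct_negative pct_sig_positive pct_sig_negative
#> 1   all 200           0          100            0               86                0

res <- attribute_seasonal_trends(fld, "PGS")
summarize_contributions(res)$shares
#> carryover    clm_ps       clm  residual
#> 40.182214 11.608277 43.950117  4.259392

area_fractions(classify_dominant_driver(prof))
#>                VGC concurrent_climate  preceding_climate
#>               0.22               0.77               0.01
```

With the default generating parameters (EGS→PGS carryover 0.5, temperature
sensitivity 0.02 index/°C, 0.3 °C/decade warming) every simulated cell
shows a positive peak-season carryover coefficient (86 % individually
significant), and the decomposition attributes the greening trend about
40 % to carryover and 44 % to concurrent climate — the designed behavior
of the synthetic system.

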