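---
title: "Multi-hazard extreme-event exposure: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-hazard extreme-event exposure: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazexposure)
```

## The analysis in one paragraph

`hazexposure` quantifies how strongly species geographic ranges and
ecoregions are exposed to four types of extreme climate events — heatwaves,
soil-moisture droughts, river floods and wildfires — in gridded output from
climate-impact model ensembles. "Extreme" is always defined *locally*:
each grid cell is compared against the distribution of a long, stationary
pre-industrial control simulation for that same cell, so the method measures
departures from local historical variability rather than absolute
thresholds. Cell-year event flags are reduced to event frequencies over
30-year windows, combined into multi-hazard counts, and aggregated over
range masks with area and overlap weights to give a single exposure
proportion per species or ecoregion, with ensemble minimum/mean/maximum
across climate model × impact model combinations.

## Event definitions

All four classifiers calibrate on the full supplied control run and flag by
*strict* exceedance (ties never flag).

**Heatwaves** use a two-step definition built on the daily heatwave
magnitude index (HWMId). Step one identifies heatwave periods: runs of at
least 3 consecutive days on which daily maximum temperature exceeds the
90th percentile of control temperatures for that day of year, pooled over a
centred 31-day window (wrapping across the December–January boundary).
Step two scores each period: a day at temperature $T_d$ contributes a
magnitude

$$M_d = \frac{T_d - Q_{25}}{Q_{75} - Q_{25}} \quad \text{if } T_d > Q_{25},
\qquad M_d = 0 \text{ otherwise},$$

where $Q_{25}$ and $Q_{75}$ are quartiles of the control run's *annual
maximum* temperature series — i.e. severity is measured in units of the
local interannual spread of annual extremes. A period's magnitude is the
sum of its daily magnitudes, the annual HWMId is the maximum over periods
(0 with no period), and a cell-year is an extreme heatwave year when the
annual HWMId exceeds the 97.5th percentile of the control HWMId
distribution for that cell. Heatwave periods are never stitched across the
year boundary; short events split across December–January can be missed,
which biases all periods (control and scenario) equally and therefore
biases exposure *downward*, not upward. Cells where $Q_{75} = Q_{25}$ have
no meaningful magnitude scale and are flagged unusable (`NA`).

**Droughts** operate on monthly root-zone soil moisture, reflecting the
slower dynamics of soil water. A cell-year is a drought year when soil
moisture stays below the 2.5th percentile of the pooled control months for
3 or more consecutive months within the calendar year. Two conventions
were genuinely open:

* *Pooling*: the level is computed from all control months pooled, not per
  calendar month — the defining criterion is "below the 2.5th percentile of
  the control simulation", without seasonal stratification. A per-calendar-
  month mode is available (`per_month_drought = TRUE` in
  `calibrate_thresholds()`) for users who want seasonality-relative
  droughts.
* *Run attribution*: runs are evaluated within calendar years only; a
  November–February spell counts toward neither year unless at least three
  of its months fall in one year. This matches the convention of flagging
  droughts "in a given year" and keeps the classifier invariant to
  relabelling years.

**River floods** fit a generalized extreme value (GEV) distribution to the
annual maxima of daily outflow from the control run, per cell. A T-year
return level is the GEV quantile at non-exceedance probability $1 - 1/T$;
the default 40-year return period is therefore exactly the 97.5th
percentile of the annual-maximum distribution, keeping the flood definition
on the same probability scale as the other events. A cell-year floods when
its annual maximum outflow exceeds that level *and* at least 1% of the cell
area is flooded that year (the flooded-area fraction is taken as an input
field, evaluated per year; a static exclusion can be achieved by passing a
per-cell mask through the `dryness_mask` argument) *and* the cell passes
the dryness mask. The dryness mask removes cells with annual mean
discharge below 0.1 mm/day (the boundary value is retained) from both
flood and drought classification, since percentile thresholds are
meaningless where there is essentially no water.

**Wildfires** compare annual burned-area fractions against the 97.5th
percentile of the control's annual burned area, per cell.

### Percentile sensitivity

A single upper-tail percentile $q$ (default 97.5) drives all four
definitions: droughts mirror it to $100 - q$ and floods use the return
period $100/(100-q)$ years. `run_sensitivity()` re-derives the levels at
$q \in \{95, 97.5, 99\}$ from the stored control metrics without
re-running the expensive calibration; because the flagged sets are nested,
event counts are non-increasing in $q$ — a property the test suite checks
cell by cell.

## Numerical choices

* Percentiles are empirical type-7 quantiles (R's default), evaluated with
  a C++ selection kernel for the 365-day windowed calibration because the
  day-of-year windows overlap heavily.
* GEV fitting is maximum likelihood (Nelder–Mead) started from Hosking
  L-moment estimates; the shape parameter is restricted to $(-0.5, 0.5)$
  for numerical stability, non-convergent fits fall back to the L-moment
  estimate with a warning, and cells with constant annual maxima are
  flagged unusable rather than fitted.
* Frequency-threshold comparisons are done on *counts*: $k$ flagged years
  out of $w$ qualifies at threshold $t$ iff $k \ge t\,w - \varepsilon$
  with a conservative $\varepsilon = 10^{-9}$, so 10 of 30 years
  ($0.3\overline{3}$) qualifies at 0.33 regardless of floating-point
  representation.
* Cell areas use the exact spherical band formula
  $A = R^2\,\Delta\lambda\,(\sin\varphi_2 - \sin\varphi_1)$ with
  $R = 6371$ km — exact, latitude-only, and telescoping to $4\pi R^2$ over
  a full sphere. The cosine-latitude rule is recovered exactly
  ($A(0°)/A(60°) = 2$).
* Rasterization of polygons is analytic Sutherland–Hodgman clipping
  against half-open cell rectangles
  $[\text{centre} - \tfrac{res}{2}, \text{centre} + \tfrac{res}{2})$ in
  longitude–latitude space; geometries wrapping the antimeridian are not
  supported, and pre-tabulated fraction tables are accepted directly.
  Seasonal range polygons are assumed unioned into a single geometry per
  species before rasterization.

## Windows, ensembles and exposure

Event frequency is the number of flagged years in a 30-year window divided
by 30; the baseline window is fixed to the 30 years centred on 2000
(1985–2014) regardless of scenario, and future windows are centred between
2030 and 2085. Change is future minus baseline frequency.

Exposure of an entity (species range or ecoregion) with overlap fractions
$o_i$, cell areas $a_i$ and cell frequencies $f_i$ is

$$E = \frac{\sum_i f_i\, a_i\, o_i}{\sum_i a_i\, o_i} \in [0, 1],$$

over land cells only. Weighting by frequency follows the reading of
"weighted by how often it was exposed" as a multiplicative factor; an
unweighted any-event variant is obtained by passing the indicator
$f_i > 0$ to `entity_exposure()`. Entities with zero overlap-weighted
land area (e.g. small-island species the grid does not resolve) are
excluded up front by `filter_unrepresented()`. Because the weights are a
proper weighted mean, ecoregion exposures aggregated over an ecoregion
partition reconstruct the global land-mean frequency exactly — a
conservation property tested to $10^{-9}$ relative tolerance.

Two ensemble-order decisions matter and were made deliberately:

* Exposure is computed *per combination* and the ensemble mean/min/max is
  taken across combinations, so the reported ensemble range brackets
  exposures an actual model combination produced. (Averaging frequency
  fields first and then computing exposure is the convention for mapped
  mean-frequency figures; `ensemble_stats()` supports both orders.)
* Multi-hazard counts are computed per combination and then summarised;
  thresholding an ensemble-mean field and averaging thresholded fields
  differ, and the per-combination route preserves the min–max contract.
* Counts of entities above an exposure cutoff (e.g. at least 50% of range
  exposed) use ensemble-mean exposure; since the table carries `ens_min`
  and `ens_max` per entity, per-combination bounds on those counts can be
  derived from the same output.

## The synthetic-forcing generator

Real inputs to this kind of analysis are multi-model archives that cannot
ship with a package, so every pipeline stage runs against a seeded
generator that emulates their statistical structure:

* daily maximum temperature: latitude-dependent mean (28 °C at the equator
  minus 0.4 °C per degree of latitude) plus a seasonal sine (amplitude
  3 °C + 0.15 °C per degree of latitude, peaking mid-July/mid-January by
  hemisphere) plus AR(1) noise with lag-1 autocorrelation 0.7 and marginal
  sd 3 °C — the autocorrelation produces realistic multi-day heat spells
  that stress the run-detection logic;
* monthly soil moisture: a logistic transform of an AR(1) process
  (autocorrelation 0.5), bounded in [0, 1] by construction with
  multi-month persistence;
* daily outflow: lognormal with a seasonal cycle and autocorrelated log
  noise; annual burned area: gamma-distributed fractions (mean 2% of the
  cell); annual flooded fraction: beta(2, 18); annual mean discharge: a
  wet/dry cell map (1 vs 0.05 mm/day, 10% dry cells) that exercises the
  dryness mask;
* scenario runs add deterministic trends (°C per decade warming,
  fractional drying, multiplicative flow/burn scaling) to the *identical*
  stationary noise, so a zero-trend scenario is bit-identical to the
  control under the same seed — the cleanest possible null;
* each of the `n_climate` × `n_impact` pseudo-ensemble members gets its own
  derived seed and mildly perturbed noise/seasonality parameters, so
  members differ in structure, not just realisation;
* species ranges are contiguous random blobs with fractional cell overlaps
  (a configurable number placed entirely off-land to exercise island
  exclusion), and ecoregions are a nearest-seed partition of the land
  cells.

Every stochastic draw flows through one derived substream per (variable,
combination), so regenerating one variable never shifts another. The
calendar is 365-day no-leap throughout.

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: spatial correlation of weather across cells
(noise is independent per cell), physically consistent hydrology or fire
behaviour (outflow, soil moisture and burned area are statistically
independent of temperature), the variance structure of actual CMIP6/ISIMIP
ensembles, leap calendars, and coastline-accurate land masks. The package
validates the *method* — calibration, classification, aggregation,
weighting — not any claim about real-world exposure magnitudes.

## Problem sizes used by the test suite

The suite favours the smallest sizes at which each property is
informative: calibration-rate checks use 2,000-year controls on 20×20
cells for annual metrics and 4×4/6×6 cells for daily metrics (the
flagged-rate property is per cell-year, so statistical power comes from
years, not cells); the trend-response check runs the full 5×3
pseudo-ensemble on a 20×20 grid with a 100-year control and a 1985–2100
scenario at three warming rates; oracle-equivalence checks use 1,000
random series and a Gumbel sample of 10,000. The default desk-scale
configuration of `run_pipeline()` (20×20 grid, 100-year control, 5×3
ensemble, 200 species, 12 ecoregions) completes in a few minutes on one
CPU.

## Known limitations

* Exposure is not impact: sensitivity and adaptive capacity are outside
  scope, and frequency does not capture intensity or duration changes that
  can matter biologically.
* Gridded artifacts are serialized as plain-text CSV with a metadata
  header rather than NetCDF; the format is exact and self-describing but
  not CF-conventional.
* Polygons crossing the antimeridian, self-intersection detection, and
  sub-annual event timing are unsupported.
* The fire classifier inherits whatever its input field resolves; extreme
  "megafire" behaviour beyond the input's statistics is not represented.

## A minimal run

```{r pipeline, eval = FALSE}
cfg <- list(seed = 42,
            grid = list(lat0 = 30.25, lon0 = 10.25, nlat = 8, nlon = 8,
                        resolution = 0.5, land_fraction = 0.7),
            control_years = 60, centers = c(2050, 2085),
            ensemble = list(n_climate = 2, n_impact = 2),
            species = list(n = 30, n_offland = 2, size_min = 1, size_max = 12),
            ecoregions = list(n = 4))
res <- run_pipeline(cfg)
subset(res$summary$mean_exposure,
       window_center == 2085 & entity_kind == "species")
```
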