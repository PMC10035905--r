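---
title: "Methods: a simplified crop-climate sensitivity pipeline for Proso millet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simplified crop-climate sensitivity pipeline for Proso millet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosoclim)
```

This vignette is the package's own account of its science: the model
structure, the parameters that matter and why they have the defaults they
have, what the synthetic weather does and does not emulate, and the
numerical and design choices a maintainer would want written down.

## The problem

Proso millet (*Panicum miliaceum*) is a ~70-day, drought-tolerant C4 cereal
grown rainfed in a tropical dry-zone environment with a bimodal monsoon:
the major rains fall in October–December, and the crop occupies a minor
rainy season, sown around 15 March and harvested by mid-June. The pipeline
quantifies (i) yield sensitivity to joint temperature/rainfall anomalies,
(ii) yield under mid-century (2040–2069) climate signals from a 20-model
CMIP5 ensemble under RCP4.5 and RCP8.5, and (iii) spatial yield potential
over an island-scale grid.

## Crop model

The simulator is a deliberately compact, single-bucket reconstruction of
the APSIM-millet model family: daily time step, eleven stages (sowing,
germination, emergence, end of juvenile, floral initiation, flag leaf,
flowering, start grain fill, end grain fill, maturity, harvest ripe).
Sowing→germination is controlled by soil moisture (germination requires
available water above 15 % of capacity); every later phase is exited when
its thermal-time target is met.

**Thermal time.** A triangular response with cardinal temperatures
10/30/45 °C: 0 °Cd at 10 °C, rising to 20 °Cd at 30 °C, falling to 0 at
45 °C. The default evaluates the response at the daily mean temperature; a
`diurnal-8pt` mode averages over eight standard within-day interpolation
temperatures, which matters above the optimum (e.g. at the +8 °C corner of
the sensitivity design, where afternoons overshoot 45 °C).

**Phase targets.** Emergence→end-juvenile, flag-leaf→flowering,
flowering→start-grain-fill and maturity→harvest-ripe come from the shipped
per-accession genotype table. The floral-induction phase uses a short-day
response, `112.4 °Cd × max(0, daylength − 11.5 h)` — millet is a short-day
plant, but the functional form and the 11.5 h base are package choices;
only the slope is an accession coefficient. Grain fill is allocated
`TT(flowering→maturity) − TT(flowering→start grain fill)`, which makes end
of grain fill and maturity coincident; the genotype table offers no
separate target for the last filling phase, so this allocation is the
parsimonious closure. Germination→emergence is given a fixed 40 °Cd
(sowing-depth scale); it too is a package default, not a measured value.

**Water balance.** One bucket of plant-available water capacity
(default 120 mm, 60 % full at sowing). Rain infiltrates up to 50 mm/day;
the excess, and any saturation excess, runs off. Stage-1 soil evaporation
removes up to 2 mm/day from the uncovered soil fraction on wet-surface
days (30 % of that on dry days). Transpiration supply is `kl × soil water`
with `kl = 0.08`/day. The per-season budget closes to machine precision:
initial water + rain = final water + runoff + evaporation + transpiration,
and the test suite asserts this to 10⁻⁶ mm.

**Growth.** Potential daily biomass is `RUE × srad × cover × f_chill` with
RUE = 2.2 g/MJ and canopy cover a logistic in cumulative thermal time from
emergence (midpoint 350 °Cd, rate 0.012/°Cd — a compact stand-in for leaf
area and light extinction over the stand). `f_chill` is a C4 chilling
limitation: photosynthetic efficiency declines linearly below a 24 °C
daily-mean threshold, reaching zero at the 10 °C base. It is inactive at
the warm study site (daily means ~27–28 °C, still above threshold at the
−1 °C anomaly) and matters only for the cool highland cells of the mapping
grid. Transpiration demand converts
potential growth through the vapour-pressure deficit,
`demand (mm) = potential × vpd / (1000 × TE)`, with TE = 0.009 kPa and vpd
computed from saturation pressure at `0.75·Tmax + 0.25·Tmin` minus that at
Tmin, floored at 0.1 kPa. The water-stress factor
`min(1, supply/demand)` multiplies growth, and — between emergence and flag
leaf — the day's thermal time, so early drought delays phenology.

**Yield.** Grain number per m² is fixed at flowering
(`grains/head × heads/plant × plants/m²`, scaled by mean pre-flowering
stress). Grain filling is degree-day-driven: the daily sink is
`grain number × 0.61 mg/grain/day × (tt/20) × stress`, so the potential
grain mass over the fill phase depends on its thermal-time target, not on
how many calendar days the phase happens to span — a cool season fills
longer but not bigger. The sink is capped by the day's assimilate plus a
retranslocation pool of 10 % of biomass at the start of grain fill, and by
a maximum harvest index of 0.45. Yield (kg/ha) is grain mass (g/m²) × 10.

**Calibration.** RUE, PAWC, plant density (10/m²) and heads per plant are
not site measurements. One calibration pass fixed heads per plant at 1.0 so
that the sink-limited potential yield (~3.5–4 t/ha across accessions)
respects the crop's widely cited ~4 t/ha potential, and the 30-season mean
yield on the default synthetic climate lands near the observed subsistence
scale (~1.5 t/ha). Users matching a specific site should tune RUE and PAWC
first; both enter linearly in the energy- and water-limited regimes.

## Synthetic weather

The generator emulates the statistical structure the analysis needs, not
any particular station record: two-state first-order Markov rainfall
occurrence (monthly stationary wet-day probability and wet-after-wet
persistence), gamma wet-day amounts (shape 0.8), monthly-mean temperatures
with AR(1) daily anomalies (sd 1.0 °C, ρ = 0.6, tmax > tmin enforced), and
a deterministic seasonal radiation curve reduced by 0.75 on wet days. The
default monthly shape is bimodal — minor rains March–June, major rains
October–December — and `calibrate_gen_config()` rescales wet-day means (one
factor for season months, one for the rest) and shifts temperatures so the
closed-form expected normals hit the targets exactly; the default target is
the site baseline (32.1 °C / 23.3 °C / 1121 mm / 289 mm). A 200-year
realisation reproduces these within Monte-Carlo tolerance (tested at 5 %;
typically within ~1 %).

What it does *not* emulate: multi-day synoptic persistence beyond lag one,
cyclone-scale extremes, rainfall–temperature coupling (beyond wet-day
radiation reduction), or any real geography — the mapping grid is an
abstract 0.25° lattice with a smooth southwest-wet/northeast-dry rainfall
gradient plus a Gaussian cool-highland temperature anomaly (up to 9 °C) in
the interior, the two gradients that structure yield on the study island.
Consequently, passing tests demonstrate correct model behaviour *under
these statistics*, not skill against observed station data. Daily-scale
statistics (wet-day frequency, intensity distribution) are assumptions of
the template, stated here because no daily climatology is shipped.

Stream discipline: every (location, variable) pair draws from its own
seeded substream, so appending grid locations never perturbs existing
series, and all output is rounded to 0.01 so file round-trips are exact.

## Scenario machinery

Sensitivity anomalies are additive in temperature and multiplicative in
rainfall, applied uniformly to every day — rainy-day counts are invariant
by construction. The 99-member design is a Latin hypercube over
[−1, +8] °C × [−50, +50] %: each margin is split into 99 equal strata with
one uniform draw per stratum, paired by a seeded permutation
(`lhs::randomLHS`). The protocol's CO₂ dimension is omitted: the crop model
has no CO₂ response pathway (C4 physiology; the underlying model family is
not parameterised for CO₂), so varying it would be decorative.

GCM change signals are applied by the delta method — per-month additive
temperature deltas and multiplicative rain ratios on the baseline daily
series, preserving its day-to-day structure. Because only the ensemble's
climate *normals* are shipped (not monthly delta sets), the fixture bridge
`delta_from_normals()` builds constant-monthly deltas that reproduce a
target row's annual normals exactly; the round-trip is tested to 0.5 % for
all 40 model × scenario rows.

## Statistics

Ensemble summaries use the sample (n−1) standard deviation for the CV,
strict inequalities for threshold counts, and unrounded means with rounding
applied only at presentation. "Significantly different" claims use Welch's
unequal-variance t-test (the two yield samples have no pairing structure);
trend claims use OLS of yield on year with a two-sided t-test on the slope.
The response-surface emulator is the conventional full quadratic in
(ΔT, ΔP) fitted by OLS to the 99 accession-mean relative changes; the raw
member table is exported alongside so contours can be drawn without the
fit. Change histograms use left-closed 10 % bins (`[−10, 0)`, `[0, 10)`,
…), so an exact zero counts as an increase — a boundary convention, stated
because it is otherwise invisible.

Per design member, yields are averaged over years within accession first,
then across accessions ("accession-mean of year-means"), so accessions are
weighted equally regardless of their failure years.

## Numerical choices and degenerate inputs

* Missing weather values use the single sentinel `NA`; a series validates
  only when gap-free, and gap-filling errors name the first unfillable date.
* The season window (15 March–15 June) is inclusive on both ends — 93 days
  every year; leap days are kept (the simulation is date-driven).
* Climate normals use complete calendar years only; partial edge years are
  dropped.
* IDW uses power 2 over all points, haversine distances (the grid spans
  several degrees of latitude), and short-circuits exactly at source points
  (distance < 1 m); outputs are convex combinations of the sources.
* A season that never germinates, or that runs past the hard stop (30 days
  after the window) before maturity, is flagged failed rather than raised
  as an error; yield is whatever grain had formed (zero if none).
* Ties in ensemble extreme-change lookups are broken by model-label order.

## Problem sizes

The shipped tests and the reproduction script use the full study
dimensions: 30 seasons × 5 accessions (baseline), × 20 models × 2
scenarios (projection), × 99 members (sensitivity), and 95 grid locations
(30 seasons, all five accessions for the potential map, accession L_12 for
the uniform-anomaly maps, mirroring the single-cultivar scenario analysis).
A full pipeline run is a few minutes on one CPU.

## Known limitations

* The crop model is a compact reconstruction, not APSIM: no tillering,
  leaf-number canopy dynamics, nitrogen or residue cycling (nitrogen is
  assumed non-limiting), no damage mechanism for heavy rain after sowing.
  Absolute yields therefore carry the calibration's uncertainty even
  though directional responses are robustly ordered.
* The quadratic emulator under-fits the steeply convex response at the
  −50 % rainfall corner: with the default calibration its residual RMS is
  ≈ 3.5 % and its intercept at the origin ≈ −1.3 %. Users needing an exact
  origin should contour the raw member table instead of the fit.
* Warming benefits only a thin cool margin of the mapping grid (~2 % of
  locations at +1 °C). Real highland warming benefits act through
  nonlinear cold-failure mechanisms (chilling damage, frost, stand
  establishment failure) that the linear chilling factor does not capture,
  so the share of warming-advantaged locations is understated.
* The photoperiod response form (short-day, 11.5 h base) and the
  germination–emergence target are structural assumptions.
* Grid soils are part of the synthetic specification; ingestion of real
  soil profiles is deliberately out of scope.
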