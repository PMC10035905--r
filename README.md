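# prosoclim

Agro-climatic sensitivity analysis for Proso millet (*Panicum miliaceum* L.),
a short-duration, drought-tolerant C4 cereal grown as a rainfed subsistence
crop in tropical monsoon climates. The package asks the questions an
agronomist planning crop diversification would ask: how sensitive is the
crop's yield to warming and to rainfall change, what do mid-century climate
projections imply for its current growing area, and where else could it be
grown?

It is aimed at crop modellers and agro-climatologists who want a compact,
fully scriptable version of that workflow — one that runs end-to-end on
synthetic weather, with every step testable.

## What it computes

* **Daily weather handling** — reading/writing CSV and an APSIM-met-like
  dialect, gap-filling a station record from a fallback source with
  per-value provenance, growing-season extraction (15 March–15 June), and
  climate normals.
* **A stochastic weather generator** — two-state Markov rainfall occurrence
  with gamma wet-day amounts, AR(1) daily temperatures and a clear-sky
  radiation curve, calibrated in closed form to target normals (the default
  site: mean Tmax 32.1 °C, Tmin 23.3 °C, 1121 mm annual and 289 mm
  growing-season rainfall), plus a gridded variant with a smooth wet–dry
  gradient for mapping.
* **A process-based crop simulator** — thermal-time phenology through the
  eleven millet stages (cardinal temperatures 10/30/45 °C), a single-bucket
  soil water balance, radiation- and water-limited biomass with
  transpiration-efficiency coupling, stress-delayed development, and a
  sink-limited grain fill parameterised by accession-specific genotype
  coefficients (five accessions, L_1–L_25).
* **Climate scenarios** — the 99-member Latin-hypercube temperature ×
  rainfall sensitivity design (ΔT ∈ [−1, +8] °C, ΔP ∈ [−50, +50] %),
  delta-method application of GCM change signals (additive temperature,
  multiplicative rainfall), and the five uniform mapping anomalies.
* **Ensemble statistics** — multi-model means (with outlier exclusion),
  percent-change ranges, threshold counts, and coefficients of variation
  over a shipped table of mid-century (2040–2069) climate normals for 20
  CMIP5 models under RCP4.5/RCP8.5.
* **Impact response surfaces and tests** — quadratic yield-change emulator
  ΔY%(ΔT, ΔP) = c0 + c1ΔT + c2ΔP + c3ΔT² + c4ΔP² + c5ΔTΔP fitted by OLS,
  10-percent change binning, Welch two-sample comparisons and OLS yield
  trends.
* **Yield mapping** — per-location mean yields over a 95-location grid,
  inverse-distance-weighted interpolation on great-circle distances, and
  percent-difference maps against a reference site.

## Worked example

```r
library(prosoclim)

# 31 years of synthetic weather for the default dry-zone site
wx <- generate_weather(default_gen_config(seed = 1), years = 31)
summarize_weather(wx)
#> <climate_normals> Tmax 32.1 C  Tmin 23.3 C  annual rain 1053 mm  seasonal rain 254 mm

# 30 seasons x 5 accessions under the baseline climate
cam <- run_campaign(wx, 1980:2009)
round(mean(cam$yield))
#> [1] 1508

# how much yield does one degree of warming cost?
warm <- run_campaign(apply_anomaly(wx, dT = 1), 1980:2009)
round(percent_change(mean(warm$yield), mean(cam$yield)), 1)
#> [1] -5.2
```

The first number is the 30-season, all-accession mean grain yield in kg/ha
under the baseline climate — subsistence-scale, well below the crop's
~4 t/ha potential, because the simulated seasons are frequently
water-limited. The second is the relative yield change under a uniform +1 °C
anomaly with unchanged rainfall: warming shortens the crop cycle and raises
the vapour-pressure deficit, costing about 5 % of yield at this site.

Ensemble statistics work directly off the shipped CMIP5 normals table:

```r
ens <- load_gcm_ensemble()
count_exceeding(ens, "annual_rain", "RCP4.5", "above")$count   # 17 of 20 wetter
round(multimodel_mean(ens, "seasonal_rain", "RCP8.5", exclude = "GFDL_CM3"))  # 323
```

## Package layout

| Area | Files |
| --- | --- |
| Weather I/O and normals | `R/weather-io.R` |
| Stochastic generator and grid | `R/weather-gen.R` |
| Scenario construction/application | `R/scenarios.R` |
| Crop simulator | `R/cropsim.R` |
| Ensemble statistics | `R/ensemble-stats.R` |
| Response surfaces, tests, bins | `R/surface.R` |
| Mapping and IDW | `R/mapping.R` |
| Campaign orchestration | `R/campaigns.R` |
| Fixtures (genotypes, CMIP5 normals) | `inst/extdata/` |

The methods vignette (`vignettes/prosoclim-methods.Rmd`) documents the
model equations, parameter choices, calibration and known limitations.
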