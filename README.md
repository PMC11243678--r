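# dunedyn

Decade-scale coastal dune vegetation dynamics from monthly Landsat-style
surface-reflectance scenes.

Coastal dune vegetation in the Mexican Caribbean shifts under seasonal
climate (dry, rainy, and the cool "northerlies" season), storms and
human pressure. `dunedyn` is an R package plus a numbered analysis
workflow that quantifies that dynamism from a monthly scene archive:

* **Preprocessing** — Collection-2 QA_PIXEL bitmask decoding (cloud bit
  3, shadow bit 4, 2-bit cloud confidence in bits 8–9) and conversion of
  digital numbers to reflectance (`DN × 0.0000275 − 0.2`) or °C (×0.1
  for TerraClimate temperatures), under a strict NoData contract.
* **Indices** — `SAVI = (NIR − Red)/(NIR + Red + L) · (1 + L)` with soil
  adjustment `L = 0.5`, and `NDVI = (NIR − Red)/(NIR + Red)`.
* **Compositing** — per-pixel medians over five biannual windows
  (2011–12 … 2019–20) and monthly zone summaries labeled by climatic
  season (dry Mar–May, rainy Jun–Oct, northerlies Nov–Feb).
* **Classification & change** — five SAVI density classes cut at
  0 / 0.25 / 0.35 / 0.45 (bare soil … high-density arboreal), percent
  cover and hectares per class, and biannual differences
  `IVMd = IVM2 − IVM1` with pixelwise category-shift maps.
* **Trend** — per-pixel Mann–Kendall test, `S = Σ_{i<j} sign(y_j − y_i)`,
  `τ = S/D` with `D = n(n−1)/2`; exact two-sided p for short series
  (tie-aware), normal approximation with tie-corrected variance
  otherwise; positive/negative/neutral classes at α = 0.05.
* **Group statistics** — Lilliefors K–S normality screen (Monte-Carlo
  p), Mann–Whitney U, tie-corrected Kruskal–Wallis, Bonferroni pairwise
  post hoc, Spearman rank correlation; exact permutation modes for small
  samples.
* **Climate attribution** — distance-based linear modelling (DistLM) of
  monthly zone SAVI on Tmax/Tmin/precipitation via the Gower-centered
  matrix `G = −½JD²J` (permutation pseudo-F, forward selection by
  adjusted R²) and dbRDA ordination of the fitted variation.
* **Synthetic decade** — a seeded generator with ground truth (zone
  baselines, injected trends, seasonal boost, clouds, SLC-off-style
  stripes) standing in for the satellite archive, used by the tests and
  the workflow.

Grids travel as ESRI ASCII rasters (`.asc`, text, explicit
`NODATA_value`, optional `.prj` CRS sidecar); stacks are described by a
`manifest.csv` (year, month, band, path); climate tables are CSV in the
TerraClimate storage convention.

## Worked example

```r
library(dunedyn)

mann_kendall(c(1, 3, 2, 4))
#> Mann-Kendall: S = 4, D = 6, tau = 0.6667, p = 0.3333 (exact), n = 4 -> neutral
```

Four observations give six ordered pairs, five rising and one falling:
score S = 4 of a maximum D = 6, τ = 0.67, but with n = 4 the exact
two-sided p of 0.33 cannot approach significance — short series are
classed neutral unless the evidence is unanimous.

The full decade, end to end (about two seconds):

```r
cfg <- pipeline_config(out_dir = "run", seed = 42,
                       simulate = list(rows = 30, cols = 30, cloud_frac = 0.2))
m <- run_pipeline(cfg)
m$n_biannual_layers
#> [1] 5
```

The same stages are laid out as a narrated workflow under `analysis/`
(`01_simulate.R` … `06_climate_attrib.R`), each writing its tables under
`results/`. On the default synthetic decade the workflow prints, among
other things:

```
zones differ: U = 14400, p = 7.14e-41
NZ seasons: K-W H = 79.91, p = 4.44e-18
  dry vs northerlies           adj p = 3.36e-12
  dry vs rainy                 adj p = 0.778
  northerlies vs rainy         adj p = 1.45e-15
```

— the two dune zones carry distinct SAVI levels, and among seasons only
the northerlies stand apart (dry vs rainy level), the pattern the
generator encodes. The attribution stage then reports temperature
covariates explaining ~90% of the monthly SAVI variation (permutation
p = 0.001) with precipitation marginal, and a first dbRDA axis carrying
100% of the fitted variation.

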