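# canopymort

Individual-tree analysis of drought-induced forest mortality as a function
of canopy structure, for forest ecologists and remote-sensing scientists
working with lidar canopy height models (CHMs) and repeat aerial imagery.

During a multi-year drought, does a tree's size and its neighborhood
structure predict whether it dies? `canopymort` implements the full
analysis chain for that question — and ships a synthetic-scene generator
with a *known* mortality process so every stage can be validated by
parameter recovery rather than trust:

* **Scene generation** — clustered stem maps (Thomas process), four genera
  sorted along an elevation gradient, truncated-Weibull heights, crown
  allometry, CHM/terrain/land-cover rasters, and ground-truth mortality
  drawn from
  `logit P(dead) = β₀ + f(height) + β_c·CCTH + β_e·((elev−e₀)/1000)² + ε`,
  where `f` is continuous piecewise-linear with knots at 14 m and 39 m and
  segment slopes (−, +, −), and `β_c < 0`.
* **Crown delineation** — marker-controlled watershed segmentation of the
  CHM (priority flood in C++), removal of trees under 5 m, and
  segment-to-truth matching with recall / precision / F-score.
* **Competition indices** — CCTH (canopy cover taller than the central
  tree), CC66 (taller than 66 % of its height) and CVTH (CV of neighbor
  heights) in 15/30/50/100 m neighborhoods.
* **Crown shadow ratio** — ray-traced fraction of a crown's surface shaded
  by neighbors within 15 m, averaged over 23 half-hour solar steps
  (07:00–18:00, 1 Aug 2016, 37.42° N), plus a reduced two-leaf
  evapotranspiration response to shading.
* **Terrain covariates** — Horn slope/aspect, D8 flow accumulation,
  `TWI = ln(a / tan β)`, clear-sky solar radiation.
* **Dead-tree calling** — a tree is dead when over 35 % of its crown
  pixels classify as dead (threshold swept 30–50 %); pre-drought dead
  trees leave both numerator and denominator; annual rates
  `100·n_dead/n_trees/years` per stand or grid cell.
* **Statistics** — weighted binning and regression; continuous piecewise
  (segmented) regression with exhaustive breakpoint search + BIC; beta
  regression; random-intercept mixed models; bootstrap mediation
  (CCTH → shadow → mortality); random-forest importance and partial
  dependence (ntree 500, mtry 3).

## Worked example

Recovering the generator's known structure from a synthetic cohort — the
core sanity loop of the package:

```r
library(canopymort)
set.seed(1)
n <- 60000
h <- runif(n, 5, 60)
trees <- data.frame(tree_id = 1:n, x = runif(n, 0, 100), y = runif(n, 0, 100),
                    height = h, crown_radius = 0.6 * h^0.7,
                    crown_base_height = 0.4 * h, genus = "Pinus",
                    crown_shape = "cone", dead = NA, dead_fraction = NA,
                    predead = FALSE)
dtm  <- grid_raster(matrix(1650, 11, 11), origin = c(0, 110), cell_size = 10)
comp <- data.frame(tree_id = trees$tree_id, ccth = runif(n, 0, 60))
trees <- assign_mortality(trees, comp, dtm, mortality_params(), seed = 2,
                          predead_prob = 0)

# mortality rate (%/yr) binned by 2 m of height, piecewise fit
hser <- bin_weighted(trees$height, 100 * as.numeric(trees$dead) / 4,
                     bin_width = 2)
piecewise_fit(hser)
#> Piecewise weighted fit: 2 breakpoint(s) at  15, 39
#>   segment slopes: -0.249, 0.185, -0.248
#>   weighted R2 0.962

# mortality rate binned by 2 % of CCTH, weighted linear fit
cser <- bin_weighted(comp$ccth, 100 * as.numeric(trees$dead) / 4,
                     bin_width = 2)
wls_fit(cser)
#> Weighted linear fit: slope -0.07069 (se 0.00262, p 1.32e-21),
#>   intercept 6.471, weighted R2 0.963, n = 30
```

The fit finds the generator's two height breakpoints (truth 14 m and 39 m;
the 2 m bin grid puts candidates at odd centres) with the
negative–positive–negative slope pattern, and a strongly significant
negative mortality–CCTH slope: about −0.7 %/yr per 10 % of CCTH under the
default effect size. Each slope is in percent mortality per year, per metre
of height or per percentage point of CCTH.

The whole pipeline — scene through statistics, with every artifact written
to disk (trees CSV, ASCII-grid rasters, stands GeoJSON, fits JSON, and a
provenance manifest; reruns with the same seed are byte-identical):

```r
report <- run_all(run_config(
  scene = scene_config(extent_m = c(200, 200), intensity_ha = 110, seed = 42),
  out_dir = "demo_run", seed = 42))
report
#> <run_report> 322 trees, 137 segments; overall called mortality 4.68 %/yr;
#>   segmentation F 0.628; elapsed 12.8 s
subset(report$sweep, select = c(threshold, n_dead, rate_pct_per_year))
#>   threshold n_dead rate_pct_per_year
#> 1      0.30     67          6.368821
#> 2      0.35     63          5.988593
#> 3      0.40     60          5.703422
#> 4      0.45     58          5.513308
#> 5      0.50     52          4.942966
```

The called mortality rate sits in the 4–5 %/yr range the generator is
calibrated to, and raising the dead-call threshold lowers the apparent
rate monotonically, as it must.

## Layout

```
R/                 pipeline stages (one file per stage) + S3 fit classes
src/watershed.cpp  priority-flood marker-controlled watershed
inst/extdata/      reference cohort-count table
tests/testthat/    unit, property and acceptance suites with
                   independent oracles (voxel ray marching, brute-force
                   D8 routing, exhaustive breakpoint enumeration)
vignettes/         methods vignette: models, conventions, limitations
scripts/           acceptance script (see above)
```
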