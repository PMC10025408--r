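# phenofield

Desk-scale, multi-modal field-phenomics processing pipelines in R.

Field phenotyping platforms — rail-mounted gantries and drones — image
thousands of plants many times per season with RGB cameras, thermal
cameras, PSII chlorophyll-fluorescence imagers and structured-light
laser scanners. Turning that raw sensor stream into *per-plant,
per-date* trait tables requires a chain of unglamorous but
precision-critical steps: affine georeferencing, plot clipping, plant
detection, canopy segmentation, point-cloud registration, time-series
association and multi-modal joins. phenofield implements that chain for
breeders and quantitative geneticists who want individual-plant growth,
temperature, photochemistry and morphology traits plus their
repeatability, and for methods developers who need a fully synthetic,
truth-bearing testbed for each stage.

## What it computes

* **Georeferencing** — pixel→geographic via the 6-coefficient
  geotransform at pixel centers (lon = a·x + b·y + 0.5(a+b) + c, and the
  analogue for latitude), WGS84→UTM projection, and plant **bounding
  area** BA = |(SEe − NWe)(SEn − NWn)| m².
* **Detection** — a pluggable detector contract with a classical
  reference detector (greenness index 2G − R − B, Otsu threshold,
  connected components), evaluated by IoU (|A∩B|/|A∪B|), recall
  TP/(TP+FN), precision TP/(TP+FP), F1 and point-wise accuracy
  (TP+TN)/total.
* **Canopy temperature** — linear DN→°C calibration, K-means (K = 3) on
  each plant clip, median/mean canopy temperature (MEDT/MEAT) from the
  coldest cluster, plus a centered 10×10 ROI median.
* **PSII fluorescence** — 101-frame stacks (1 pre-pulse, 50 pulse, 50
  post-pulse); per pixel F0 (pre-pulse) and FM (pulse maximum) with
  five-bin contribution thresholds; plot-level FV = FM − F0 and
  FV/FM = (FM − F0)/FM.
* **3D morphometrics** — dual-scan translation alignment (RANSAC),
  landmark-based affine georeferencing, per-plant clipping, ICP merging,
  RANSAC plane plant/soil segmentation, DBSCAN neighbor removal, then
  PH = Zmax − Zmin, axis-aligned and PCA-oriented bounding volumes,
  convex-hull volume and point count.
* **Tracking & fusion** — agglomerative clustering of detection centers
  (average linkage, threshold 6e-7 degrees) into plant time series with
  "double" (merged-plant) flagging from a marked outlier layer; thermal,
  PSII and 3D traits fused into one table keyed by plant id and date.
* **Repeatability** — REML variance components for
  y = μ + irg + g + g×irg + rep(irg) + row(rep×irg) + col(rep×irg) + ε
  and r = σg² / (σg² + σgi²/n_irg + σε²/n_plot).
* **Synthetic field** — a deterministic generator of a whole season
  (rasters, stacks, scan pairs, plot/outlier GeoJSON, landmark JSON)
  with ground truth for every stage.
* **Pipeline runner** — YAML-configured (tags / modules /
  workload_manager / paths), locally parallel, per-unit seeded so
  results are bitwise independent of the worker count; thin CLI at
  `inst/scripts/phenofield`.

## Worked example

Simulate a small season, run the full pipeline, and read the fused
trait table:

```r
library(phenofield)

td  <- tempfile("season")
cfg <- default_pipeline_config(file.path(td, "in"), file.path(td, "out"),
                               n_workers = 1, seed = 7,
                               sim = list(n_plot_rows = 2, n_plot_cols = 2,
                                          dates = c("2020-02-03",
                                                    "2020-02-10",
                                                    "2020-02-17")))
log <- run_pipeline(cfg)
table(log$status)
#> ok
#> 26

fused <- read.csv(file.path(td, "out", "fused.csv"))
head(fused[, c("plant_id", "date", "bounding_area", "medt", "fvfm", "ph")], 4)
#>   plant_id       date bounding_area     medt      fvfm         ph
#> 1   G01_23 2020-02-03   0.007181849 21.68474 0.8242098         NA
#> 2   G01_23 2020-02-10   0.016895395 21.84741 0.8244288         NA
#> 3   G01_23 2020-02-17   0.030624991 21.76447 0.8245087 0.08267366
#> 4   G01_24 2020-02-03   0.008097793 21.79022 0.8242098         NA
```

Each row is one plant on one date: `bounding_area` (m²) tracks canopy
growth from the RGB detections, `medt` (°C) is the canopy temperature
from the thermal K-means (the simulated canopy is 22 °C), `fvfm` is the
plot-level maximum PSII quantum yield (simulated around 0.77–0.83), and
`ph` (m) appears on dates with 3D scans. `out/evaluate/` holds detection
metrics against the generator truth and the double-plant association
confusion; `out/track/clusters.csv` lists each tracked plant with its
`is_double` flag.

Single stages are available as plain functions (`detect_plants_reference`,
`extract_canopy_temperature`, `compute_f0_fm`, `icp_merge`,
`fit_variance_components`, ...) — see the package help and the methods
vignette in `vignettes/`.

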