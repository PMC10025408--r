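---
title: "phenofield: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenofield: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenofield turns multi-modal field-phenomics sensor data — georeferenced
RGB and thermal rasters, PSII chlorophyll-fluorescence image stacks, and
3D laser-scan point clouds — into individual-plant, time-series trait
tables. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-field generator does and does
not emulate, and the design choices made where the problem was genuinely
open.

## Georeferencing and bounding area

A raster's six-coefficient affine geotransform maps 0-based pixel
(column, row) coordinates to geographic coordinates at pixel centers:

$$\mathrm{lon} = a x + b y + 0.5(a + b) + c, \qquad
  \mathrm{lat} = d x + e y + 0.5(d + e) + f,$$

with $a$ and $e$ the E–W and N–S pixel spacings ($e < 0$ for north-up
rasters), $b, d$ rotation terms and $(c, f)$ the upper-left corner. A
detection's pixel box becomes a geographic box by mapping the (x_min,
y_min) corner to NW and (x_max, y_max) to SE; both corners are projected
to WGS84/UTM and the **bounding area** is

$$\mathrm{BA} = \left| (SE_e - NW_e)\,(SE_n - NW_n) \right| \;
  \mathrm{m}^2 .$$

The absolute value matters: under north-up conventions the northing
difference is negative, and an area must be non-negative. Because no
projection library ships with this R stack, the UTM forward/inverse
projection is implemented directly as the transverse-Mercator Krüger
series (4th order in the third flattening, scale 0.9996, 500 km false
easting), with the inverse conformal latitude solved by Newton
iteration. Truncation error is far below a millimeter across a UTM
zone; the test suite checks round trips against 1e-6 m and the northing
increment against a numerically integrated meridian arc.

Plot clipping tests each pixel center against the plot polygon
(even-odd rule); pixels outside are masked with a nodata sentinel (NaN
for floating-point rasters). Clips keep a corrected geotransform whose
upper-left corner is the polygon bounding-box corner.

## Plant detection

The detector is a pluggable contract: any function from a raster clip to
pixel boxes with confidences in [0, 1] can be registered by name, so a
learned model can replace the built-in one without code changes. The
reference implementation is deliberately classical: a greenness index
(2G − R − B) for 3-band input (raw intensity for single-band),
Otsu or fixed thresholding, 8-connected components, and a minimum
component area (`min_area_px`). It exists so that the full pipeline is
testable end to end without network weights; it is not a contribution in
itself. No confidence threshold is applied by default.

## Canopy temperature

Thermal digital numbers are converted to Celsius by a linear
gain/offset calibration supplied through configuration (the synthetic
sensor uses gain 0.04 °C/DN, offset −273.15 °C). For each detected
plant, the bounding-box clip is clustered by 1-D K-means with K = 3
(kmeans++ seeding, 10 restarts, seeded from configuration). Transpiring
canopies are cooler than sunlit daytime soil, so the coldest-mean
cluster is taken as canopy by default; with K = 3 the middle cluster —
mostly mixed boundary pixels — is excluded from the statistics. The rule
is overridable (`"warmest"`, `"largest"`) for nighttime or cold-soil
scenes. Reported statistics are the median and mean canopy temperature
(MEDT, MEAT), canopy quantiles, and the median of a 10×10-pixel ROI
centered in the clip (clipped at the edges of small boxes). Clips where
all pixels are identical return whole-clip statistics with a
`degenerate` flag.

## PSII chlorophyll fluorescence

A capture is a 101-frame stack over two seconds: one frame shortly
before the saturating LED pulse, 50 during the one-second pulse, 50
after. Per pixel, F0 is the pre-pulse frame value and FM the maximum
over the pulse frames; post-pulse frames are retained but unused. Each
pixel is binned by five ascending FM contribution thresholds; pixels
below the first edge are background and excluded. Plot-level F0 and FM
are means over non-background pixels (median available), and

$$F_V = F_M - F_0, \qquad F_V/F_M = (F_M - F_0)/F_M .$$

The instrument's own threshold values are configuration input; when none
are given the package falls back to five equal quantile edges of the
capture's FM histogram, which is only sensible when plant pixels
dominate the capture — the pipeline configuration therefore passes
explicit thresholds. Aggregating pixel means first and forming the ratio
afterwards (rather than averaging per-pixel ratios) was chosen because
it is stable for dim pixels with small FM.

## 3D morphometrics

The 3D stage mirrors a gantry dual-scanner workflow:

1. **Orientation/scale**: raw scans are scaled to meters, west scans are
   mirrored in y to restore right-handed chirality, and gantry offsets
   are added.
2. **Dual-scan alignment**: a RANSAC loop estimates the (x, y)
   translation of the west scan onto the east scan. Scoring is
   restricted to the densest above-ground window — a featureless ground
   plane matches at any horizontal shift, so only canopy points carry
   signal — and candidate correspondences are canopy apexes (per-cell
   local z-maxima), which guarantees the true pairing is among the
   proposals. The best proposal is refined by the mean inlier offset.
3. **Landmark affine**: a least-squares 6-parameter 2D affine maps cloud
   (x, y) to orthomosaic lon/lat from at least three non-collinear
   landmark pairs (a JSON file contract replaces an interactive GUI);
   z stays in meters.
4. **Plant clipping**: each RGB-derived detection box, expanded by `pad`
   meters in UTM, gathers its points per tile; fragments are re-centered
   to a local meter frame.
5. **ICP merge**: point-to-point ICP (nearest-neighbor correspondences
   within `max_corr`, Kabsch update, termination on relative objective
   change) merges east/west fragments; merges below a fitness floor are
   rejected and fragments kept separate.
6. **Plant/soil segmentation**: a RANSAC plane (candidate triples drawn
   from the lower half of the z range, least-squares refinement, upward
   orientation) labels points within `dist_thresh` of the plane or below
   it plus `margin` as soil.
7. **Neighbor removal**: DBSCAN over xyz keeps the cluster nearest the
   expected plant center (ties to the larger cluster), dropping noise.
8. **Traits**: plant height PH = Zmax − Zmin; axis-aligned bounding
   volume AABV; oriented bounding volume OBV as the extent product in
   the principal-component frame; convex hull volume CHV (an incremental
   hull built in-package, checked against an external-library oracle);
   point count NP.

OBV uses the PCA-oriented box, not the minimal-volume box: it is
deterministic and matches common library behavior, but it is an
approximation — for clouds with degenerate (isotropic) covariance, such
as a perfect cube, PCA cannot recover the orientation and the PCA box
can exceed the minimal one. The tests therefore assert what PCA
actually guarantees: CHV ≤ OBV and CHV ≤ AABV always hold because any
bounding box of the points contains their hull, while OBV ≤ AABV does
not hold in general.

All distances (`pad` 0.1 m, ICP `max_corr` 0.05 m, DBSCAN `eps` 0.04 m,
plane `dist_thresh` 0.004 m, `margin` 0.005 m) are in meters and sized
to decimeter-scale rosette crops on millimeter-noise scans; they are
configuration knobs, not constants.

## Tracking and fusion

Detections from all dates are clustered on raw (lon, lat) degrees by
agglomerative clustering with average linkage, cut at a distance
threshold of 6e-7 degrees (about 6 cm at mid latitudes). The threshold
and linkage are configuration knobs; the default is kept in degrees for
fidelity with established practice even though its metric meaning
varies with latitude. Marked outlier points — field locations where two
plants merged into one apparent canopy — are clustered together with the
detections, and any cluster containing one is flagged `double` so those
records can be excluded from genetic analyses. Each cluster becomes a
plant with id `genotype_clusterNumber`, the genotype coming from the
plot map. A cluster may hold at most one detection per (date, sensor);
surplus same-date members (farther from the centroid) are split off,
which prevents physically impossible tracks.

Thermal detections join the nearest RGB cluster centroid within the
same threshold; PSII traits are plot-level and broadcast to all plants
of the plot by (plot_id, date); 3D traits join by (plant_id, date).
3D rows with unknown plant ids are kept but flagged `orphan`.

Double-plant flagging is evaluated with the marked/flagged confusion.
Each field mark identifies exactly one canopy, so it is attributed to
its nearest cluster centroid (within the clustering threshold), not to
every cluster nearby — the two members of a pair sit within the
threshold of the pair midpoint and would otherwise both count as
missed. Then:
TP = marked and flagged, FN = marked not flagged, FP = flagged not
marked, TN = neither, giving recall, precision, F1 and accuracy; an
empty marked class leaves recall absent rather than zero.

## Repeatability

Per trait and collection date, a linear mixed model is fitted by REML
(lme4) with irrigation fixed and genotype, genotype × irrigation,
replication-in-irrigation, and row/column-in-(rep × irrigation) random:

$$y = \mu + \mathrm{irg} + g + g{\times}\mathrm{irg}
      + \mathrm{rep(irg)} + \mathrm{row(rep{\times}irg)}
      + \mathrm{col(rep{\times}irg)} + \varepsilon .$$

Irrigation is treated as fixed because its variance does not enter the
repeatability denominator. Variance estimates are non-negative by
construction (REML on a constrained scale). Repeatability is

$$r = \frac{\sigma_g^2}
  {\sigma_g^2 + \sigma_{gi}^2 / n_{irg} + \sigma_\varepsilon^2 / n_{plot}},$$

with $n_{irg}$ the treatments per genotype and $n_{plot}$ the plots per
genotype, taken as modal counts across genotypes when the design is
unbalanced. On a simulated 100-genotype × 3-treatment × 3-rep design
with $(\sigma_g^2, \sigma_{gi}^2, \sigma_\varepsilon^2) = (4, 1, 1)$ the
closed-form r is 0.9; the test suite requires the mean estimate over 20
simulations to land within ±0.05.

## The synthetic field generator

`sim_config()` / `generate_field()` define the reference desk-scale
study conditions: a 4 × 4 plot grid near (−112.0, 33.07), plots 1.02 m ×
4.0 m with two seed lines 0.31 m apart and 10 plants per plot (with a
few cm of placement variation, as in real thinned stands), five weekly
collection dates with logistic canopy growth (r0 = 0.03 m to rmax ≈
0.12 m, genotype and plant lognormal variation), canopy at 22 °C vs
soil at 35 °C with 0.3 °C pixel noise, per-plot F0 ∈ [90, 110] and FM ∈
[450, 550] with a linear pulse ramp, hemispherical plant clouds (4000
points/m² of surface) on a ground plane (800 points/m²) with 1 mm point
noise and a known (0.03, −0.01) m west-scan misalignment, and a 10%
per-plot chance of an intentionally planted "double" pair. Any two
plants whose canopies merge by season end (distance below the sum of
their final radii) are marked as doubles with an outlier point at the
pair midpoint, mirroring the end-of-season field marking protocol.
3D scans exist for the last collection date, reflecting that laser
scanning typically starts once plants are established. All randomness
flows from one seed through fixed per-modality substreams, so adding a
modality does not perturb the others and the same seed is byte-for-byte
reproducible.

The generator emulates geometry, radiometric contrast and pulse
kinetics, not realism: plants are disks/hemispheres without occlusion,
leaves, specularity, wilting or registration error beyond the one known
translation; soil is spatially white noise; plot polygons are exact.
Passing the end-to-end tests therefore demonstrates that the pipeline
machinery — georeferencing, clipping, detection bookkeeping, clustering,
registration, segmentation and joins — is correct under known truth,
**not** that the reference detector or segmenter would reach the same
accuracy on real imagery, where trained models take their place.

## The pipeline runner

A YAML config with four sections (`tags`, `modules`,
`workload_manager`, `paths`) drives execution. Modules run in listed
order; within a module, input units (one raster, one 101-frame stack,
one scan pair) are dispatched to a local pool of `n_workers`
(fork-based). Every task derives its RNG seed from (global seed, module
name, unit id), never from the worker, so outputs are bitwise identical
for any worker count — the test suite asserts this for 1 vs 4 workers.
A failed task is logged (JSON-lines task log) and does not abort its
module; downstream joins tolerate the gap. Cluster-scheduler fields
(cores per worker, memory per core) are parsed and recorded for config
compatibility but only `n_workers` drives the local pool.

## Numerical choices and limitations

* K-means on 1-D temperatures uses 10 kmeans++ restarts under a fixed
  seed; clustering ties are resolved by total within-cluster sum of
  squares.
* The incremental convex hull uses an epsilon of 1e-10 × cloud diameter
  for visibility tests; degenerate (coplanar) clouds report CHV as NA.
* Agglomerative clustering cut heights sit on raw degrees; fields
  spanning several degrees of latitude would need a metric CRS instead.
* The dual-scan aligner assumes the misalignment is a pure translation
  of at most a few decimeters and that canopies are visible in both
  scans; scenes without above-ground structure fall back to scoring on
  all points and will register only if textured.
* Binary PLY and compressed GeoTIFF are not read; the raster container
  is plain TIFF plus an ESRI world file and JSON sidecar, which
  round-trips the six affine coefficients exactly.
* Problem sizes in the tests (4 × 4 plots, five dates, one 3D date,
  ~170 plants) were chosen as the smallest season on which every
  pipeline stage has enough data to measure recovery meaningfully.
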