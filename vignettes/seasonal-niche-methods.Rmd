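---
title: "Methods: seasonal Grinnellian niche analysis with SeasonalNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal Grinnellian niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SeasonalNiche)
```

# The problem

Migratory birds experience different climates in the breeding and wintering
parts of their annual cycle. Whether a species *follows* one Grinnellian
niche — the set of scenopoetic, climate-like conditions under which it can
persist — across seasons, or *switches* between seasonal niches, shapes how
its distribution responds to climate change and where its transient migratory
habitat sits relative to either niche. SeasonalNiche implements a complete,
seeded workflow for asking that question from presence-only records and
monthly climate rasters, and ships a synthetic-data module so every stage is
testable against known ground truth.

The climate inputs are monthly maximum temperature, minimum temperature
(degrees C) and precipitation (mm) on one shared geographic lon/lat grid
(`ClimateStack`). Records carry a month; the default season map models
breeding with May–June, winter with December–February and the migratory
passage with April and September–November, excluding the transitional months
March and August, whose records cannot be assigned to a period with
confidence. The map is plain configuration (`defaultSeasonMap()`); a study
that compiles breeding records into July but models May–June simply overrides
it. Records are made spatially and seasonally unique: at most one record per
grid cell and season, the earliest in input order winning
(`dedupOccurrences()`); cells are half-open with row 1 northernmost, so a
point on a shared edge belongs deterministically to the cell to its
south-east. A season's environmental value at a point is the mean over the
season's months — the least surprising composite, and per-month extraction
remains available.

# The rule-set ensemble model

Presence-only distribution models in the genetic rule-set family evolve
populations of interpretable IF–THEN rules. The grammar here has three rule
kinds: *range* rules (apply inside a per-variable climate box), *negated
range* rules (apply outside it) and *logit* rules (apply everywhere, predict
presence where a logistic score crosses one half). Each rule predicts
presence or absence; an ordered rule set predicts by "first applicable rule
wins", with absence as the default, so every climate vector has a defined
prediction.

Fitness of a rule is the z-score of its accuracy gain over the prior
prevalence of its predicted class, scored on a held-out internal split (30%
of the presence+background data). Presence records carry three times the
weight of background points in that accuracy (`gaParams(omissionBias = 3)`):
the evaluation protocol downstream deliberately privileges omission error
over commission error, and an omission-neutral fitness lets broad absence
rules swallow known presences, starving the best-subsets filter. The GA runs
a population of 40 rules for up to 30 generations (binary tournament
selection, 20% elitism, variable-wise crossover, point mutation of interval
bounds and coefficients, occasional insertion of fresh rules), stopping early
after 8 generations without improvement. The final model walks the rules in
fitness order and *incorporates or rejects* each: a rule is kept only if, on
the points no earlier rule decided, its predictions beat the prior of its
class. Rules with non-positive fitness never enter; the fall-through default
is absence.

The per-season protocol splits records 80/20 into calibration and evaluation
(`splitCalibration()`), samples a background of up to 10 000 cells from the
modelling region — the union of cells within a 1-degree buffered bounding box
of the season's records, a stand-in for the unknown accessible area — fits
100 replicate models, and selects the 10 best (`selectBestSubset()`): first
keep replicates with training omission at most 0.10, then keep the ten whose
commission (fraction of region cells predicted present) is closest to the
survivor median, ties broken by lower omission and then replicate index.
Replicate-to-replicate variability is intrinsic to the approach — typically a
quarter to a half of replicates pass the omission filter — which is exactly
why the protocol over-fits replicates and filters. The ensemble's suitability
map counts member votes per cell (`agreement`, 0–10); the binary map applies
a majority consensus (votes ≥ k/2, configurable — the combination rule is a
genuinely open choice and majority is the least arbitrary). Projection onto
any other month's layers is the same prediction call (transferability);
nodata propagates.

# Partial ROC

A suitability map is evaluated only in the region of high sensitivity:
thresholds run over the distinct agreement values; for each, sensitivity on
the held-out records is traced against the proportion of area predicted
present; the piecewise-linear curve is clipped at sensitivity ≥ 1 − *E*
(default *E* = 0.05, always logged — the tolerance expresses how much
omission the study accepts); and the statistic is the ratio of the model's
area under the clipped curve to the chance (1:1 line) area over the same
interval, both by trapezoid. The ratio lives in [0, 2] with 1 meaning
chance-like; because thresholds are ranks, it is invariant under any strictly
monotone rescaling of the agreement values. A map that is constant over the
region *is* the chance line and returns exactly 1. The bootstrap resamples
half the test records (ceiling) with replacement 1000 times; the p-value is
the fraction of bootstrap ratios at or below 1.

# Internal niche structure

Over the consensus-presence cells of a season, each climate variable is
Z-standardized with the sample (n − 1) standard deviation; the niche centroid
is then the zero vector, and a cell's distance to centroid is the Euclidean
norm of its standardized row. (A printed sum-of-squares without the root
appears in parts of this literature; the package applies the root — the
quantity is a distance, and DC of a (3, 4) row must be 5.) Distances are cut
into optimal / suboptimal / marginal zones. The default breakpoints (1.515,
2.95) make the three bands contiguous and total on [0, ∞): every finite DC
has exactly one zone and distances beyond any observed maximum are still
marginal. Published cutoffs of this kind are data-derived, so they are
overridable, and `cutoffs = "auto"` splits the observed DC range into three
equal-width bands. Records are placed in zones with the *season's*
standardization applied to the record's own month's climate by default —
transient records are judged on the conditions they actually experienced —
with a season-mean mode available; the choice matters and both are exposed.

# Polar-coordinate breadth

Breadth treats each variable as a force vector at a fixed angle: a climate
row projects to the vector-sum equilibrium point, giving a 2-D cloud per
stage. Variables are min-max scaled to [0, 1] *over the union of the stages
being compared* (raw units would let precipitation dominate), and the default
angles are evenly spaced in the order tmax, tmin, prec — the assignment is a
convention, and breadth is invariant to a global rotation of it. The occupied
climate is delimited by the alpha-hull: the union of Delaunay triangles whose
circumradius is at most alpha. With alpha = Inf this is the convex hull;
smaller alpha follows concavities and avoids overestimating the occupied
area. The default alpha is twice the median nearest-neighbour distance of the
cloud, computed after collapsing near-coincident points (snapped to 1/200 of
the bounding-box diagonal) — neighbouring grid cells project to
near-duplicate points whose raw nearest-neighbour distances would drive the
median, and hence alpha, to zero. Overlap between two stages rasterizes both
hulls onto one 100 × 100 lattice spanning their joint bounding box (a cell
counts if its centre is inside) and reports both directional percentages plus
the occupied-cell counts ("pixels", the breadth unit used in reporting).

The triangulation is a Bowyer–Watson implementation with two numerical
safeguards: a deterministic, index-based symbolic jitter of 1e-8 of the cloud
span breaks the cocircular degeneracies that grid-derived clouds are full of
(areas change by a negligible O(1e-8) of span²), and the enclosing
super-triangle is placed a thousand spans out so that no hull triangle's
circumcircle can reach a super-vertex — closer placements visibly clip the
hull boundary. Clouds larger than 1500 points are thinned deterministically
(evenly spaced indices) before triangulation in the pipeline.

# PCA-env similarity

The similarity analysis compares the two seasons in a shared two-axis
principal-component space calibrated on the pooled, standardized climate of
the two seasons' *modelling regions*. Using each season's region as its
availability background — rather than only the predicted-presence cells — is
deliberate: occupancy corrects occurrence density by availability
(z = o/e, rescaled to sum to 1, with a small relative floor of 1e-8 of the
surface maximum so genuinely unavailable cells are exactly zero), and a ratio
of two densities is unstable when the denominator is as concentrated as the
numerator; with region backgrounds, identical niches score D ≈ 0.6 and widely
separated ones D ≈ 0, with the expected monotone decline in between. Kernel
densities use a Silverman-type bandwidth per axis on a 100 × 100 lattice
covering all background scores with a 10% margin.

Schoener's D = 1 − ½·Σ|z₁ − z₂| summarizes overlap (0 complete
differentiation, 1 complete similarity; symmetric). The similarity test
replaces the focal season's records with a same-size draw from the pooled
records of both seasons, 100 times, recomputing D against the other season's
observed grid; the p-value uses the add-one convention
p = (1 + #{null D ≥ observed D})/(n + 1), so p is never exactly zero and
small p means the seasons are *more similar* than random re-labelling of the
available records would produce. Both directions are runnable; they differ in
whose sample size and background the null uses.

# The synthetic-data generator

The generator emulates interpolated monthly climatologies on a 120 × 120
grid of 0.0416-degree cells: maximum temperature is a linear latitudinal
gradient (0.25 °C per row, warming southwards from a base of 8 °C) plus a
seasonal cosine peaking in July (amplitude 12 °C) plus a smooth,
month-invariant noise field (amplitude 0.8 °C, a coarse Gaussian field
bilinearly interpolated); minimum temperature subtracts a 10 °C diurnal range
that itself varies smoothly in space (amplitude 1 °C) — real diurnal ranges
vary with aridity and terrain, and a rigid tmax − tmin offset would make the
two temperature variables informationally identical; precipitation has a
*longitudinal* gradient (−0.3 mm per column from a 70 mm base), its own
seasonal cosine (amplitude 25 mm, peak in August) and noise (5 mm), clipped
at zero with a report. The longitudinal moisture axis is what makes the
realized climate genuinely two-dimensional: with both gradients latitudinal,
every climate combination would sit on a single curve and no
three-dimensional niche centroid would be attainable.

Ground-truth niches are diagonal Gaussians in climate space; occurrence cells
are drawn *without replacement* with probability proportional to suitability
on the season-mean climate (so generated data are already spatially unique,
mirroring the dedup rule), one record per drawn cell with a month uniform
over the stage's months. Scenario construction places the *follower* centroid
at the per-variable midpoint of the overlap between the two seasons' realized
climate ranges — interior to both, so records drawn around it are not
truncated by a range edge — and *switcher* centroids ± Δ/2 standardized
(spread) units from it along the axis separating winter-typical from
breeding-typical climate; migratory-month niches sit at the midpoint, between
the two seasonal niches. Default record counts are 246 breeding, 83 winter
and 28/20/33/15 for April/September/October/November; spreads default to
1.5 °C for the temperatures and 5 mm for precipitation.

What the generator does *not* emulate: coastlines, terrain, spatial
autocorrelation beyond the smooth noise field, record biases (roadside
sampling, detection), temporal climate trends, and biotic interactions. A
passing pipeline on these scenarios demonstrates that the machinery recovers
known niche structure and orderings under clean sampling; it does not
certify performance on biased real-world occurrence data. One further
statistical consequence of finite discrete landscapes is worth knowing: the
expected climate mean of sampled records is the availability-weighted
suitability mean, not the niche centroid itself — the two coincide only when
availability is flat around the centroid, which is why the package's tests
compare against the weighted expectation and treat the centroid as a
0.25-spread approximation.

# End-to-end orchestration and determinism

`runPipeline(runConfig(...))` executes season assignment → dedup → per-season
80/20 split, 100 replicates, 10 best → partial ROC → inter-prediction and
migratory-month projections with the directional overlap table → niche
structure and migratory-record zone classification → polar breadth and
between-season overlap → PCA-env similarity in both directions → monthly
climate profiles, and returns a plain summary in which every number is one
module's output (the report layer recomputes nothing). One global seed
deterministically derives per-stage seeds by hashing stage names
(`deriveSeed()`), so stages can be rerun in isolation and a configuration
reproduces its summary JSON bit for bit.

Problem sizes in the shipped tests are chosen for desk-scale runtimes: unit
tests use 10–60-cell-wide grids and 10–30 replicates; the end-to-end
follower/switcher recovery runs the full 120 × 120 design with 100
replicates per season (roughly two minutes per scenario on one core); the
determinism check uses a 60 × 60 grid with 24 replicates and a steeper
latitudinal gradient (0.5 °C per row) so the two seasons' climates still
overlap on the smaller grid. The similarity-test calibration experiment uses
the exchangeable form of "identical niches": two independent 100-record draws
from one niche on one season's months against one shared background. Drawing
the two sets from different seasons of a follower scenario would not be a
calibration check — the seasons then differ in availability, which is
precisely the signal the randomization null is designed to model.

# Known limitations

* The genetic algorithm is this package's own documented variant of the
  rule-set family; results that depend on its internals are properties
  (omission bounds, transferability orderings, breadth and similarity
  orderings), never numeric reproductions of any particular desktop
  implementation's maps.
* Commission is measured over a buffered bounding box of the records because
  the truly accessible area of a real species is unknowable from records
  alone; the buffer is configuration.
* Rasters are exchanged as single-band ESRI ASCII grids; no reprojection is
  performed and all inputs must share one geographic grid.
* Breadth is two-dimensional by construction (the polar projection); no
  volume-based measure for more variables is provided.
* The o/e occupancy correction, while availability-aware, remains sensitive
  to bandwidth at very small record counts (< ~20); the bandwidths used are
  always recorded in the result objects.
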