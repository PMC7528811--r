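---
title: "Filtering occurrence records and its downstream effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering occurrence records and its downstream effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occfiltr)
```

# The procedure

`occfiltr` takes geo-referenced occurrence records — one observation or
specimen of a species at a coordinate, with Darwin-Core-style meta-data —
and answers three questions: which records are problematic and why; what do
species richness maps look like before and after removing them; and how do
automated conservation assessments change.

The quality tests fall into two families. Meta-data tests need no
geography:

| test | flags a record when | class |
|---|---|---|
| `basis` | basis of record is fossil or unknown/absent | unfit |
| `year` | collection year < 1945 | unfit |
| `precision` | stated coordinate uncertainty > 100 km | unfit |
| `count` | individual count outside [1, 99] | unfit |
| `id_level` | not identified to species (or finer) rank | unfit |

Gazetteer/coordinate tests compare coordinates against reference layers:

| test | flags a record when | class |
|---|---|---|
| `duplicate` | same species + same coordinates rounded to 4 decimals, except the keeper | unfit |
| `zeros` | both \|lat\| and \|lon\| ≤ 0.5° | error |
| `equal_latlon` | lat = lon (or lat = −lon) within 1e-9° | error |
| `realm_mismatch` | terrestrial record at sea, or marine record on land | error |
| `country_centroid`, `province_centroid` | within 1 km of a centroid point | unfit |
| `capital` | within 10 km of a capital | unfit |
| `urban` | inside an urban polygon | unfit |
| `institution` | within 0.1 km of a biodiversity institution | error |

A record hit by any error-class test is *erroneous* (its coordinates are
likely wrong); one hit only by unfit-class tests is *unfit* (usable in
principle, too imprecise or unsuitable for most analyses). The class
membership is a configuration table, not code — analyses at coarse grain
may legitimately reclassify, say, centroids.

All tests are evaluated on all records, so per-test percentages share the
group total as denominator and can sum to more than the overall flagged
percentage (records can carry several flags). The filtered data set is the
union-complement: records with no flags, coordinates untouched at full
input precision.

## Threshold choices

The 1945 cut-off (coordinates of pre-war records usually derive from
retrospective geo-referencing of locality text), the 100 km precision
limit (the grain of many macro-ecological analyses), the [1, 99]
individual-count window, the exclusion of fossils and unknown sources, and
the 4-decimal duplicate rounding are the package defaults for user-level
cleaning of aggregator downloads. Boundary conventions are: year 1945 is
kept, uncertainty of exactly 100 km is kept, counts 1 and 99 are kept.
Buffer radii default to 1 km for political centroids (a deliberately
conservative choice — centroid coordinates in gazetteers are exact, so a
small radius suffices), 10 km for capitals (capital coordinates are a
city-scale vague-locality artefact), and 0.1 km for institutions
(institution coordinates are building-scale). The zeros test uses a 0.5°
box rather than exact equality to catch truncated near-zero artefacts; the
equal-lat/lon test is exact to 1e-9° and by default also flags the
sign-flipped pair lat = −lon, which is the same keyboard slip with a sign
error (configurable off; the exact origin is left to the zeros test).
Absent meta-data never flags a record, with one deliberate exception: a
missing basis of record counts as unknown source.

The duplicate keeper is the record with the smallest `record_id` in
lexicographic order — an arbitrary but fixed rule that makes the flag set
a deterministic function of the data.

# Spatial model

All geometry runs on the authalic sphere (R = 6371.0088 km, the sphere
with the WGS84 surface area). Distances are haversine great circles;
against an ellipsoid model this is accurate to < 0.6%, irrelevant at the
0.1–10 km buffer scales used here, and keeps results exactly reproducible
from the formulas. Point-in-polygon is even-odd ray casting with a
per-feature bounding-box prefilter; the prefilter is a pure optimization
whose output is test-verified identical to the brute-force path, and both
are checked against an independently coded winding-number oracle on random
points. Boundary points count as inside land and inside urban polygons:
coastal collection localities are legitimate, and the convention minimizes
false sea flags. A buffer test fires at distance exactly equal to the
radius. Polygon features spanning more than 180° of longitude
(antimeridian crossers) are rejected at load time; the package targets
regional study windows.

Gazetteer layers are explicit inputs (GeoJSON, one file per layer); the
package bundles no real-world gazetteer. An empty or missing layer makes
its test flag nothing, with a warning, so a partial gazetteer degrades
gracefully rather than silently passing bad records.

## The equal-area grid

Richness, AOO and locations all use a cylindrical equal-area projection
with standard parallel 30° (Behrmann): x = R λ cos 30°,
y = R sin φ / cos 30°. Cells are half-open squares
[i·s, (i+1)·s) × [j·s, (j+1)·s) anchored at the projected origin — every
point maps to exactly one cell, and the anchor is declared rather than
inherited from any particular gridding tool, so cell counts are
reproducible from the definition. Richness cells default to 100 km (the
typical macro-scale mapping grain), AOO cells to 2 km (the IUCN guideline
scale) and location cells to 10 km.

# Criterion B assessment

Per species: EOO is the area of the convex hull of all its records — the
hull is found in the projected plane, and the hull polygon's area is then
measured on the sphere. With fewer than three distinct non-collinear
records the EOO is undefined (`NA`); assessment then proceeds on B2 (AOO)
alone, rather than substituting AOO for EOO — a declared, configurable
choice. AOO is 4 km² per occupied 2-km cell; the number of locations is
approximated by 10-km cell occupancy. True IUCN locations are defined by
threat events and cannot be computed from coordinates alone; the grid
proxy is the standard automated stand-in and is labelled as such.

The category is the more severe of B1 (EOO against 100 / 5 000 /
20 000 km²) and B2 (AOO against 10 / 500 / 2 000 km²), each requiring the
locations count to be at most 1 / 5 / 10 for CR / EN / VU. Species meeting
neither get a single not-threatened proxy category — the pipeline's
evaluation is binary (threatened vs not), so NT and LC are deliberately
not distinguished. Subconditions beyond the locations count (severe
fragmentation, continuing decline) are out of scope; the assessment is
preliminary by construction. For agreement statistics, reference species
categorised DD or NE are excluded rather than counted as not threatened.

# The synthetic study system

The generator exists so that every claim the package makes is testable
against known truth. `make_toy_gazetteer()` builds a fixed world: a
continental rectangle (longitude −30…30°, latitude −22…22°) inside a
−40…40° × −30…30° window, split into two countries, each with a centroid,
capital, institution and urban polygon, plus four province centroids. The
layout is engineered so the tests are separable: every reference point is
hundreds of kilometres from every other and from the lat/lon diagonals,
urban polygons contain no reference points, and the origin (0, 0) lies on
land. That last property matters: a zeros-planted record must be flagged
by the zeros test *only*, so the origin must not also be at sea for a
terrestrial group.

`simulate_occurrences()` gives each species a random rectangular range on
land (terrestrial groups) or in open sea (marine groups) and samples clean
records uniformly inside it, rejecting locations that violate the clean
contract: right side of the coast, outside urban polygons, at least the
separation margin (default 30 km = 3 × the largest buffer, so floating-
point distances cannot straddle a threshold) from every reference point,
outside the zeros box, off the diagonals, and distinct from all other
records of the species after 4-decimal rounding. Records per species are
log-normal with median 10 and σ(log) = √(2 ln 10) ≈ 2.15 — a heavy-tailed
distribution whose mean (~100) puts the default 5-group × 20-species run
near 10⁴ records and whose tail reaches the 10³–10⁴ records that dominant
species contribute in real aggregator downloads — capped at 2 000 records
per species to bound simulation size.

Contamination is planted at a configured rate per issue (default 3%, 5% in
the acceptance-scale runs), exactly one issue per contaminated record:
coordinates moved to (0, 0), onto the diagonal, across the coast, onto a
centroid/capital/institution point, into an urban polygon; or one
meta-data field spoiled (year 1600–1944, fossil/unknown basis, count 0 or
150, genus/unranked rank, stated uncertainty 150–500 km); or an exact
duplicate of a clean record of the same species, generated after the
original so the fixed keeper rule flags the copy. Planting respects the
same separability the clean contract does — a diagonal plant is rejected
into a position where no buffer or realm test also fires.

Three guards keep the ground truth exact rather than approximate. At most
one zeros plant per species and at most one plant per gazetteer point per
species — otherwise two plants of the same species would collide at
identical coordinates and collaterally trip the duplicate test. And
land-anchored plants (zeros, centroids, capitals, institutions, urban) are
not used in marine groups, where the planted record would also be a realm
mismatch; their contamination mass falls back to clean there. The
practical consequence is that realized planting rates for the point-copy
issues sit below the configured rate for very record-rich species; the
rate-fidelity property is therefore tested on a simulation with moderate
per-species counts, where the guards do not bind.

The reference assessments used by the evaluation stage are themselves
synthetic: Criterion B applied to each species' ground-truth clean
records. Agreement of the filtered-data assessment with this reference is
perfect by construction when recovery is exact — the evaluation checks the
pipeline's internal consistency, not the field accuracy of automated
assessments.

## What the toy world does not emulate

Passing the recovery tests shows the tests implement their definitions
exactly; it does not show how filtering performs on real data, where clean
records legitimately occur near centroids, in cities and on coastlines,
where one record can carry several problems at once, where realms are
fuzzy (estuaries, islands below gazetteer resolution) and where taxonomy
itself is noisy. Real-data per-test flag fractions, and any tuning of
thresholds per taxon or region, must come from real studies; the package
exposes every threshold in `filter_config()` for exactly that reason. The
toy world's rectangular geometry also means polygon tests are never
exercised on concave coastlines or holes by the simulation itself; those
paths are covered by dedicated geometry tests instead.

# Numerical and scale choices

Duplicate keys are built by formatting rounded coordinates to fixed
decimals (with negative zero folded to zero), avoiding float-equality
pitfalls. The spherical polygon area uses the line-integral form
Σ (λ₂−λ₁)(2 + sin φ₁ + sin φ₂) R²/2, exact for edges along parallels and
meridians and within fractions of a percent of a strict geodesic polygon
at hull-edge lengths that occur here; it is cross-checked against an
independent implementation in the tests. Collinearity of a candidate hull
is decided by planar hull area ≤ 1e−12 of the squared extent.

Default test-suite and acceptance problem sizes — 5 groups × 20 species
(~5 000–15 000 records depending on seed), 1 000-point spatial-oracle
sweeps, 100 random subset pairs for the monotonicity suite, 2 000-point
uniform samples for area recovery — are chosen so the full suite completes
in well under a minute while every property is exercised at a scale where
binomial noise cannot hide a defect. All randomness flows from a single
integer seed; two runs with the same seed produce byte-identical data
artifacts (the run manifest's timestamp aside), which the acceptance suite
asserts.

# Known limitations

* Locations are a grid proxy; threat-based locations can differ in either
  direction.
* EOO of ranges spanning > 180° longitude, or of circum-polar species, is
  outside the projection's comfort zone; the package targets regional
  windows.
* The erroneous/unfit split is binary per test; real records graded by
  severity need downstream judgement.
* Reference-assessment comparison is exact-string species matching; no
  synonymy resolution is attempted.
* Aggregator-internal quality flags, when present in a download, are
  neither required nor interpreted — the package ingests every row with
  parseable in-range coordinates and applies its own tests.
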