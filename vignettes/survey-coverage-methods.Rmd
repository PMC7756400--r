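---
title: "Methods: survey footprints, coverage statistics and multi-survey density tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey footprints, coverage statistics and multi-survey density tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlcover)
```

## What the package computes

Scientific bottom trawl surveys are the backbone of fishery-independent
monitoring of demersal species, but each survey is run nationally or
regionally, on its own design, and its data are not always available.  Three
questions follow for anyone trying to track climate-driven range shifts:

1. **How much of the relevant ocean do the surveys cover?**  Footprints are
   built from haul coordinates and compared against productive-shelf,
   fished-area and landings grids.
2. **How many surveys does it take to cover a species' range, and across how
   many jurisdictions does that range extend?**
3. **Can heterogeneous surveys be combined into one density field so that a
   population's center of gravity can be tracked through time?**

Because raw survey data are largely restricted, the package ships seeded
generators for every input; all statistics are exercised and tested on
synthetic worlds whose generating parameters are known exactly.

## Survey footprints

A survey's spatial domain is summarized by the alpha shape of its haul
positions: the union of Delaunay triangles whose circumradius is at most
$\alpha$ (the radius convention of the alpha-convex-hull literature), with
$\alpha = 1$ degree as the default.  As $\alpha \to \infty$ this is the
convex hull; smaller $\alpha$ lets the outline follow concave coastlines and
archipelago-shaped designs.

Design choices a maintainer should know about:

* **Degree-space geometry, spherical areas.**  Hulling runs in lon/lat degree
  space — an accepted planar approximation at survey scale (a few degrees)
  that keeps $\alpha$ interpretable — while areas are always evaluated on
  the authalic sphere (radius 6371.0072 km).
* **Radius, not inverse.**  The alpha parameter is the circumradius bound in
  degrees.  The radius-versus-$1/\alpha$ ambiguity in the literature is
  resolved explicitly; the parameter is exposed everywhere.
* **Self-verifying triangulation.**  The Bowyer–Watson construction uses a
  finite enclosing triangle, which can clip near-degenerate hull slivers
  whose circumcircles reach past it.  The implementation therefore checks
  that the triangle areas tile the convex hull exactly and escalates the
  enclosing scale (on recentered coordinates) until they do.  Insertion
  order is fixed by lexicographic point ordering, so footprints are
  deterministic; duplicated haul positions are removed first.
* **Holes dissolved by default.**  Footprints are effective sampling
  domains, so interior holes of the alpha complex are filled;
  `keep_holes = TRUE` preserves them.
* **Degenerate inputs** (fewer than 3 distinct or collinear points) raise an
  error by default; a configurable square buffer (`fallback_buffer_deg`)
  exists for edge-case workflows.
* **Antimeridian.**  Point sets straddling 180° (Bering Sea style) are
  recentered to [0, 360) before hulling and split back at ±180 on output.
* Hauls are pooled across the study window when building a footprint;
  per-year footprints can be had by grouping before the call.

Footprint unions are kept as collections of parts with point-membership
semantics — that is all the raster comparison needs — and union areas are
computed by an exact slab-decomposition sweep (event abscissae at every
vertex and pairwise edge intersection), rather than by constructive polygon
booleans.

## Grid conventions and coverage statistics

All rasters are cell-center-registered regular lon/lat grids with half-open
cells, so every point belongs to exactly one cell and counting oracles are
exact.  Missing cells are excluded from every denominator.  The coverage
thresholds (all configurable, `threshold_config()`):

| parameter | default | meaning |
|---|---|---|
| depth band | 30–500 m, inclusive | the depth range bottom trawl surveys target |
| chlorophyll-a | > 0.5 mg/m³, strict | productivity proxy for shelf cells |
| fished | ≥ 2 trawl events | "more than one" detected activity |
| habitat probability | > 0.5, strict | occurrence-probability mask |
| range target | 50% | habitat fraction a survey set should reach |
| density mask | 0.1% of maximum | separates occupied from unoccupied cells |

A cell is *productive shelf* when the depth and chlorophyll conditions both
hold; *fished* when the event count condition holds.  Footprints are
rasterized by the cell-center rule (boundary counts as inside).  Coverage is
the fraction of eligible cells inside the footprint union; landings coverage
weights cells by landings instead of counting them.  When a covered cell is
claimed by several surveys, its availability attribution goes to the *most
open* class (publicly available > partly > on request > not public >
incomplete metadata), answering "could data for this cell be obtained?".

## Species ranges and survey sufficiency

Habitat surfaces (occurrence probability on a 0.5° grid, AquaMaps-style) are
thresholded strictly at 0.5 into habitat masks.  Range coverage is the
fraction of habitat cells inside the footprint union, with the overlapping
surveys listed most-open-first.  "Number of surveys needed" is reported two
ways, side by side, because the raw-count versus minimal-set distinction is
genuinely open:

* `n_to_target`: the count of overlapping surveys, reported when the union
  reaches the target (the survey-count convention of coverage tallies);
* `surveys_to_target()`: a planner returning either the greedy order
  (largest marginal habitat gain first, lexicographic tie-break) or the
  exact minimum-cardinality set (exhaustive enumeration, guarded to ≤ 20
  footprints).  Greedy cumulative fractions are non-decreasing with
  non-increasing marginal gains; the exact optimum never exceeds the greedy
  count.

Transboundary accounting counts, for a habitat mask, every region containing
at least one habitat cell center; for a stock polygon, every region whose
intersection area exceeds $10^{-6}$ of the smaller area.  A subject is
transboundary when it overlaps more than one region.

## The Poisson-link delta-gamma catch model

Catches from multiple surveys are combined through a hurdle model in which
both parts derive from one latent numbers-density.  For haul $i$ with area
swept $a_i$ (km²), year $t_i$, survey $s_i$ at location $(x_i, y_i)$:

$$\log n_i = \beta_n(t_i) + \sum_b \gamma_b(t_i)\, B_b(x_i, y_i) + \eta(s_i)$$
$$p_i = 1 - \exp(-a_i n_i), \qquad
  r_i = \frac{a_i n_i w_i}{p_i}, \qquad \log w_i = \beta_w(t_i)$$

with catch 0 with probability $1 - p_i$ and otherwise Gamma-distributed with
mean $r_i$ and shared coefficient of variation $\sigma$.  $\eta$ is the
per-survey log-catchability, fixed at 0 for the reference survey; setting
all $\eta \equiv 0$ recovers the identical-gear assumption.  Declared
choices, since the construction leaves them open: the Gamma is parameterized
by mean and CV with one CV across years and surveys; catchability enters the
numbers-density predictor; and the spatial term is a fixed low-rank basis —
tensor-product quadratic polynomials (8 non-constant terms) or Gaussian
radial bases at user knots, with year-varying coefficients — standing in for
spatial random fields.  The basis preserves what matters here
(interpolation across contiguous survey domains, center-of-gravity shifts)
at desk scale without re-implementing a full spatio-temporal random-effects
machine, at the cost of smoother, less local surfaces.

**Estimation.**  The likelihood (zeros contribute $-a_i n_i$ on the log
scale; positives contribute $\log p_i$ plus the Gamma log-density) is
maximized by BFGS with analytic gradients, started from moment initializers:
year encounter rates inverted through the Poisson link for $\beta_n$, mean
positive catch for $\beta_w$.  Convergence requires a relative gradient norm
below $10^{-6}$; standard errors come from the inverse numerical Hessian of
the analytic gradient.  Encounter probabilities are computed as
`-expm1(-mu)` to stay accurate near 0.  Years lacking both an encounter and
a zero are flagged as inestimable for the hurdle part.

**Identifiability.**  Catchability separates from the shared spatial field
only where survey domains overlap (or through the rigidity of the global
basis).  The synthetic designs used in the tests therefore place surveys on
overlapping bands; with disjoint domains, catchability contrasts rest
entirely on the basis extrapolation — the regression-discontinuity situation
— and should be interpreted with care.  Relabeling the reference survey
rescales the catchability-free density surfaces by the estimated offset of
the new reference; the package's invariance check verifies exactly this
reparameterization identity rather than literal equality of surfaces.

**Density surfaces and centers of gravity.**  Predicted density
$d = n \cdot w$ (kg/km², catchability excluded, i.e. in the reference gear's
scale) is evaluated at cell centers, optionally masked below 0.1% of the
surface maximum (the maximum cell always survives; masked cells become
missing, never zero).  The center of gravity weights cell centers by density
times exact spherical cell area; displacements are haversine great-circle
distances (mean radius 6371.0088 km) with bearings, plus the relative
(Δlon, Δlat) convention.  The model interpolates within the combined survey
domain; prediction grids are restricted to it (`cog_track(domain = ...)`)
because polynomial extrapolation outside sampled areas is meaningless.
Whether tracks use masked or unmasked surfaces is configurable; unmasked is
the default.

## The synthetic world

`gen_world()` builds a shelf: depth rising monotonically from a designated
coast edge to 2000 m, chlorophyll decaying exponentially from ~5 to
~0.05 mg/m³ with an e-folding scale of a third of the domain, Poisson trawl
effort concentrated where depth is 30–500 m (mean 6 events versus 0.2
outside), landings positive exactly where effort is, and rectangular regions
tiling the domain.  Depth and chlorophyll are deterministic closed forms of
position, so classification fractions are enumerable exactly from the stored
`truth`.  `gen_hauls()` places hauls by a parent–offspring (Neyman–Scott
style) process with parents preferentially on the trawlable band — mimicking
stratified designs clustered on the shelf — with uniform placement as the
degenerate option; each generator call seeds one RNG and records its seed.
`gen_habitat()` is a logistic function of great-circle distance to a range
center (probability 0.5 at the stated midpoint).  `gen_catches()` draws from
the delta-gamma model above, with lognormal area swept.

What the generators deliberately do **not** emulate: real bathymetry or any
real survey's actual footprint, gear-dependent size selectivity, temporal
autocorrelation in year effects, anisotropic or fine-scale spatial
structure, and observation errors in haul positions.  Passing tests
therefore demonstrate the correctness of the accounting and estimation
machinery under the stated generative assumptions — not that any particular
real-world coverage percentage is reproduced, which would require the
restricted survey metadata and the external depth/chlorophyll/effort/
landings/habitat databases.

## The default study configuration

`default_config()` fixes the synthetic study once: a 10° × 8° world at 0.2°
resolution with the coast on the west, four EEZ-like regions, five surveys
of 400 hauls (four meeting the inclusion rules — at least 4 sampled years in
2001–2019, at least one since 2015, not near-shore — and one excluded for
sampling only 3 years), two species with shelf-centered habitat surfaces on
a 0.5° grid, and a density case study of two surveys with overlapping
domains (catchability offset 0.2 on the log scale for the second survey),
six years, 150 spatially balanced stations per survey-year, and a
numbers-density bump drifting north at 0.1°/year.  These sizes keep a full
pipeline run at a few seconds while leaving every estimate comfortably
identified; the drift corresponds to a net ~56 km northward shift over the
six years, which the fitted track recovers up to sampling noise.  Haul
placement for the density stage is uniform within each survey region
because survey designs aim for spatially balanced station coverage; the
clustered process is exercised by the footprint stages.

## Numerical details worth recording

* Half-open cell membership makes rasterization exactly reproducible by a
  winding-number oracle; boundary points count as inside.
* The slab sweep for overlay areas is exact in the planar (square-degree)
  measure; in km² it integrates authalic latitude bands per slab, exact in
  longitude and first-order in latitude within a slab.
* Ties in the greedy set cover break lexicographically by survey id; the
  exact planner enumerates subsets by increasing cardinality and stops at
  the first feasible size.
* The encounter-rate initializer clamps yearly rates to [0.02, 0.98] before
  inverting the link, keeping starting values finite in all-zero or all-hit
  years.
* All validation failures raise classed conditions (`schema_error`,
  `validation_error`, `geometry_error`, `grid_mismatch`, `linkage_error`,
  `degenerate_input`, `parameter_error`, ...) so callers can branch on them.

## Known limitations

* Geometry is planar in degree space; at very high latitudes alpha shapes in
  degrees distort (the continental-shelf surveys the package targets sit
  below ~75°).
* The low-rank basis cannot represent fine-scale density structure; with
  strongly non-overlapping surveys, catchability and spatial effects are
  only weakly separable.
* The exact set-cover planner is exponential and guarded at 20 footprints.
* No projected coordinate systems, shapefiles, or curvilinear grids; rasters
  are plain-text ASCII grids in geographic coordinates.
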