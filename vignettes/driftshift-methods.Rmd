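---
title: "Measuring winter waterfowl distribution shifts from citizen-science checklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring winter waterfowl distribution shifts from citizen-science checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftshift)
```

## The scientific problem

Extreme winter weather — polar-vortex cold outbreaks in particular — can
force wintering waterfowl to move on the time scale of days to weeks, a
window far too short for conventional surveys at continental extent.
Semi-structured citizen-science checklists (eBird-style data) record
occurrence, abundance and observer effort continuously and everywhere, so
they offer a natural before/after design around an extreme climatic event
(ECE): compare where the population mass sat in the weeks before the event
with where it sat during and after.

driftshift implements that comparison as a tested pipeline:

1. **Effort filtering** of checklist observations to control the main
   detection biases of volunteer data.
2. **Abundance-weighted positional centroids** ("center of mass") of each
   species in an early window (January 1 – February 6) and a late window
   (February 7 – 28), per year and per flyway or continentally.
3. A **signed shift statistic**: the great-circle distance between early
   and late centroids, signed by the north–south direction of the move.
4. **Severe-February classification** of years from gridded temperature
   anomaly fields.
5. A **Bayesian hierarchical linear model** of the signed shifts on
   foraging strategy, an event indicator and their interaction, with year
   random intercepts, summarized as marginal medians with 66%/95% credible
   intervals per strategy-by-event cell.
6. **GPS-telemetry cross-validation**: the same centroid statistic computed
   from telemetry fixes of marked birds, compared as an absolute
   discrepancy in km.

A synthetic-data generator with known ground truth makes every stage
testable without any external download.

## Filtering rules and their boundary semantics

Checklist observations pass six rules, applied in a fixed order with a
per-rule attrition audit: (1) complete checklists only; (2) stationary
protocols, or traveling protocols under 5 km; (3) one observation per
unique (latitude, longitude, date, species) combination, so heavily
surveyed sites are not over-weighted; (4) at most 10 observers;
(5) one checklist per shared group identifier; (6) at most 5 h duration.

Boundaries are read literally: travel strictly `< 5` km, observers
`<= 10`, duration `<= 5` h. Two cases the rules do not pin down were fixed
as package policy: a traveling checklist with *missing* travel distance is
removed (the bound cannot be verified), while a missing duration is kept
(there is no evidence the limit was exceeded). Deduplication in (3) and
(5) keeps the row with the lexicographically smallest checklist identifier
— deterministic and independent of input order, which is what makes the
filter idempotent and order-insensitive. Rule (3) deduplicates per
species-row by default; a per-checklist option (`dedupe_by = "checklist"`)
is available because either reading of "unique latitude, longitude and
date combinations" is defensible.

Presence-only counts (`"X"`) survive I/O as an explicit marker and are
excluded from abundance-weighted centroids by default: they carry no
abundance weight, and inventing one would be an analysis decision, not a
parsing one. `nonzero_observations(presence_as_one = TRUE)` recodes them
as count 1 for users who prefer not to discard detections.

## Centroids, distance and sign

The centroid is the weighted arithmetic mean of positions in geographic
degrees, the convention of center-of-mass analyses of continental survey
data. For data confined to continental North America this is numerically
safe: nothing straddles the antimeridian, and at these latitudes the
difference from a 3-D unit-vector mean is negligible relative to the
10–300 km shifts of interest.

Shift magnitude is the haversine great-circle distance on a sphere of
radius 6371.0088 km (the IUGG mean radius; fixing it makes results
identical across geodesy backends). The sign comes from the latitudinal
direction only — positive northward, negative southward — because the
quantity of scientific interest is a north–south displacement while the
natural metric is the full great-circle distance. A purely east–west move
therefore has signed shift zero by convention; this is a measure-zero
event for real centroids. Signed shifts are the default model response;
the unsigned magnitude is retained in the shift table for users who want
it.

GPS centroids support two weightings: the plain mean of all fixes, and the
mean of per-region centroids weighted by each region's share of fixes.
With frequency weights the two are algebraically identical (the tests
assert this); the second form exists so that other weights — e.g.
balancing deployment regions with very unequal marked samples — can be
explored.

Flyway assignment is an even-odd ray cast in geographic coordinates
against single-ring polygons. Points exactly on a shared boundary go to
the first flyway in canonical order (Atlantic, Mississippi, Central,
Pacific) — a deterministic tie-break for a measure-zero event.
Overlapping polygons are rejected outright. February 29 is excluded at
ingest (the season window ends February 28), and the early/late boundary
is February 6/7 inclusive on both sides.

## Severe-February classification

A February is severe when anomalies at or below −4 °C cover strictly more
than 15% of the masked (conterminous-US) region. Both inequalities are
literal, so exactly 15% coverage is *not* severe and a cell exactly at
−4 °C *does* count as cold. Coverage is the masked-cell fraction by
default and area-weighted when the grid carries cell areas; the default is
count-based because anomaly products vary in grid spec and a cell-count
fraction is the only interpretation that needs no extra metadata.

Two analysis designs are built from year labels. The single-event design
isolates February 2021: years 2015 and 2019 — whose Februarys were also
abnormally cold — are removed entirely, and the event indicator is true
only for 2021. The pooled design keeps all years, flags 2015, 2019 and
2021 as severe, and is continental-scope only, because the severe cold in
the three years occurred at different spatial scales and flyway-specific
fits would not measure a comparable contrast. Historical severe/non-severe
labels for other years are user-supplied inputs, not computed claims: the
package computes the criterion for any grid it is given, but it does not
bundle the historical anomaly fields.

## The hierarchical shift model

The response is the signed shift `delta_km` for observation *i* (a
species-by-year-by-scope shift record):

$$
\Delta_{i} \sim \mathrm{N}\!\left(\beta_0 + \alpha_{year(i)}
 + \beta_{strat(i)} + \beta_{E}\,E_{i}
 + \beta_{strat(i) \times E}\,E_{i},\; \sigma_\varepsilon^2\right),
\qquad \alpha_j \sim \mathrm{N}(0, \sigma_{year}^2)
$$

with foraging strategy (generalist reference: Mallard, Northern Pintail,
Green-winged Teal; grubbing: Snow Goose, Greater White-fronted Goose;
wetland obligate: Northern Shoveler, Gadwall), event indicator `E`
(reference: non-event year), their interaction, and a random intercept per
year. Dummy coding is pinned so that the intercept is exactly the
generalist/non-event cell.

**Priors.** Fixed effects get vague normal priors with mean 0 and sd 2.5
*on the response standardized to unit standard deviation*, then draws are
transformed back to km. A literal N(0, 2.5 km) prior would be absurdly
informative for effects of order 100 km; the autoscaled reading is the
only one under which a "vague" 2.5-sd prior makes sense, and it matches
the autoscaling convention of mainstream Bayesian regression software.
The two standard deviations get half-normal(0, 2.5) priors on the same
standardized scale — a weakly-informative positive-support default the
data dominate easily. A truncation floor of 1e-6 keeps precisions finite
on degenerate (zero-variance) inputs, which the tests exercise.

**Sampler.** The model is fit by Gibbs sampling in JAGS with, by default,
3 chains of 10,000 iterations, 5,000 discarded as warmup and no thinning;
desk-scale runs in the tests use 3 × 2,000 (5,000 for the one
boundary-case null fit, where a variance component truly at zero mixes
slowly). The likelihood is parameterized with hierarchical centering: the
year-level terms (intercept and event effect, which is constant within a
year) sit in the regression for the year intercepts,
$\alpha^{raw}_j \sim \mathrm{N}(\beta_0 + \beta_E E_j, \sigma^2_{year})$,
rather than in the observation mean. The two parameterizations define the
same posterior, but centering decouples the year-level effects from the
random intercepts and mixes far better under Gibbs updates; reported
year-intercept draws are the deviations from the year-level mean, so the
user-facing parameterization is the conventional one. Any general-purpose
MCMC would be acceptable here — correctness is defined by parameter
recovery and convergence diagnostics, not by matching a specific sampler's
draws.

**Convergence.** Split-R̂ (each chain split in half before the
between/within variance comparison, so within-chain trends are caught) is
computed for every parameter; a fit with any R̂ above 1.10 is returned
flagged with a warning, never as a silent success. `check_convergence()`
exposes the per-parameter values.

**Marginal summaries.** Each strategy-by-event cell is summarized from the
per-draw linear predictor with the year intercept marginalized at zero —
the population-level cell mean, the standard marginal-means convention for
random intercepts. Summaries are the posterior median and the central 66%
and 95% quantile intervals; the generalist/non-event cell is *exactly* the
posterior of the intercept, an identity the tests assert. Averaging over
realized years instead would answer a different ("these years only")
question and is easy to compute from the returned draws.

## The synthetic-data generator

The generator emulates, with known ground truth: checklist observations
scattered isotropically (Gaussian in km, converted to degrees at the
centroid's latitude) around configurable true centroids per
species/year/period/flyway cell, negative-binomial counts, presence-only
records, and per-rule injected violations of every filter rule; GPS fix
streams with per-region deployment imbalance (84 and 210 birds in the two
default regions, mirroring real marking imbalance) at an hourly cadence;
anomaly grids with an exactly controlled cold-area fraction; and shift
records drawn from the hierarchical model's generative form. All
randomness flows from a single seed through fixed per-table sub-streams,
so every table is byte-reproducible independently of generation order.

Default effect sizes are continental-scale magnitudes: a generalist
non-event shift of 143.1 km north, guild offsets of +42.7 km (grubbing)
and −86.3 km (wetland obligate), an event main effect of −84.6 km,
interactions of −114.9 and +10.5 km, year-level sd of 25 km and residual
sd of 100 km. The year-level and residual spreads are the generator's own
realism choices (the field's shift estimates have credible intervals of
±30–150 km at these scales); the rest reproduce published continental
cell medians.

What the generator does *not* emulate matters for interpretation: there is
no observer spatial bias beyond the configured scatter, no detection model,
no phenology within periods, and no spatial autocorrelation of counts.
Passing tests therefore demonstrate that the pipeline measures what it
claims on data obeying its assumptions — not that real checklist data are
free of residual bias after filtering.

## Numerical choices and problem sizes

- Earth radius fixed at 6371.0088 km; centroid arithmetic in degrees;
  relative agreement with an independent summation oracle at 1e-12 and
  with a spherical-law-of-cosines distance oracle at 1e-6 is asserted in
  the tests.
- Deduplication and boundary tie-breaks are all deterministic (smallest
  identifier, first canonical flyway), so every non-MCMC stage is a pure
  function of inputs and seed; the pipeline manifest records MD5 hashes to
  make this checkable.
- Desk-scale test sizes: recovery runs use 8 simulated years with three
  event years, 33 records per strategy-year cell (~100 per
  strategy-by-event cell, 792 total) at 3 × 2,000 iterations, 20
  replicates; the null check uses 4,800 records at 3 × 5,000 iterations.
  These sizes make the 95%-interval coverage and the ±0.2 km null band
  sharp while keeping a full run in minutes on one core.

## Known limitations

- The centroid is a single summary of a distribution; bimodal responses
  (part of a population evicted south while the rest stays) can cancel in
  the mean. Kernel-density or occupancy approaches are out of scope by
  design.
- The event indicator is year-level, so the event effect is identified
  from between-year contrasts and its uncertainty is driven by the year
  random intercepts — with a single event year the model is honest about
  that (wide intervals), but it cannot be made precise.
- Real flyway boundaries are complex multipolygons; the bundled synthetic
  flyways are rectangles standing in for them, and the reader accepts any
  single-ring GeoJSON polygons in geographic coordinates.
- Headline posterior estimates from the motivating continental analysis
  require the full multi-year eBird extract and are not reproducible at
  desk scale; the package's tests instead verify the machinery (filter,
  geometry, classifier, model recovery) against independent oracles and
  known simulation truth.
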