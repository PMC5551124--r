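---
title: "Designing a supplementary air-pollution monitoring network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a supplementary air-pollution monitoring network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory air-quality networks are built to enforce standards, not to
support epidemiology: monitors sit where administration requires them, while
cohort members live where housing is. When exposure at residences is
predicted from such a network, whole neighbourhood types can be unrepresented
by any monitor. `sitenet` implements a design procedure that places a fixed
number of new monitoring sites so that the *kinds of places people live in*
— described by geographic covariates related to the pollutant — are covered
by monitors in proportion to where residences actually are.

Three location roles run through the package:

* **current** — existing regulatory monitors (the only places with
  measurements),
* **subject** — residences whose long-term exposure must be represented,
* **candidate** — practical spots for a new monitor (public buildings such
  as community service centers).

The procedure has three steps: select the covariates that drive the
pollutant's annual average (a land-use regression, LUR), cluster *all*
locations in the space of those covariates, and then allocate new sites to
clusters where monitors are scarce relative to residences.

## Screening annual averages

Hourly measurements become daily means only when at least 18 of 24 hours
(75%) are present; the annual mean is the unweighted mean of those daily
means, a deliberate two-stage average so that well-sampled days do not
dominate. A site's annual average is considered representative only when

* at least 10 distinct months contain a daily average,
* at most 91 days (25% of the year) are missing, and
* every run of consecutive missing days is strictly shorter than 45 days.

All thresholds are arguments of `daily_averages()` and `site_eligibility()`.
The prose forms "more than 18 hours" and "more than 9 months" are read as
≥ 18 and ≥ 10 — the accompanying percentages (18/24 = 75%) fix the intent —
while the 45-day run criterion is strict (< 45), so a 44-day run passes and
a 45-day run fails. Missing-day runs are evaluated within the calendar year
only. The annual mean is reported for ineligible sites too, flagged, so the
screening is auditable.

## Geographic covariates

Covariates come in two metric families. *Proximity* is the Euclidean
distance to the nearest source of a kind (nearest point on a segment for
roads); *density* is the count of point sources, the clipped length of line
sources, or a land-use area share within a circular buffer. Before
modelling, proximity is truncated at a cap (1 km by default; 2 km is the
convention for large physical features such as coastlines and rivers) and
log-transformed: `log(min(d, cap) + 1)`. The 1 m offset keeps zero
distances finite and makes a location *on* a source recode to exactly 0;
natural log is used throughout. Truncation before the log reflects that a
source's influence is local — beyond the cap, "far is far".

Two screening rules remove covariates that cannot carry spatial signal:
any variable with fewer than 10% distinct values across locations, and any
land-use area-share variable whose maximum share never reaches 10%. These
are implemented as two independent rules (`exclude_low_variability()`,
which reports every exclusion with its reason); reading them as a single
conjunction would let a near-constant land-use variable survive, which
contradicts the purpose of the screen.

Scaling (`zscale()`) centres and standardises each covariate over the
*pooled* current + subject + candidate set, since clustering operates on the
pooled set; the per-variable means and SDs are retained so the identical
transform can be applied to new locations or inverted. The SD uses the
sample (n−1) denominator by default, with a population option — either
satisfies "divide by the standard deviation", but one must be fixed for
reproducibility.

## The land-use regression

`forward_select()` grows the model from the null model, at each step adding
the candidate with the largest in-sample R² gain among those whose
coefficient is significant at `entry_alpha` (default 0.05; the design
tradition says "significant" without a level). For a single added variable
the coefficient t-test and the F-test of the R² change are the same test,
so the t-test is used. Two guards bound multicollinearity: an entering
variable is removed again if its VIF exceeds 10 or its absolute Pearson
correlation with any selected variable exceeds 0.7. A removed variable is
permanently barred — re-entry is unspecified in the tradition and barring
prevents cycling. Selection stops at five variables, a cap chosen because
the model is fitted on only a few dozen monitors.

Model quality is summarised by leave-one-out cross-validation:
`loocv_r2()` refits the *fixed* selected set on n−1 sites, predicts the
held-out site, and returns 1 − MSE/var(y). The variance uses the n
denominator by default (config-exposed). Because the score is MSE-based, a
model that predicts worse than the mean scores below zero — that is a
feature, not a bug, of judging predictions against the identity line.
Reported effect sizes are standardized as coefficient × (p90 − p10) of the
covariate (linear-interpolation percentiles, quantile type 7), making
effects comparable across covariates with different units.

## Clustering and the number of clusters

All locations are clustered by k-means in the z-scaled space of the selected
covariates only; predicted concentrations are never a clustering feature.
Lloyd's algorithm converges to local optima, so `kmeans_best()` restarts it
(1000 times in the standard design) from K distinct data rows sampled at
random and keeps the restart with the lowest total within-cluster sum of
squares (SSW). Random-row initialisation is the default because the design
tradition specifies only "different initial cluster centers"; k-means++
would change which optima are reachable. If a cluster empties during
iteration, its center is reseeded at the point currently farthest from its
assigned center; a cluster emptied *indirectly* by such a reseed keeps its
stale center for one iteration and is itself reseeded on the next pass.
Iteration stops when assignments are unchanged. The per-iteration SSW trace
of the winning restart is stored, and tests assert it never increases.

The number of clusters is guided by the decrease in overall deviation,

$$\mathrm{DiD}(\%) = 100 \times \Bigl(1 - \frac{1}{J}\sum_{j=1}^{J}
\sum_{k=1}^{K} \frac{SSW_{jk}}{SSE_j}\Bigr),$$

with SSW normalised per characteristic by that characteristic's total sum
of squares. This is the only normalisation under which one cluster gives
exactly 0, singleton clusters give exactly 100, and the curve rises toward
a plateau as within-cluster variability shrinks. `did_curve()` evaluates
the statistic twice per k — once with the predicted concentrations as a
single characteristic (J = 1), once with the selected covariates (J = 5) —
and the k at the start of the *common* plateau is the advisory choice.
`suggest_k()` codifies "plateau" as: the smallest k ≥ 2 from which both
curves' forward gains stay below a threshold (default 1 percentage point)
over a three-step lookahead, falling back to the largest k evaluated with a
warning. Since the published choice of nine clusters for Seoul was a visual
judgement, k always remains user-overridable (`pipeline_config(K = ...)`).

## Allocating the new sites

For each cluster the *current-to-subject proportion* (×10⁴ for display)
measures how well monitors cover residences. `allocate()` repeats, once per
new site: among clusters that still have candidate locations, place one site
in the cluster with the minimum unrounded proportion, then count the placed
site as a current location before the next pick. This incrementing is the
reading under which recomputing the proportion between picks changes
anything, and it reproduces both published Seoul allocations exactly —
clusters (2, 3, 7, 8, 9) receiving (1, 6, 4, 8, 1) sites for PM2.5 and
(3, 4, 5, 6) receiving (4, 3, 9, 4) for NO2 — including that clusters with
zero candidates (PM2.5 cluster 4, NO2 cluster 2) never receive sites despite
minimal proportions. Ties break to the lowest cluster index by default; a
seeded random tie rule is available, and on both published tables the final
counts are tie-rule invariant (the only tie, PM2.5 clusters 2 and 7 at
proportion 0, resolves to the same totals either way). The concrete
candidate within the chosen cluster is drawn uniformly at random — no
criterion beyond uniformity is inferable from the published design, and
spatial spacing or population weighting is deliberately out of scope.

## Stability

`subsample_stability()` reruns the clustering on random 90% subsamples
(100 replicates in the standard design) and compares each run to the
full-data solution *restricted to the retained locations* — the only
well-defined pairing — via the adjusted Rand index (`adjusted_rand()`,
Hubert–Arabie contingency-table form; 0.90/0.80/0.65 are the conventional
excellent/good/moderate bands). Replicate seeds derive from the master seed
so any single replicate can be reproduced alone.

## What the synthetic city emulates — and what it does not

`generate_city()` builds the statistical structure the method assumes:
monitors spread evenly (a jittered grid, as regulatory networks cover a
city), residences clumped into Gaussian districts, candidates uniform;
line sources (major roads) and point sources (bus stops, construction
sites) on a planar rectangle; proximity and buffer-density covariates
computed from real geometry plus noise covariates unrelated to
concentration; and a ground-truth annual average that is *exactly* linear
in the recoded covariates plus i.i.d. Gaussian noise. Role counts default
to the study conditions the method was built for (37 monitors, 31,097
residences, 412 candidates); tests use smaller counts explicitly. The
defaults (20 km extent, 500 m buffers, intercept 35 µg/m³ with a −1.5
effect per log-metre of major-road proximity, noise SD 1.5 µg/m³) were
chosen once to give urban-background-like annual means in the mid-20s µg/m³
with monitor-to-monitor spread of a few µg/m³.

Real covariate fields are *not* emulated: there is no spatial
autocorrelation in the concentration noise (the LUR itself has no spatial
residual term, so adding one would test a different model), no road-network
topology, no geodetic coordinates, and the generating model is exactly the
model the LUR fits. Passing tests therefore demonstrate that the machinery
is correct and self-consistent — recovery of known coefficients, exact
cross-validation on noiseless data, reproduction of the published
allocations — not that five covariates suffice for any real city.

## Numerical choices and degenerate inputs

* Nearest-center assignment breaks ties to the lowest center index, making
  every restart fully deterministic given its initial centers.
* `did()` rejects constant characteristics (zero SSE) rather than returning
  an indeterminate ratio.
* `zscale()` refuses zero-SD columns, pointing at the screening step;
  `forward_select()` likewise refuses constant candidates and responds with
  an error, not a silent drop, when preprocessing was skipped. Density
  covariates that are constant over the few *monitor* locations (while
  variable city-wide) are excluded from the candidate set by the pipeline.
* Aliased candidates (exactly collinear with the selected set) are treated
  as non-significant rather than crashing the t-test lookup.
* All randomness (restart initialisation, subsampling, tie-breaks,
  candidate draws) flows from explicit integer seeds; derived seed streams
  keep replicates individually reproducible.

## Problem sizes

The test suite and the reproduction script run the full machinery at
deliberately modest sizes — synthetic cities of a few hundred locations,
8–25 k-means restarts, DiD curves to k = 8–15, 10–20 stability replicates —
which exercise every code path of the standard design (1000 restarts,
k ≤ 50, 100 replicates) at a fraction of the cost. The published-table
allocations are exact integer computations and run at full scale.

## Known limitations

* k-means with Euclidean distance is the clustering model; silhouette or
  information-theoretic k selection are not provided.
* No spatial constraints on the allocation (spacing, population weighting,
  distance to existing monitors).
* The LUR is ordinary least squares: no regularisation, dimension
  reduction, or kriging of residuals.
* Planar metre coordinates only; geocoding and GIS extraction of real
  covariate inventories happen upstream of this package.
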