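---
title: "Predictive characterization of wild germplasm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive characterization of wild germplasm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Crop wild relatives harbour adaptive alleles that breeding programs want,
but no program can screen every wild population. Predictive
characterization ranks populations by their probability of carrying a
target trait using only where they grow: either by thresholding
environmental conditions known to select for the trait (the *environmental
filtering* method) or by training models on a set of evaluated accessions
and projecting them onto unevaluated populations (the *calibration*
method). `predchar` implements both, together with the ecogeographic land
characterization (ELC) map that stratifies selections across distinct
adaptive scenarios, and a synthetic-data generator with recorded ground
truth so the whole pipeline is testable end to end without any external
download.

This vignette explains the models and procedures, the tunable parameters
and their defaults, the numerical choices, and what the synthetic tests do
and do not demonstrate about real data.

## The ELC map

An ELC map partitions a territory into categories meant to proxy distinct
adaptive scenarios. It is built in three steps.

**Variable selection.** A random forest classifies occurrence cells
against background cells drawn at random from the territory (10 background
cells per presence by default, drawn without duplicates from cells with
data; `rank_variables()`). Each candidate variable is scored by its
permutation-based mean decrease in accuracy (MDA). The response is not
part of the field's standard description of this step, so the package
offers two: presence/background (default — it matches
"explaining the distribution" and works for single-taxon runs) and a
multiclass response on taxon identity. Latitude and longitude participate
as geophysic candidates. Within each of the three components
(bioclimatic, edaphic, geophysic), the top 15 variables by MDA are then
scanned in decreasing order and a variable is dropped when it correlates
with an already-retained variable of the same component (Pearson
`|r| > 0.5` with `p < 0.05`; `prune_correlated()`). Correlations are
computed on the occurrence-site values, because selection concerns the
environmental space the populations occupy, not the whole grid. Ties in
MDA are broken lexicographically so reruns are identical. The greedy scan
never drops a component's MDA maximum. Whether "top fifteen" applies per
component or to a pooled set is ambiguous in the method's usual
formulation; per component is the default and `pooled = TRUE` is
available.

**Clustering.** Each component's retained layers are z-standardized per
layer (without standardization, millimetres of rain would swamp degrees
Celsius) and clustered with k-means (25 restarts, seeded) for
`k = 1..max_k` with `max_k = 6`. The number of clusters is chosen by an
elbow rule on the within-cluster sum of squares (wss): the smallest
`k >= 2` whose next decrease `wss(k) - wss(k+1)` falls strictly below half
of the previous decrease `wss(k-1) - wss(k)`; if the rule never fires, the
component keeps `max_k` clusters, and a (near-)constant component keeps
one. The sentence this rule comes from ("the decrease ... is less than
50%") admits a second reading — decrease less than half of the *current*
wss — which is available as `elbow = "absolute"`. Note that the ratio rule
reads the *shape* of the wss curve: wss that decays geometrically (each
split explaining a fixed fraction of what remains) stops at `k = 2`,
whereas clusters of comparable size and separation produce near-linear
decay and are counted correctly. This is the regime the rule presumes and
the regime the synthetic generator produces (see below).

**Category composition.** Every cell carries a (bioclimatic, edaphic,
geophysic) cluster triple; the distinct triples realized on the grid
become the ELC categories, renumbered densely over the sorted triples so
reruns are comparable (the numbering of any particular historical map is
not reconstructable and is not claimed). Cells missing any component are
category 0 and populations landing on them are flagged excluded; they
never enter trait selections. Population assignment is nearest-cell
lookup, consistent with the categorical per-cell semantics of the map —
no interpolation rule is defined for categories.

## Aridity indices and rule tables

The De Martonne aridity index is `IarDM = P / (T + 10)` with `P` annual
precipitation (mm) and `T` annual mean temperature (°C); the constant 10
keeps the denominator positive in temperate climates. The monthly variant
is `IarDMm = 12 Pm / (Tm + 10)`, and the flowering-season index `IarDMf`
averages the monthly indices for March–June, the window in which drought
damages lentil and related legumes most. Twelve identical months
reproduce the annual index exactly, which the tests verify numerically.
The index is left undefined for `T <= -10` °C: records there raise a
domain error and must be flagged by the caller, not clamped — no site in
the package's intended scope approaches that temperature, but the
contract is total. In the monthly formula the precipitation symbol is
read as *monthly* precipitation; a config flag documents the alternative
reading rather than guessing silently.

Three rule tables classify sites. All interval bins are left-closed and
right-open, consistent with the printed aridity bounds (`10 <= I < 20` is
semi-arid, so exactly 10 is semi-arid and exactly 60 per-humid):

* aridity: `[0,5)` deserts/extremely arid, `[5,10)` semi-desert/arid,
  `[10,20)` semi-arid, `[20,30)` sub-humid, `[30,60)` humid, `>= 60`
  per-humid;
* topsoil texture, evaluated in fixed order with the first match winning:
  Clay (clay ≥ 40, sand ≤ 45, silt < 40), Silty Clay (clay ≥ 40,
  silt ≥ 40), Sandy Clay (clay ≥ 35, sand > 45), Silty Clay Loam
  (27 ≤ clay < 40, sand ≤ 20), else Other. The predicates never overlap
  on the 1%-step composition grid (verified exhaustively against a
  brute-force oracle), but the order is fixed for safety. Compositions
  must sum to 100 ± 2%, a tolerance absorbing rounding in soil databases;
* topsoil salinity by electrical conductivity (dS/m): `[0,2)` non-saline,
  `[2,4)` slightly, `[4,8)` moderately, `[8,16)` strongly, `>= 16` very
  strongly saline.

## Environmental filtering

Each trait applies threshold rules, ranks the survivors, and caps the
subset at 30 populations while keeping ELC categories proportionally
represented:

* **drought** — `IarDM < 15` and `IarDMf < 15` (strict, "below 15"),
  ranked from most to least arid during flowering; ties broken by the
  annual index, then population id;
* **salinity** — conductivity `> 4` dS/m (moderately saline or higher);
  if no population qualifies, a fallback tier selects `2 < ec < 4`
  (slightly saline) and the result records which tier fired;
* **waterlogging** — poorly drained texture (Clay, Silty Clay, Sandy
  Clay, Silty Clay Loam) and `IarDM > 25` (strict), ranked from most
  humid down.

Capping uses largest-remainder (Hamilton) rounding of per-category
quotas, with remainder ties resolved toward the larger category and then
the smaller category id, and each quota filled with its category's
best-ranked members. Hamilton rounding minimizes the total absolute
deviation from exact proportionality (the test suite checks this against
a brute-force minimizer over all feasible allocations); a category whose
proportional share rounds to zero therefore receives no member. Filters
are order-stable — applying the criteria jointly or sequentially yields
the same set — and populations without a usable ELC category never enter
a selection.

## Calibration

Evaluated accessions carry a Disease Severity Rating (DSr, 0–100, low =
resistant). `binarize_dsr()` labels as resistant the accessions strictly
below the empirical first-decile threshold (type-7 quantile, linear
interpolation). The strict inequality matters: with boundary ties a weak
inequality would inflate the resistant class beyond the decile, and the
label is meant to capture maximal resistance only. Alternative cutoffs
(e.g. 17%, 35%, 50%) are one parameter away for traits that resist
modeling.

`train_suite()` evaluates nine presence/absence algorithms — GLM, GAM,
GBM, CTA, ANN, FDA, MARS, RF and SRE — over `n_runs` (default 100)
stratified 75/25 train/test splits. Stratification is a deliberate
choice: an unstratified split can empty the rare resistant class
(`stratify = FALSE` is available). Both classes receive equal total
weight regardless of prevalence. For each run the suitability cutoff is
the threshold maximizing the True Skill Statistic
(`TSS = sensitivity + specificity − 1`) on the *training* predictions,
and the run's TSS is then scored on the held-out 25% at that fixed
cutoff. TSS is prevalence-independent and symmetric under class swap.
Mean TSS per algorithm is binned into the conventional five performance
classes (Fail < 0.2 ≤ Poor < 0.4 ≤ Fair < 0.6 ≤ Good < 0.8 ≤ Excellent).

Algorithm implementations ride on the field-standard engines where one
exists (binomial GLM; penalized smooths via `mgcv`; gradient boosting via
`xgboost`; CART via `rpart`; single-hidden-layer perceptron via `nnet`;
random forest via `randomForest`). Flexible discriminant analysis is
linear discriminant analysis on a natural-spline basis expansion with
equal priors; the MARS-style learner is a compact forward selection over
hinge bases with a generalized-cross-validation stop, fit by weighted
least squares on the 0/1 response. The surface range envelope predicts
presence only inside the per-variable 2.5th–97.5th percentile box of the
training presences, with suitability the fraction of variables inside.
Hyperparameters live in one auditable `params` block; none is tuned per
dataset.

Permutation importance of a fitted run shuffles one predictor at a time
(100 permutations by default), averages the predictions over the
shuffles, and reports one minus the Pearson correlation with the
intact-data predictions, clipped to [0, 1]. A variable the model never
consults scores exactly 0; a constant-prediction model scores 0
everywhere.

`select_and_project()` ranks algorithms by mean TSS and reports the top
three with their best runs' importance tables. The final pick is
deliberately not fully automatic: a model dominated by a variable that is
not biologically meaningful as a lone mechanism (longitude is the
classic case) can be excluded via `exclude_variables`, and `choose`
overrides the pick entirely — model choice among near-tied algorithms is
a judgment call and the package surfaces the evidence rather than
burying it. The chosen algorithm's highest-TSS run is refitted
deterministically from its recorded seed, suitability is projected as
the predicted probability scaled to 0–1000, and populations strictly
above the run's cutoff are labelled resistant; the top 30 resistant
populations by suitability form the candidate subset. If every
algorithm's mean TSS is below 0.2, the trait is declared unmodelable and
no projection is made — an explicit, honest outcome rather than a
degraded map.

## The synthetic generator

`synthetic_truth()` fixes everything the generator needs and everything a
test needs to check recovery: zones per component (at most 6, matching
the clustering cap), per-zone layer values, the variables that drive
occurrence intensity, the logistic severity link, and noise levels. Its
defaults are the package's fixed study conditions: 624 populations across
four taxa weighted 443:145:29:7, 105 of them genebank-held, 351
rust-type and 204 broomrape-type evaluations, zone counts (4, 3, 3).

Design choices worth knowing:

* **Zones are contiguous.** Each component partitions the grid into
  axis-aligned bands (a Voronoi option exists) because ELC maps are
  spatial mosaics; shuffled pixels would let any clusterer succeed for
  the wrong reason.
* **Zone centers are mutually equidistant.** Centers sit on a regular
  simplex in standardized variable space (separation 2.5 spreads),
  embedded through an orthonormal frame with equal row norms so every
  layer carries an equal share of the between-zone signal. Equidistant,
  comparably sized clusters produce near-linear wss decay — the regime
  in which the 50%-decrease elbow rule identifies the true count. This
  is a property the rule *requires*, not a convenience: with strongly
  hierarchical cluster geometry the rule understops by design.
* **Monthly climate is derived, not free.** March–June precipitation is
  the annual total times a fixed Mediterranean monthly share times a
  per-zone seasonality factor; monthly temperature sits at the month's
  position within the zone's seasonal range. Independent monthly centers
  would decouple flowering-season aridity from annual aridity, which is
  physically wrong and leaves the drought filter's second criterion
  vacuous.
* **Occurrence sampling.** Cells are drawn with intensity
  `exp(beta * z)` over the informative variables (default: annual mean
  temperature, beta = 1), so those variables genuinely shape the
  realized distribution; `beta = 0` recovers uniform occupancy, which a
  goodness-of-fit test confirms. One percent of cells are a shared
  no-data mask; populations can still occur there (occurrence records do
  not depend on environmental-layer coverage) at the median intensity,
  so a handful of populations land on uncharacterizable sites and
  exercise the exclusion path.
* **Severity.** `DSr = 100 (1 − logistic(eta)) + N(0, 8)`, clipped to
  [0, 100], with `eta` a linear function of standardized site
  environment (default: temperature and radiation). High linear
  predictors mean resistance, so resistance concentrates where the link
  says. Gaussian-then-clip noise was chosen over a Beta model for
  transparent moment control.
* **Seeding.** One master seed fans out into named substreams per stage,
  so any stage can be regenerated independently and bit-identically.

What the generator does *not* emulate: real European climate gradients,
actual *Lens* niche envelopes, spatial autocorrelation beyond zone
structure, observation bias in occurrence databases, or measurement
error in digital soil cartography. Passing the synthetic recovery tests
therefore shows the algorithms are implemented correctly and identify
known structure under their own assumptions — it does not validate any
ecological claim about a real territory.

## Numerical choices and degenerate inputs

* All interval classifications are left-closed; all selection
  comparators are strict, as printed in their sources; both are asserted
  at the boundaries in the tests.
* The binarization quantile estimator is type 7; the TSS-maximizing
  cutoff searches midpoints of consecutive distinct predictions plus the
  extremes, taking the lowest threshold on ties.
* k-means ties and restarts are controlled by seeded substreams;
  MDA ties break lexicographically; drought ranking ties break by
  `(IarDMf, IarDM, pop_id)`.
* Degenerate inputs have defined behaviour: constant layers collapse to
  one cluster; an all-identical DSr vector is a domain error; an empty
  class makes TSS a domain error; algorithm failures within a run are
  recorded and excluded from means with a count, never silently dropped.

## Problem sizes in the tests

The test-suite and the acceptance script run the full pipeline at sizes
chosen to exercise every code path in seconds: grids of 30–60 cells a
side, 150–624 populations, 25 model runs per algorithm (the procedure
per run is identical to the 100-run study design; the mean TSS is simply
averaged over fewer replicates), and 25-seed recovery loops for the
clustering and importance properties. One caveat discovered during
development and worth keeping in mind when interpreting shuffled-label
checks anywhere: with a *single* fixed label permutation and
zone-structured predictors, individual algorithms can genuinely learn
the permutation's chance zone–label associations (per-algorithm mean TSS
fluctuates to roughly ±0.17 at a few hundred records), while the suite
as a whole stays skill-free and below the 0.2 unmodelable bound. Null
checks in this package therefore assert the operational bound (all mean
TSS < 0.2 and the unmodelable verdict) plus a near-zero grand mean,
rather than a tight band per algorithm.

## Known limitations

* The ELC category numbering is deterministic but arbitrary; categories
  are comparable across reruns of the same data, not across datasets.
* Correlation pruning is greedy; it does not find the maximum
  uncorrelated subset.
* The calibration suite shares one train/test split design across
  algorithms but does not do spatial block cross-validation; with
  spatially clustered evaluations, held-out TSS can flatter models.
* No ensemble projection: a single best run is projected, faithful to
  the method this package implements, although ensembles are common
  elsewhere in species distribution modeling.
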