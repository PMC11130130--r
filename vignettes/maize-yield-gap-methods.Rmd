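---
title: "Methods: survey-based yield-gap analysis for smallholder maize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-based yield-gap analysis for smallholder maize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`maizegap` implements a complete analysis chain for field-level maize survey
data from smallholder systems in Sub-Saharan Africa: data cleaning,
agro-climatic stratification, per-zone identification of yield-improving
management practices with conditional inference trees, a mixed-model
comparison of technology levels, extrapolation safeguards, and a 2050
self-sufficiency scenario model. This vignette explains the statistical
machinery, the tunable parameters, and the design decisions taken where the
design was genuinely open. Everything described here is exercised by the
package's tests or by the drivers under `analysis/`.

## The scientific problem

Farm surveys record yields together with management practices (cultivar
type, fertilizer rates and placement, plant density, sowing date, weeding,
pest control) and are observational: practices correlate with each other and
with the environment. The analysis therefore (i) stratifies fields into
climate zones so that within-zone comparisons share a biophysical
background, (ii) uses permutation-test-based recursive partitioning, which
only splits on statistically significant associations, to identify the
practices that explain within-zone yield variation, and (iii) quantifies
the joint yield benefit of adopting bundles of improved practices with a
mixed model that absorbs residual zone and year variation.

## Synthetic survey generator

The generator (`truth_spec()`, `generate_survey()`) is a first-class module,
not a fixture: it draws surveys whose statistical structure matches what the
analysis assumes, with a known truth, so parameter recovery is measurable.

* **Yield model.** On the square-root scale (the scale on which field-yield
  residuals are approximately normal),
  `sqrt(yield) = b0 + effects(management) + u_zone + u_year + e`, truncated
  at zero and squared. Zone and year intercepts are Gaussian with SDs 0.15
  and 0.10 (sqrt scale) and the residual SD defaults to 0.15. The draws of
  the zone and year intercepts are centred to sum to zero: without
  centring, the finite number of years (7) leaves an O(sd/sqrt(K)) offset
  absorbed into the estimated intercept that no estimator can remove, and
  recovery of the *population* level means would be unmeasurable. The
  residual SD is deliberately on the low side of field experience, so that
  technology explains most within-zone variation; what passing tests show
  about noisier real surveys is correspondingly weaker (see Limitations).
* **Effects.** The four level-defining practices act through step responses
  at the published category boundaries (hybrid vs OPV; N above 42 kg/ha;
  density above 4 plants/m2; sowing more than 9 days early), plus a hybrid
  x high-N synergy term: the benefit of a hybrid is largest under high N
  supply. The step decomposition makes the expected yield of each
  technology level exactly specifiable: with the default targets 1.8 / 2.9
  / 3.6 / 4.3 t/ha the baseline-to-HN step on the sqrt scale is split 45%
  hybrid main effect, 30% high-N main effect, 25% synergy, and the higher
  steps are the density and early-sowing effects. Because every level above
  baseline combines hybrid with high N, the split does not move the level
  means. Optional linear slope terms (default 0) are available when smooth
  dose-response structure is wanted. Real response curves are of course
  smooth and saturating; the step shape is a deliberate idealization that
  gives the trees a sharp recoverable signal.
* **Practice distributions.** Practices are drawn from a latent
  adoption-class mixture (traditional / improved nutrition / + density /
  + early sowing / mixed) because adoption is bundled in these systems —
  programme farmers tend to adopt hybrid seed, fertilizer, density and
  timing together. This yields realistic co-adoption and gives each
  technology level roughly 8-9% of fields.
* **N-P correlation.** N and P rates are right-skewed and strongly
  correlated (target Pearson r = 0.72). P is generated from a latent
  log-scale regression on log N (slope 0.75 for the default target; the
  slope-to-correlation map was calibrated once by simulation and is
  interpolated for other targets).
* **Missingness** is missing-completely-at-random per column, with default
  rates of 2-10% on the columns that are incomplete in real deposits. This
  is the simplest mechanism consistent with per-column missing counts;
  informative missingness is out of scope.
* **Coordinates** are Gaussian clusters per zone inside region bounding
  boxes, with a small rate (0.4%) of planted remote sites to exercise the
  isolation filter. Environmental covariates carry zone-level structure
  (zone means plus field noise) and no direct yield effect: their influence
  in real data is absorbed here by the zone intercept.

`truth_summary()` returns the expected yield per technology level in closed
form (exact for the default step truth) or by Monte-Carlo on the generator's
own linear predictor; the two agree to 0.01 t/ha at n = 10^6 and the tests
assert it. The reporting convention is `(E[sqrt yield])^2` at zero random
effects, matching the mixed model's back-transform; an optional
retransformation correction adds the total random variance.

## Quality control

`apply_qc()` applies, in a fixed order with first-match-wins attribution:
Bonferroni-adjusted studentized-residual outlier detection on yields
(reference model configurable, default one intercept per region), plant
density and fertilizer rates above `min(mean + 4 SD, cap)` with hard caps of
12 plants/m2 and the elemental equivalents of 400 kg/ha of product (184 kg
N/ha, 80 kg P/ha), missing geolocation, missing N or P, and atypical sowing
dates (|deviation| > 60 days by default; the cutoff is a documented choice,
since "atypical" is not defined quantitatively in survey protocols). The 4-SD
thresholds are computed on the sample with complete geolocation and nutrient
data and then frozen, which makes the operation idempotent and the removal
report exactly reconcilable (`n_in = n_out + sum(removed)`).
`fertilizer_to_nutrients()` converts product amounts with a typical
composition table; phosphorus is elemental P, not P2O5.

## Climate zones

Zonation uses three bioclimatic indices — annual growing-degree days (base
0 C), aridity index (precipitation / PET) and temperature seasonality (SD of
monthly means x 100, the bio4 convention; a plain-SD convention is
available) — binned by a configurable scheme of class edges
(`inst/extdata/zone_scheme.yaml`). The shipped edges approximate the global
yield-gap atlas zonation (1000 C-day GDD classes, aridity classes densified
in the semi-arid range); they are configuration, not code, because the
published scheme's exact re-delineated edges are not printed anywhere, and
results should be reported alongside the scheme used. Bins are half-open
`[lo, hi)` — a value exactly on an interior edge goes to the upper bin — and
refining edges can only subdivide zones, never rearrange them.

Within each zone, sites more than three standard deviations above the zone
median of per-site median great-circle distances are dropped
(`filter_isolated()`; haversine distances, since fields span degrees of
latitude). Strata are zone x season combinations (two-season regions
contribute two strata per zone), eligible only with strictly more than 200
fields. Sowing deviations are taken about the stratum mean; strata whose
dates span the December/January boundary use a circular mean.

## Conditional inference trees

The tree module is implemented from first principles because the
permutation-test partitioning *is* the analytical core:

* **Association test** (`association_pvalue()`): a standardized linear
  statistic under the permutation null. For numeric, ordered and logical
  predictors the statistic is the squared standardized cross-product
  (equivalently `(n-1) r^2`), referred to N(0,1) via its signed root; for
  factors with k levels it is the quadratic form `(n-1) SSB/SST`, referred
  to chi-square with k-1 degrees of freedom. Tests are case-wise on
  non-missing pairs; a constant predictor gives p = 1 by convention. A
  Monte-Carlo option permutes the response (`n_perm` draws, add-one
  estimator); tests verify it against full enumeration at n = 7.
* **Variable selection** (`select_split_variable()`): Bonferroni adjustment
  of the minimum p-value across the candidates testable at the node — the
  conservative default of the conditional-inference framework; ties break
  by declared candidate order, so duplicated columns resolve
  deterministically.
* **Split search** (`best_split_point()`): for numeric predictors, the cut
  maximizing the standardized two-sample statistic over all feasible
  boundaries (each child at least `min_bucket` non-missing cases), with the
  cut placed at the midpoint of adjacent distinct values; for factors, the
  exact best binary level partition found via the sorted-group-means
  reduction. Both equal exhaustive search, which the tests assert on small
  inputs.
* **Stopping rules** (`cit_params()`): split significance alpha = 0.01,
  maximum depth 10, intermediate nodes above 20% of the observations (200
  when the initial n exceeds 1000), terminal nodes above 5% (or 50); the
  low-n variant (alpha = 0.1, 10 / 8) serves sparse regions. Lowering alpha
  can only shrink a tree.
* **Missing values** route to the child holding the majority of non-missing
  cases (recorded per node); there are no surrogate splits. This is the
  simplest auditable rule; the framework literature leaves the policy open,
  so it is configurable in the sense of being isolated in one place.
* With all-null predictors the familywise probability of any split is held
  at alpha (verified by simulation with a binomial confidence band), and
  with the asymptotic test the whole procedure is deterministic.

**Importance** (`relative_importance()`): a practice counts as significant
in a zone when it appears as a split variable anywhere in the zone's tree;
relative importance is the share of zones where that happens. The default
denominator counts only zones where the practice is evaluable (at least two
observed values) — a zone planted entirely with hybrids cannot show a
cultivar effect; the all-zones denominator is available for comparison.
Type shares aggregate practice importances into nutrients / cultivars /
establishment / pest management within regions.

A note on pooled analyses: when zones are pooled, zone-structured
environmental covariates are confounded with the zone intercepts and will
legitimately dominate a tree's splits. The stratified analysis is the place
where covariates belong; pooled trees in the tests therefore use management
candidates only.

## Technology levels and the mixed model

`assign_level()` groups fields into baseline (OPV, low N, low density,
average-or-late sowing), hybrid + high N, + high density, and + early
sowing, using the published fixed boundaries by default (low N < 14, high N
> 42 kg/ha; low density < 3, high density > 4 plants/m2; early more than 9
days before the zone average; late a deviation of at least 0). A
tercile-based variant derives the boundaries from the pooled data
(quantile type 7, documented because tercile edges shift across quantile
conventions); middle-category or incomplete fields are unclassified.

`fit_sqrt_lmm()` fits, by REML (the standard choice for variance components
with few grouping levels),

    sqrt(yield) ~ tech_level + (1 | zone) + (1 | year)

with crossed random intercepts (the model lists them additively, not
nested). `marginal_means()` evaluates each level at zero random effects and
squares, with delta-method standard errors (`se = 2 |m| se_m`); the
retransformation variance correction is available but off by default, since
squared conditional means are the group-yield reporting convention.
Averaging over estimated random-intercept levels instead of setting them to
zero is a near-no-op here because estimated intercepts are centred; the
zero-random-effect evaluation is the documented default.
`level_contrasts()` reports ratios, percent gains and absolute differences
against baseline.

## Scenario model

`scenario_table()` computes, per scenario, production = yield x area (area
fixed at 40 Mha), SSR = production / demand, balance = production − demand,
and the extra land needed to cover a deficit at the scenario's own 2050
yield, `max(0, −balance) / yield` — the convention that reproduces whole-Mha
land requirements from rounded deficits. All identities hold exactly at
full precision; `round_scenario_table()` applies presentation rounding only
(yields and SSR to one decimal, Mt and Mha to integers). Current production,
demand and yield are external statistics taken as configuration
(`inst/extdata/ssa2050.yaml`), as are the 2050 demand, the historical gain
rate of 0.027 t/ha/yr and the yield potential of 10.6 t/ha. The same-rate
2050 yield is configured at its published value (2.7 t/ha) rather than
recomputed, because the underlying base-year inputs are carried at higher
precision in the source material than the printed 2.0 t/ha starting yield
(2.0 + 0.027 x 30 = 2.81); the linear projector is available and tested for
explicit use.

## Extrapolation safeguards

* **Spatially matched folds** (`nndm_folds()`): candidate fold structures
  are k-means clusterings of the coordinates with q = k..Q clusters
  greedily merged into k balanced folds (q = k gives pure spatial blocks,
  large q approaches a random split), plus a plain random split. The
  winner minimizes the Wasserstein-1 distance (computed on a percentile
  grid) between its test-to-training nearest-neighbour distances and the
  target distribution of prediction-to-training distances. By default the
  prediction locations are the sample itself (leave-one-out target), under
  which spatially unstructured data selects an essentially random split;
  passing a prediction grid that extends beyond the sampled clusters makes
  blocked folds win, which is the honest-validation use case.
* **Dissimilarity index** (`di_config()`, `dissimilarity_index()`): weighted
  Euclidean distance on standardized environmental variables to the nearest
  reference field (weights, typically model importances, normalized to sum
  to one and applied as sqrt-weight axis scalings), divided by a reference
  statistic. The default unit is the mean leave-one-out nearest-neighbour
  distance of the reference set, which is self-calibrating (reference
  points score 0, the cloud averages exactly 1); the mean-pairwise-distance
  unit of the area-of-applicability literature is available and is the
  sensible choice when thresholding map predictions at 40%, under which
  in-distribution points score well below the threshold. Applicability is
  strict: a point exactly at the threshold is outside.
* **SHAP contract** (`fit_yield_gbm()`, `shap_additivity_check()`): boosting
  and attribution delegate to xgboost; the module owns the contract that
  the base value plus per-feature attributions reproduces each prediction.
  Boosted-tree leaf values accumulate in single precision, so the identity
  holds to an absolute error proportional to the prediction magnitude; the
  response is therefore centred and scaled to half-unit SD before training
  (inverted on prediction, attributions rescaled to t/ha) and the default
  ensemble is modest (60 rounds, depth 4, learning rate 0.2), keeping the
  worst-case residual below the 1e-6 tolerance on the model scale.

## Problem sizes and determinism

The test-suite simulations use the generator's default study conditions:
25 zones x 200 fields (n = 5000) for mixed-model recovery (100 replicates)
and importance ranking (50 replicates), 10 zones x 200 (n = 2000) for the
pooled interaction check, n = 500 with 20 null predictors and 1000
replicates for the familywise-error simulation, and n <= 8 for the
enumeration oracles. Every stochastic component takes an explicit seed; the
tree growing itself is deterministic with the asymptotic test. The whole
suite and the acceptance script each run in a few minutes on one CPU.

## Limitations

* The generator's step-shaped dose responses and low residual noise are
  idealizations: passing recovery tests demonstrates correctness of the
  estimators under the assumed structure, not robustness to the messier
  confounding, measurement error and informative missingness of real
  surveys.
* The deposited field database is not bundled; `load_deposited()` maps a
  user-downloaded copy onto the survey schema and fails with download
  instructions otherwise. Checks against the real-data group means are
  gated on that download.
* Raster acquisition (climate, soil, terrain), crop-model yield potentials
  and crop calendars are out of scope; the relevant quantities enter as
  numeric inputs.
* The conditional inference trees use asymptotic reference distributions by
  default; exact multivariate permutation distributions for multi-df
  statistics are not implemented (Monte-Carlo approximation is).
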