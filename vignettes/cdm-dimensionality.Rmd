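---
title: "Assessing the dimensionality of cognitive diagnosis data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the dimensionality of cognitive diagnosis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmdim)
```

## The problem

Cognitive diagnosis models (CDMs) are restricted latent class models for
dichotomous test data. Each of `K` latent *attributes* is a binary skill, so
respondents fall into one of `2^K` attribute profiles, and a binary `J x K`
Q-matrix declares which attributes each item measures. Every Q-matrix
estimation or validation method assumes that `K` itself is known — yet in
practice `K` is exactly what an analyst has to decide first. cdmdim implements
a toolbox for that decision: classical factor-analytic dimensionality
statistics adapted to dichotomous data, a model-comparison procedure built on
empirical Q-matrix estimation, a calibrated Monte Carlo simulator to study all
of them, and the accuracy metrics used to summarize such studies.

## The measurement models

Under the DINA model an item has a guessing parameter `g_j` and a slip
parameter `s_j`; respondents mastering all required attributes succeed with
probability `1 - s_j`, everyone else with probability `g_j`. The saturated
G-DINA model instead gives every *reduced latent group* (each combination of
the item's required attributes) its own success probability, equivalently
written as an intercept plus main effects plus interaction terms (the delta
parameterization; `prob_to_delta()` and `delta_to_prob()` convert between the
two exactly).

`fit_em()` estimates either model by marginal maximum likelihood with an EM
algorithm over the full `2^K`-class space: the E-step computes posterior class
membership from the current probability tables and class weights, the M-step
replaces each reduced-group probability with its expected-count success
proportion and the class weights with posterior means. Design choices:

* **Initialization.** Item probabilities start at the observed item mean plus
  uniform jitter (half-width 0.05), with reduced groups ordered by the number
  of mastered attributes; class weights start uniform. Deterministic under a
  seed.
* **Convergence.** Maximum absolute change of any parameter below `1e-4`, or
  1000 iterations; the `converged` flag is honest. Probabilities are clamped
  to `[1e-4, 1 - 1e-4]`, and a reduced group with vanishing expected count
  keeps its previous value (boundary smoothing) and increments a warning
  counter.
* **Likelihood-stall stop.** `fit_em(loglik_tol = ...)` optionally also stops
  when one iteration improves the log-likelihood by less than a threshold.
  This is disabled by default; `mc_select()` enables it at 0.01 because the
  candidate scan consumes only maximized log-likelihoods, which stabilize long
  before the parameters do on the flat ridges of overspecified candidates. On
  a stratified bench of eleven conditions this cut the slowest scan from 151 s
  to 37 s without changing any AIC selection.
* **No monotonicity constraint during estimation.** Monotonicity is imposed in
  the generator only; estimation is unconstrained.
* **Canonical class order.** Binary counting with attribute 1 as the
  fastest-varying bit, fixed everywhere (posteriors, weights, probability
  tables).

## The synthetic-data generator

`gen_dataset()` reproduces a fully crossed simulation design
(`sim_conditions()`, 972 cells): attributes `K in {4, 5, 6}`, item quality
`IQ in {0.40, 0.60, 0.80}`, sample size `N in {500, 1000, 2000}`, items per
attribute `JK in {4, 8}`, attribute correlation `AC in {0, 0.30, 0.60}`,
threshold range `AT in {0, 0.50, 1}`, and generating model DINA or G-DINA.
These defaults *are* the study conditions; they are not tuning knobs.

* **Attribute profiles** are thresholded equicorrelated multivariate normal
  draws; thresholds run equidistantly from `-AT` to `AT`, so roughly half the
  attributes are easier and half harder.
* **Q-matrices** are rejection-sampled under four constraints: two embedded
  identity blocks, at least one further item per attribute, all pairwise
  column Pearson correlations below 0.50, and one-/two-/three-attribute item
  proportions of 0.50/0.40/0.10 (rounded; the one-attribute count never drops
  below `2K`, so the identity blocks always fit). The identity blocks sit at
  random row positions — the constraints say nothing about where.
* **Item quality** bands: `P(0) ~ U(0, .2)` and `P(1) ~ U(.8, 1)` for
  high-quality items, `U(.1, .3)`/`U(.7, .9)` for medium, `U(.2, .4)`/`U(.6,
  .8)` for low, giving expected quality `P(1) - P(0)` of 0.80/0.60/0.40. For
  G-DINA multi-attribute items the intermediate group probabilities are drawn
  uniformly between `P(0)` and `P(1)` and re-drawn until (i) group mean
  success is non-decreasing in the number of mastered attributes and (ii) the
  per-attribute delta sum — main effect plus every interaction containing the
  attribute — exceeds 0.15. "Associated with an attribute" is read as
  including interactions; that keeps every attribute materially relevant.
* **Responses** are independent Bernoulli draws from the class probability of
  each person's profile.
* **Reproducibility.** One RNG stream per dataset, keyed by (master seed,
  condition id, replicate) with replicate counts up to 100; results are
  identical regardless of evaluation order or method subset, because the
  assessment step is re-seeded per method.

What the generator does *not* emulate: missing data, polytomous responses,
higher-order or non-equicorrelated attribute structures, item-quality
heterogeneity beyond the uniform bands, and model misspecification between
generation and estimation. Passing tests therefore speak to method behavior
under clean CDM data of this family, not to robustness beyond it.

## Dimensionality statistics

All methods return a `dim_suggestion` (the suggested count plus the full
diagnostic curve), and all are restricted to at most 9 candidate dimensions by
default, leaving room to overestimate the largest generated `K`.

* **Parallel analysis** (`parallel_analysis()`): principal-components
  eigenvalues of the Pearson or tetrachoric correlation matrix against
  reference eigenvalues from 100 copies of the data with every column
  independently permuted (preserving the univariate margins); mean or 95th
  percentile criterion; retention by the leading run of sample eigenvalues
  above their references, stopping at the first failure (0 is possible). The
  tetrachoric variants recompute tetrachorics on every permuted copy.
* **MAP** (`map_velicer()`): average squared off-diagonal partial correlation
  after partialling out `m = 0 ... 9` principal components; the minimum
  locates the dimensionality. Squared — not fourth-power — partials.
* **VSS** (`vss()`): for each candidate `K`, extract and oblimin-rotate, keep
  the `v` largest absolute loadings per item, and measure
  `1 - MS(residual)/MS(observed)` over off-diagonal correlations; the maximum
  locates the dimensionality. Complexities `v = 1` and `v = 2`.
* **DETECT** (`detect()`): conditional covariances of item pairs given the raw
  total score, Ward clustering (`ward.D2`) on the dissimilarity `max(C) - C`,
  and the classical index — the mean signed conditional covariance, positive
  within clusters — maximized over the nested partitions with 1 to 9
  clusters (a full partition search is exponential). Two conventions deserve
  a note: conditioning on the total score leaves small negative conditional
  covariances on essentially unidimensional data, and the classical index
  does not center them, which is precisely what gives DETECT its documented
  tendency to prefer finer partitions. A mean-centered, rest-score variant
  (`score = "rest"`, `center = TRUE`) is available; it behaves noticeably
  more conservatively.
* **EKC** (`ekc()`): sample eigenvalues of the tetrachoric matrix against
  Marchenko-Pastur-derived references, each coerced to at least 1; at the
  population level this reduces to the Kaiser-Guttman rule.

## Q-matrix estimation, validation, and model comparison

* **DFL** (`dfl_estimate()`): factor-analyze the tetrachoric matrix
  (principal axis with communality clamping for Heywood robustness; oblimin
  rotation by oblique gradient projection with the quartimin criterion), take
  absolute loadings, and set `q_jk = 1` when the loading reaches the row mean.
  Non-positive-semidefinite tetrachoric matrices are smoothed by eigenvalue
  clipping at `1e-6` and rescaling to unit diagonal.
* **Hull/PVAF** (`hull_validate()`): one EM fit under the provisional
  Q-matrix; saturated per-item class success probabilities estimated
  nonparametrically as posterior-weighted success proportions (no refit per
  candidate). For each item and each candidate size `t`, the best candidate by
  PVAF — the weighted variance of the collapsed class probabilities over the
  weighted variance under all `K` attributes — enters a convex hull over
  `(2^t, PVAF)` points anchored at `(1, 0)`; the retained q-vector maximizes
  the ratio of adjacent hull slopes. If only one non-anchor vertex survives,
  it is retained directly.
* **MC procedure** (`mc_select()`): for every candidate `K` from 1 to 9,
  DFL-estimate, Hull-validate, fit the CDM, and record `-2LL`, parameter
  count, AIC, BIC and the number of items with at least one significant
  pairwise Fisher-z correlation residual (Bonferroni-corrected at the item
  level, `alpha/(J - 1)`; proportion-correct and log-odds-ratio residuals are
  computed and reported but do not drive selection). AIC and BIC select their
  minimum; the residual criterion selects the most parsimonious candidate
  with the lowest flagged count; all ties break toward smaller `K`. The
  upper-limit variants substitute (or add) the generating Q-matrix via
  `Q_override`.
* **Combination rules** (`combine_rules()`): retain when all or any two
  methods agree; otherwise explore the close (within one attribute) or, at
  worst, all suggested counts. An externally computed suggestion (e.g. a
  machine-learning prediction) enters as just another named element.

## Numerics worth knowing

* **Tetrachoric correlations** are two-step pairwise maximum likelihood:
  thresholds fixed at the univariate margins, then the profile score in the
  latent correlation solved by vectorized bisection (the score is strictly
  decreasing in rho). The bivariate normal CDF integrates the bivariate
  density along the correlation path with 32-node Gauss-Legendre quadrature.
  Zero cells get a 0.5 continuity correction; estimates are bounded at
  |rho| = 0.9999. The test suite pins this against an independent grid-search
  oracle that computes the CDF by a different route.
* **Degenerate inputs.** Zero-variance items are an error naming the item;
  non-discriminating items in Hull fall back to the simplest q-vector; an
  all-`-Inf` likelihood row yields `-Inf` rather than a crash.

## Scaled replication and problem sizes

The package's accuracy claims are checked by scaled-down replication: the
acceptance script runs the full 972-cell design with 3 replicates for the
cheap statistics (parallel analysis, DETECT), and the test suite uses balanced
systematic subsets of the design — every `step`-th condition with `step`
coprime to 6, which cycles through all factor levels — sized at 89 conditions
x 2 replicates for the cheap methods, 75 conditions for Q-matrix recovery,
and 52 conditions for the model-comparison procedure (whose nine EM fits per
dataset make it the heaviest component). Metrics computed on subsets this
small carry binomial noise of a few percentage points; the tolerances in the
tests reflect that.

## Known limitations

* The model-comparison procedure estimates the same model family that
  generated the data (as in the study it replicates); applied analyses should
  prefer the saturated G-DINA throughout.
* The model-comparison selection inherits the quality of the empirical
  Q-matrices: a handful of wrong q-entries at the true dimensionality leaves
  structure for richer candidates to absorb, so AIC occasionally overshoots
  by one or two attributes (most visibly at `K = 4` with correlated
  attributes). With the generating Q-matrix supplied via `Q_override` this
  effect disappears, which is exactly the upper-limit comparison the harness
  exposes.
* Hit rates for methods that may legitimately answer 0 (PA, EKC, MAP) count 0
  as a miss; method failures are logged as missing suggestions, not misses.
* The factor-forest and network (EGA) approaches are out of scope; the
  combination rules accept their suggestions as external inputs.
* `qrr()` aligns columns by exhaustive permutation and is limited to `K <= 8`.
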