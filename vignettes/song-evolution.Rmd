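---
title: "Methods: comparative analysis of song evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of song evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models it fits, the defaults it chooses and why, what the synthetic-data
generator does and does not emulate, and the numerical decisions that make
results reproducible. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Across a radiation of species, song structure may evolve under direct
habitat-dependent selection on transmission (closed vegetation favouring
slower, lower, narrower-band songs), indirectly through morphology (body
size constrains frequency; beak size and the beak's moment of inertia
constrain how fast the vocal tract can be reconfigured, hence pace and
performance), or simply drift along the phylogeny. Separating these signals
requires (i) species-level acoustic summaries, (ii) a performance statistic
for the pace-bandwidth trade-off, (iii) regression models whose residuals
respect phylogenetic covariance, and (iv) a model-comparison framework that
weighs habitat against morphology against a constant (stochastic) baseline.

## Performance frontier and vocal deviation

Trilled song sits in a triangular region of the pace x bandwidth plane:
slow songs may be broad- or narrow-band, fast songs only narrow-band. Two
frontier estimators are implemented.

**Binned maxima** (`upper_bound_regression()`). Pace is cut into half-open
bins `[lo, lo + 2)` Hz (last bin closed); within each nonempty bin the song
with maximal bandwidth is selected; OLS is fitted through the selected
songs' *actual* pace values. Choices:

* Bin width 2 Hz — the conventional grid for this statistic; configurable.
* Regression x-values: the selected song's own pace, not the bin midpoint —
  the selected maxima are real songs and their abscissae carry information;
  `x_value = "midpoint"` is available.
* Ties within a bin: smaller pace wins, then input order. This makes the
  estimator invariant to row shuffling except through the documented rule.
* The bin grid runs from 0 to the ceiling of the largest observed pace, so
  data beyond any fixed grid are never silently discarded.

**Sliding-window percentile** (`percentile_bound()`). A window of width 2 Hz
slides in 1-Hz steps; windows holding fewer than 32 songs are dropped
(quantiles of tiny samples are outlier-driven); the 90th percentile of
bandwidth (linear interpolation, R type 7) per retained window is regressed
on the window centre. Degrees of freedom are reported as
`(1, n_windows - 2)`. Width and step are conventions, not estimates — they
are configuration, reported in the run log, and were not inferred from any
published degrees of freedom.

**Vocal deviation** is the signed orthogonal distance from the frontier
`y = mx + b`: `d = (m*pace - bw + b) / sqrt(m^2 + 1)`, positive below the
line (lower performance), zero on it. The distance is measured in the
frontier's raw mixed units (pace O(10) Hz, bandwidth O(10^3) Hz), matching
how the statistic is conventionally defined; because the bandwidth axis
dominates at these scales, a standardized variant
(`standardize = TRUE`, both axes divided by their standard deviations) is
provided but off by default. Species-level vocal performance is the mean of
per-song deviations; evaluating the deviation at the species centroid
instead (`method = "deviation_of_means"`) is available for sensitivity
checks.

**Aggregation order.** Species song tables take the arithmetic mean of each
variable on the raw scale and then log it (mean-then-log). The alternative
(log-then-mean, i.e. the log of the geometric mean) is exposed via
`order = "log_then_mean"`; by Jensen's inequality it is never larger, and on
low-variance within-species data the two differ negligibly.

## Phylogenetic PCA

With Brownian covariance `V` from the tree, the GLS ancestral mean is
`a = (1'V^-1 1)^-1 1'V^-1 X` and the evolutionary covariance
`R = (X - 1a)' V^-1 (X - 1a) / (n - 1)`. Components are eigenvectors of `R`
(covariance mode) or of `cov2cor(R)` (correlation mode); scores project the
centred (and, in correlation mode, standardised by `sqrt(diag(R))`) traits
onto the eigenvectors.

* **Mode default: correlation.** The seven log song traits mix scales
  (log Hz, log s, log counts); a correlation-type analysis keeps loadings in
  `[-1, 1]` and prevents any single variance from dominating. Covariance
  mode is available.
* **Sign convention:** each eigenvector is flipped so its largest-|loading|
  variable loads positively — eigenvectors are sign-ambiguous and a fixed
  convention makes output reproducible.
* **No within-PPCA signal estimation:** `V` is plain Brownian. An optional
  Pagel's lambda pre-transform (`lambda =`) is exposed but off by default.
* **Retention:** components with eigenvalue > 1 (Kaiser criterion).
* Vocal deviation is never an input trait — it is derived from pace and
  bandwidth, which are already in the table.
* On a star tree (equal branch lengths) every formula above collapses to
  ordinary PCA; the test suite verifies this equivalence to 1e-8, and
  `phytools::phyl.pca` serves as an independent cross-check.

In the pipeline, PPCA scores for downstream regression are computed once
from the consensus tree; recomputing per posterior tree is possible by
calling `phylogenetic_pca()` per tree but is not the default, so that the
response variables stay fixed while only the error covariance varies across
trees.

## PGLS with branch-length transformations

Each model is `y = X beta + e`, `e ~ N(0, sigma2 * V(theta))`, fitted by
maximum likelihood via Cholesky whitening — never an explicit inverse. The
five covariance families:

| family | parameter | bounds | construction |
|---|---|---|---|
| BM | — | — | `V[i,j]` = shared root-to-MRCA path length |
| lambda | λ | [0, 1] | off-diagonals of `V` times λ |
| kappa | κ | [0, 3] | branch lengths raised to κ, then `V` rebuilt |
| delta | δ | [0, 3] | entries of `V` (node depths) raised to δ |
| OU | α | [1e-8, 50/height] | `exp(-α d_ij) (1 - exp(-2α t_ij)) / (2α)` |

Notes on the less standard corners:

* The **delta** transform powers the MRCA depths entrywise without the
  height-preserving rescaling some implementations add; rescaling only
  multiplies `V` by a constant, which the ML `sigma2` absorbs, so fits and
  AICc differences are unaffected.
* The **OU** family is the single-optimum, root-at-optimum covariance
  (`d` = patristic distance, `t` = MRCA depth). As α → 0 it converges to
  the Brownian matrix (the implementation uses `expm1` so this limit is
  numerically stable), and at large α its correlation decays as
  `exp(-α d)`, the familiar exponential-decay structure. The α upper bound
  50/height makes the correlation matrix numerically diagonal at the
  boundary; bounds are configurable.
* The transform parameter is estimated by **profile likelihood**: the exact
  GLS solution at each candidate value, initialised on a 5-point grid and
  refined by bounded scalar search to 1e-6; estimates within 1e-4 of the
  bounds (relative) are flagged `boundary`. Profile stability across
  restart grids is itself a test.
* **ML, not REML**, throughout: AICc comparisons across different mean
  structures are only valid under full ML.
* **k counts** every design column (intercept included) + 1 for `sigma2`
  + 1 if a transform parameter is estimated. BM fits therefore have k one
  less than the same mean structure under any transform family.
* Predictors are **not standardized** by default, so coefficients stay on
  their log/measurement scales; `standardize = TRUE` rescales non-intercept
  columns to unit SD.
* Missing data: listwise deletion per response; `n` in every fit records
  what was actually used. Outliers are never auto-detected; explicit
  exclusion lists (`exclude_species`) are the only removal mechanism.
* Zero-length terminal branches are permitted; if a Cholesky factorisation
  fails, a ridge of `1e-10 * mean(diag(V))` is added once and logged.
* Trees are used with raw branch lengths (no rescaling to unit height
  before fitting); the generator happens to produce unit-height trees, but
  nothing downstream assumes it.

## Candidate set and multimodel inference

Mean structures combine at most one morphology group — BodySize, BeakSize,
or BeakMoment = (beak size, log beak length) — with at most one habitat
measure — the categorical dummies (closed as reference) or EnvPC1 — to
limit collinearity among predictors that are strongly correlated by
construction. Interactions are allowed with the categorical habitat only
(there is no a-priori prediction for particular values of a climate axis),
and the BeakMoment interaction expands both of its terms. With the constant
baseline: 1 + 3 + 2 + 6 + 3 = 15 structures, crossed with 5 families = 75
fits per response.

* **Weight basis:** Akaike weights are computed jointly over all 75 fits,
  pooling mean structures and covariance families into one ranking — the
  transform is treated as part of the model. `weight_basis = "per_family"`
  is available.
* **Pruning (uninformative-parameter rule):** a model within 2 AICc of a
  better-ranked model whose terms it strictly contains is rejected; the
  top model is never pruned; every pruning decision is logged with the
  dominating model named.
* **95% cumulative-weight set:** smallest weight-sorted prefix reaching
  0.95 (ties by AICc, then stable order). Weights are renormalised over
  the subset before averaging — required for the averages to be convex.
* **Zero-substitution averaging:** every parameter, intercept included, is
  averaged with value 0 where absent. Parameter total weights (the summed
  weights of containing models) are reported alongside.
* **Evidence ratios** are relative to the total weight of the constant
  structure across families; if that weight underflows to zero the ratio
  is infinite and reported censored at 1e6 in the report tables.
* **Across trees:** per tree — fit all candidates, take the 95% set,
  average; then the unweighted mean of per-tree averaged coefficients and
  total weights. The modal top family across trees is reported; transform
  estimates are averaged like coefficients.

## The synthetic-data generator

`simulate_bundle()` provides ground truth for every stage. What it
emulates, with defaults:

* **Tree:** pure-birth, 276 tips, rescaled to unit height; an emulated
  posterior sample perturbs each branch by a mean-one lognormal factor
  (SD 0.1), preserving topology — posterior uncertainty in divergence
  times only, not in topology.
* **Sampling effort:** recordings per species from a lognormal matched to
  mean 6.6 / SD 5.4 and truncated at 1; the real sampling distribution of
  archival recordings is unknown, and the truncated lognormal is the
  simplest right-skewed count model hitting both moments.
* **Morphology:** body size and beak size from correlated Brownian motion
  (target r = 0.8); log beak length tracks beak size with added Brownian
  noise tuned to r = 0.85.
* **Habitat:** a latent Brownian "openness" gradient thresholded at
  prevalences 0.45 / 0.30 / 0.25 (closed / semi-open / open) — a threshold
  model rather than a Markov transition model because it gives direct
  control over the habitat-climate correlation; `env_pc1` is the
  standardised gradient plus Gaussian noise tuned to r = 0.7.
* **Songs:** species-mean log pace = linear predictor (beak and habitat
  effects) + Brownian residual (SD 0.8); species-mean log minimum
  frequency = body-size effect (negative) + Brownian residual (SD 0.25);
  per-recording lognormal scatter around the species means. The grand mean
  log pace of 2.0 with residual SD 0.8 puts the pace distribution's 95%
  range at roughly 2-40 Hz, so the conventional 2-Hz bin grid up to 40 Hz
  is occupied the way the frontier estimator expects.
* **Frontier embedding:** each species has a performance factor
  `f ∈ (0.6, 1]` (uniform; optionally logit-linked to beak size for
  recovery experiments), and each song's bandwidth is uniform on
  `(0, frontier(pace) * f]` with the generative frontier
  `bw = -79.374 pace + 5066.2`. No song can exceed the frontier at its
  realised pace; paces past the frontier's zero crossing are redrawn
  (counted and reported), with a truncated fallback after 200 tries.
  Note counts and durations are back-solved so that recorded pace is
  exactly `n_notes / duration_s`.

What it deliberately does **not** emulate: measurement error in acoustic
features, harmonic structure or amplitude, within-species repertoire
variation, topological uncertainty, climate's spatial autocorrelation, or
non-ultrametric trees. Passing recovery tests therefore demonstrates
correctness of the estimators under the generator's assumptions, not
robustness to all features of real archival data.

All randomness flows from one integer seed; stage seeds are derived
deterministically from it, so an identical configuration yields a
byte-identical bundle and, downstream, a byte-identical report.

## Problem sizes

The test suite and acceptance script size their simulations for
informativeness per unit time: oracle-equivalence checks at n = 50-80,
transform/positive-definiteness sweeps over 20 random trees of 10-150
tips, lambda recovery at 200 tips x 20 replicates, coefficient recovery at
n = 200 x 100 replicates, frontier recovery on 20 default bundles
(~1,800 songs each), the percentile null at n = 1e5 songs, and selection
consistency at 100 species x 20-50 replicates. These scales are the
package's choices; all are configurable in the corresponding functions.

## Known limitations

* The candidate set is fixed to the one-morphology + one-habitat design;
  arbitrary formulas go through `fit_pgls()` directly but not through
  `build_model_set()`.
* Only a single-optimum OU process is offered — no multi-optimum regimes,
  no measurement-error ("lambda-on-residuals-plus-noise") models.
* `prune_uninformative()` compares term sets, not coefficient values; two
  structurally different parameterisations of the same subspace would not
  be recognised as nested.
* The evidence-ratio censoring at 1e6 is a reporting convention; raw
  weights are always available in `full_rankings`.
* Tree-averaging refits every candidate on every tree; with the full 500
  posterior trees and 75 candidates this is an overnight computation at
  276 species, which is why the pipeline default averages across 25 trees
  (configurable via `n_posterior_trees`).
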