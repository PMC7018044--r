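---
title: "Presence-background suitability modelling with flyclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-background suitability modelling with flyclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyclim)
```

## The problem

Pest risk mapping for insects such as tephritid fruit flies asks a simple
question with a messy evidence base: given where a species has been
recorded, and gridded climate surfaces for today and for an ensemble of
future climate scenarios, which parts of a territory have climate that
could support the species? Occurrence records are presence-only — there are
no reliable absences — so the standard tool is a presence-background
species distribution model, with downstream steps that turn continuous
suitability into maps decision-makers read: binary suitable/unsuitable
layers, agreement across climate scenarios, and multi-species "hotspot"
counts.

`flyclim` implements that whole chain, together with a virtual-species
simulator, so every stage can be exercised and verified end to end on data
whose ground truth is known.

## The model

The fitted object is a Gibbs distribution over the cells of the modelled
landscape. Each cell $x$ carries a feature vector $f(x)$ built from the
climate variables $v$: linear terms $v$, quadratic terms $v^2$, and
pairwise products $v_a v_b$ (first-order interactions). Products are
formed on the raw variables and every feature column is affinely rescaled
to $[0,1]$ using its minimum and maximum over the background cells. The
model assigns

$$P(x) \propto \exp\big(\lambda^\top f(x)\big),$$

and the weights maximize the penalized presence-background log-likelihood

$$L(\lambda) = \frac{1}{m}\sum_{i\in\text{presences}} \lambda^\top f(x_i)
  \;-\; \log\!\!\sum_{x\in\text{landscape}}\! e^{\lambda^\top f(x)}
  \;-\; \sum_j \beta_j |\lambda_j|,$$

where the landscape is the union of the background sample and the presence
cells. This is the classical maximum-entropy ("Maxent") formulation: the
optimum is the distribution of maximum entropy among those whose feature
expectations match the presence means to within the per-feature budgets
$\beta_j$ (the KKT conditions of the L1 penalty).

### Regularization

The penalty follows the schedule
$\beta_j = r \cdot c \cdot s_j / \sqrt{m}$, with $r$ the user-facing
regularization multiplier, $s_j$ the (population) standard deviation of
feature $j$ over the presence cells, and $c$ a base constant. We set
$c = 0.05$ by default. The widely used Maxent implementations apply
feature-class-specific tuned penalties whose magnitude, for
linear/quadratic/product features at sample sizes in the hundreds, is
about $0.05\, s_j/\sqrt{m}$; anchoring $c$ there preserves the meaning of
"multiplier 1 = default smoothing". A much larger $c$ (for example 1.0)
over-shrinks visibly: in our recovery experiments the rank agreement
between fitted and true suitability drops from $\rho \approx 0.99$ to
$\approx 0.84$. Both $c$ and $r$ are arguments of `maxent_fit()`.

### Optimization

The objective is concave with an exact L1 penalty. `maxent_fit()` uses
proximal-Newton ascent: at each iteration the gradient (presence means
minus model expectations) and the $d \times d$ feature covariance under
the current distribution are computed exactly, the penalized quadratic
subproblem is solved by cyclic coordinate descent with soft thresholding,
and a backtracking line search on the true objective guarantees monotone
ascent. Weights start at 0, so the starting point is the null
(uniform-landscape) model and runs are deterministic. Convergence is
declared when a full step improves the objective by less than `tol`
(default $10^{-7}$); a converged fit satisfies the KKT bounds
$|\bar f_j - E_\lambda[f_j]| \le \beta_j$, with equality on the active
set. The test suite checks both the KKT certificate and agreement (to
$10^{-6}$) with an independent generic convex solver on small landscapes.

### Output scales

* **raw** — $e^{\lambda^\top f(x)}/Z$ with $Z$ the training-landscape
  normalizer; sums to 1 over the training landscape.
* **cumulative** — 100 times the summed raw output of all
  training-landscape cells with raw value $\le$ the cell's own (ties
  included, so the training maximum scores exactly 100).
* **logistic** — $e^H r/(1 + e^H r)$, with $H$ the entropy of the fitted
  training distribution; an interpretable 0–1 index.

All three are strictly increasing transforms of one another, so any
rank-based operation — AUC, percentile thresholds, binary maps — is
scale-invariant. Which scale a threshold was computed on is recorded and
enforced at projection time anyway, to keep reports unambiguous.

## Data preparation

`filter_records()` applies the record filters in a fixed order (species
identity, date, coordinate validity, land mask), attributing each
rejection to the first failing filter so counts reconcile exactly.
Records with missing dates are rejected by default — a missing date
cannot demonstrate the record postdates the cutoff — with a
`keep_undated` flag to retain them. `thin_to_cells()` collapses records
to one presence per grid cell, because the likelihood is defined over
cells and duplicate records would silently reweight it.

`sample_background()` draws up to `max_n` cells (default 100,000)
uniformly without replacement from the land cells within `buffer_km`
(default 200 map units) of any presence cell. Distance is Euclidean
between cell centers: the grids are treated as equal-area planes scaled
in km, which is exact for the synthetic grids and the convention for
projected continental analyses. Presence cells are kept inside the
background landscape so the model's normalizer covers the sampled region.

`screen_collinearity()` walks candidate variables in order and keeps one
only if its absolute Pearson correlation with every already-kept variable
is below `r_max` (default 0.8) — a greedy filter that favours
variables listed first, so callers should order candidates by ecological
priority.

## Thresholding and evaluation

`auc()` is the rank (Mann-Whitney) estimator of the probability that a
random presence outscores a random background cell; ties count one half.
`cross_validate()` partitions presence cells into `k = 5` folds (sizes
within 1), refits on each training portion against the full background,
and scores held-out presences; the final reported model is always refitted
on all presences, with cross-validation serving as an error estimate only.

`threshold_p10()` implements the 10th-percentile training-presence rule as
an order statistic: the threshold is the $(\lfloor 0.1 m\rfloor + 1)$-th
smallest training presence score, and a cell is suitable iff its score is
$\ge$ the threshold. With distinct scores the training omission is exactly
$\lfloor 0.1 m\rfloor / m$ — exactly 10% when $m$ is a multiple of 10 —
and ties can only lower it. No interpolation is used: the operational
definition ("the value corresponding to 10% training omission") is exact
under this rule, which is also tie-safe. Whether the threshold is taken on
the raw or logistic scale does not affect the binary map, by rank
invariance.

## Projection, novelty, ensembles

`project_binary()` maps a fitted model onto any co-registered stack and
applies the threshold; feature values beyond the training range are
clamped to it by default (recorded in the feature spec).

`mess()` computes the multivariate environmental similarity surface: for
each cell and variable, the percentile position $fr$ of the projected
value within the reference distribution (strictly-less convention, ties
to neither side) is folded into a similarity that is negative outside the
reference range, and the cell score is the minimum across variables.
Negative scores flag environmental novelty — cells where the model
extrapolates. The reference set defaults to the model's training
environment (presence plus background cells). `mask_novel()` sets novel
cells of a binary map to 0 rather than removing them, keeping the land
denominator fixed so area percentages always sum to 100; masking is
idempotent and can only shrink suitable area. Masking is applied per
species and per scenario, before any consensus is taken.

`consensus()` marks a cell suitable when at least `min_agree` of the
scenario maps agree (default the majority, 4 of 6 for a six-model
ensemble); the baseline period, which has a single stack, enters as a
one-scenario consensus. `stack_species()` sums consensus maps into a
species-count hotspot map, and `area_summary()` tabulates the percent of
land in each count class for the unmasked and masked variants side by
side, at full precision in machine output and 1 decimal in reports.

## The synthetic study system

`make_climate()` builds bioclim-like layers as a random planar gradient
plus Gaussian white noise smoothed with a Gaussian kernel of width
`smoothness` cells and variance-normalized — the simplest field with
controllable spatial autocorrelation — and carves a common land mask from
an independent smooth field (default 90% land). `make_scenarios()` adds
per-variable offsets and smooth perturbations; when a `novelty_target` is
given, every scenario-by-period stack's offsets are scaled by bisection
against a brute-force range check until about that fraction of land cells
is out of the baseline range in at least one variable, so MESS behaviour
is testable against a known novel fraction.

`make_virtual_species()` defines truth as an inverse-logit of linear and
quadratic terms of the standardized variables. Two defaults matter:

* coefficients (when not supplied) are drawn with negative quadratic
  terms, giving each variable a niche optimum rather than an open-ended
  response;
* the intercept defaults to $-2$, a moderately low-prevalence species.
  For rare-ish species the inverse-logit is close to an exponential, so
  the sampling density lies (nearly) inside the Gibbs family being
  fitted and exact recovery is achievable in the large-sample limit; at
  prevalence near 0.5 the logistic link is visibly outside the family
  and even the asymptotic fit's rank agreement plateaus (we measure
  $\rho \approx 0.92$). Low prevalence is also the realistic regime for
  virtual-species benchmarks.

`sample_presences()` draws cells with replacement proportionally to truth
times an optional effort bias, and emits one record per draw at the cell
center — duplicates included, mirroring multi-source occurrence data;
thinning removes them downstream.

What the simulator does *not* emulate: real geography and real anomaly
structure (no orography, no coherent warming patterns, no coastlines with
realistic shape), spatially biased detection unless a bias grid is
supplied, taxonomic error, or coordinate noise. Passing tests therefore
demonstrate the correctness of the machinery and its statistical
behaviour under known truth — not that any particular real-world map is
right.

## Numerical and design choices

* **Cell geometry.** Cells are addressed row-major from the top-left;
  point-in-cell uses half-open intervals, so a point on a shared edge
  belongs to exactly one cell.
* **Raster text format.** ESRI ASCII grids are written with 6 significant
  digits (diffable fixtures); model files carry 17 significant digits so
  a saved and reloaded model predicts bit-identically.
* **Degenerate inputs.** Constant features over the background are
  dropped with a warning; a zero-range MESS reference variable scores 0
  at the constant and $-\infty$ elsewhere; an all-rejected record set
  raises an error naming the dominant rejection cause.
* **Determinism.** Every random operation takes an explicit seed and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from one master seed and records them in its manifest. Rerunning a
  config reproduces outputs byte for byte.
* **Problem sizes.** The bundled experiments run on grids up to
  100×100 with a few thousand background cells and a few hundred
  presences — large enough for the statistical properties to hold with
  margin, small enough to iterate quickly on a single CPU.

## Known limitations

* Only linear, quadratic and product features are available — no hinge or
  threshold features, so very sharp response curves are approximated
  smoothly.
* The buffer distance is planar; on unprojected lat-long grids at high
  latitudes it would distort, and no geodesic option is provided.
* Maxent's historical "percent contribution" statistic is intentionally
  absent: it depends on the training trajectory of a particular
  implementation and is not reproducible from the fitted model alone.
  Permutation importance is reported instead.
* The area accounting assumes all cells have equal area, which is what an
  equal-area projection provides and what the synthetic grids are.
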