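---
title: "Methods: sparse PLS lesion-symptom mapping and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse PLS lesion-symptom mapping and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connlsm)
```

## Overview

`connlsm` maps structural-connectome disruption to a continuous
behavioural outcome in lesioned cohorts. The pipeline has five stages:
feature construction from per-subject connectivity matrices, composite
behavioural scoring with nuisance adjustment, sparse PLS1 regression
with cross-validated sparsity, bootstrap-VIP stability selection, and
nested-model evaluation on a held-out split. A synthetic-cohort
generator with known ground truth stands in for MRI-derived data, so
each stage — and the pipeline end to end — is testable.

## Feature construction

A subject's connectome is a symmetric nonnegative region-by-region
matrix of volume-normalised streamline weights; where raw directed
counts are available, the two directions are averaged and divided by
the summed endpoint volumes: `((raw_ij + raw_ji)/2) / (vol_i + vol_j)`.
The lower triangle is vectorised in a canonical row-major order over
`i > j` fixed by the atlas's region ordering, giving `n(n-1)/2` edges.
Edges whose cohort mean weight falls strictly below 1 are removed;
a mean of exactly 1 is retained. The cross-group pairings of the three
perisylvian territories (`inferior_frontal`, `lateral_temporal`,
`supramarginal`) define an SLF-like edge set that is retained
regardless of the threshold, with provenance flags recording which rule
admitted each edge. Asymmetry up to `1e-9` is treated as file-precision
noise and symmetrised by averaging; larger asymmetry is an error, on
the view that silently repairing genuinely asymmetric input hides data
problems.

## Behavioural outcome

The two repetition instruments live on different scales (0–10 and
0–175). Each is divided by its *instrument maximum* — not the observed
sample maximum, which would make the composite depend on the sample —
and the two percentages are averaged. The composite is then adjusted by
ordinary least squares on age and months post-stroke, and the
*residuals* are the outcome for all downstream modelling. The adjusted
outcome is not re-standardised: correlations, which are what the
evaluation reports, are unaffected by scale, and keeping residual units
makes the cross-validation loss interpretable on the composite scale.

## Sparse PLS1

`fit_spls()` standardises `X` columnwise and `y` to unit variance
(edge weights span orders of magnitude, so unscaled covariances would
be dominated by a few heavy edges) and extracts components
sequentially. The sparsity primitive is soft-thresholding at the
`(keepX+1)`-th largest absolute entry of `z = X'y`, followed by
normalisation to unit Euclidean norm; entries tied with the cutoff
magnitude shrink to zero together, so a component can carry fewer than
`keepX` features under exact ties. Deflation subtracts each component
from both `X` and `y`. If a score's sum of squares falls below
`1e-12`, extraction stops early and the model records it — degenerate
deflation is an expected end state on low-rank data, not an error.
Coefficients `b = W (P'W)^{-1} q` are mapped back to the original
scale; the coefficient route and the sequential component route agree
to `1e-10` and both are exercised in the tests, alongside an
independent dense PLS1 reference and the `mixOmics` implementation
(predictions agree to machine precision).

VIP scores aggregate squared weights across components, each weighted
by the outcome variance that component explains; with unit-norm weight
columns the scores satisfy `sum(VIP^2) = p` exactly, which the tests
assert at `1e-6`.

## Tuning keepX

One `keepX` is shared across all `H = 5` components and tuned on the
grid {5, 10, 20, 35, 50, 75, 100} by repeated 5-fold cross-validation
(50 repeats) under mean absolute error, with fold assignments shared
across the grid. Two choices here deserve explanation because the
obvious alternatives fail in ways we verified empirically:

* **Held-out error is scored at component depth 1** by default
  (`eval_components = 1`). Scoring the full five-component model makes
  the loss curve slope monotonically toward dense keepX *even for a
  pure-noise outcome*: a denser weight vector spreads the same noise
  over more features, shrinking predictions toward the mean and
  mechanically lowering MAE. The effect is reproducible in `mixOmics`
  (its own tuner scores per component, and on pure noise chooses a
  sparse value while a full-depth argmin chooses the grid maximum).
  Since the sparsity penalty acts per component and stability selection
  operates on component 1, depth-1 scoring evaluates the quantity the
  penalty actually controls. Full-depth scoring remains available via
  `eval_components = NULL`.
* **The one-standard-error rule** (smallest keepX within one SE of the
  minimising mean loss, SE computed from repeat-level means because
  folds within a repeat share an assignment) is the default selection
  rule, with the plain minimiser available as `rule = "min"`. With ~50
  training subjects and hundreds of edges, chance correlations make
  marginally denser models look marginally better inside any
  cross-validation run; the 1-SE rule is the standard guard and fits
  the goal of a parsimonious, interpretable edge set.

## Bootstrap-VIP stability selection

The training set is resampled with replacement `B` times at full size
(resamples with zero outcome variance are redrawn and counted). In
each resample the model is refitted and, per edge, the component-1 VIP
(`sqrt(p) |w_1|`) and an indicator of nonzero component-1 weight are
recorded. An edge unselected in an iteration contributes VIP 0 to its
mean, so the mean VIP reflects magnitude and stability jointly — an
edge with enormous VIP in a handful of resamples does not outrank a
moderately strong, consistently selected one. Candidates must exceed
mean VIP 1 *and* selection frequency 0.5, and are ranked by mean VIP
(lexicographic tie-break).

Two tuning regimes are provided. The default
(`retune_each_iteration = FALSE`) reuses the keepX tuned once on the
full training set — cheap and adequate for exploration. The
benchmark protocol (`run_benchmark()`) re-runs the tuning grid inside
every resample with a lighter cross-validation (3 repeats of 5 folds):
replicating the tuning lets the effective sparsity adapt to each
resample, which demotes borderline features that only survive under
one particular sparsity level, and measurably improves the
specificity of the selected set.

## Nested evaluation and reporting

The cohort is split 70/30 uniformly at random (no stratification).
Nested models are prefixes of the VIP ranking — all candidates, the
top 10, the top 2 — each refitted densely (`keepX` = subset size) on
the training rows and scored on both splits by Pearson correlation
with the one-tailed p-value from the t transform,
`t = r sqrt((n-2)/(1-r^2))`. The direction is fixed a priori as
positive: more retained connectivity predicting better performance.
The number of components for these small dense refits is chosen by the
same repeated cross-validation (capped at `min(5, |subset|, n-2)`);
with ten features and fifty subjects, five fixed components routinely
overfit. The full-cohort refit table reports component-1 unit-norm
weights — labelled "loadings" in keeping with common usage, though
they are the weight vectors `w`, not the X-loadings `p` — plus VIP and
raw-scale mean, SD and range per feature. Candidate inter-correlations
are clustered agglomeratively on distance `1 - r` (average linkage by
default, configurable because chain-shaped correlation structures make
the linkage choice material; cut at 4 clusters by default).

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure the pipeline
must survive, not the imaging physics:

* **Baseline weights**: a shared log-normal edge template (median 1,
  `sdlog` 1.1 — so the mean-weight threshold at 1 removes roughly half
  the universe) times per-subject, per-edge log-normal noise
  (`sdlog` 0.25–0.4).
* **Lesions**: one sphere per subject, centre uniform in the coordinate
  cube, radius uniform in a configured range. A region at distance `d`
  from the centre retains `min(d/radius, 1)` of its edges' weight; an
  edge takes its *nearer* endpoint's factor. All edges incident to a
  damaged region therefore attenuate together — the collinearity
  mechanism that makes these feature spaces hard.
* **The planted pathway**: behaviour depends on the mean retained
  fraction (relative to the template, mean-one normalised) of a small
  planted edge set. The planted edges additionally share per-subject
  integrity factors organised as three branches around a common trunk
  (`pathway_noise_sdlog`, `pathway_branch_cor`), mirroring the
  three-branch anatomy of the SLF and the strong positive
  inter-correlation that predictive edge sets show in real cohorts. A
  pathway whose edges degrade only through independent lesion geometry
  is not recoverable by any marginal-covariance method: every null
  edge sharing an endpoint with a planted edge receives an *identical*
  attenuation series, which we verified makes selection
  indistinguishable from chance among neighbours.
* **Region measurement factors**: per-subject, per-region log-normal
  factors multiply the *observed* weights of all incident edges
  (tractography seeding efficiency); behaviour depends on the true
  retained integrity, not on them.
* **Behaviour**: a latent score `0.05 + effect * integrity + covariate
  terms + noise` maps onto the two instrument scales (0–10, 0–175) by
  clamped affine transforms, with independent half-SD instrument noise
  — giving an inter-instrument correlation near 0.9, comparable to
  real repetition batteries. Ages are uniform 30–80 years, months
  post-stroke 12–240, with small positive/negative latent slopes.
* **Noise calibration**: when `target_r2` is set, the noise scale is
  found by root-finding so that the *realised* squared correlation
  between planted integrity and the covariate-adjusted composite
  equals the target — clamping and instrument noise otherwise eat
  several points of R².

What the generator does **not** emulate: voxel-level lesion masks,
distance-dependent tractography bias, multiple or non-spherical
lesions, atlas misregistration, and aphasia-subtype structure. Tests
passing on this generator show the pipeline recovers coherent planted
pathways under realistic collinearity and noise; they do not show that
any particular real-data finding is correct.

## The reference benchmark

`benchmark_config()` fixes the study conditions used for validation:
70 subjects, a 25-region atlas (300 candidate edges), 8 planted edges
spread over the SLF-like cross-group pairs, lesion radii 8–18 units in
a 100-unit cube, planted-signal R² of 0.6, and `B = 300` bootstrap
iterations with per-resample retuning. At these sizes one replicate
runs in about half a minute; the test suite runs ten signal replicates
and ten permuted-outcome replicates.

Two honest limitations surfaced by this benchmark are worth stating
plainly. First, with ~50 training subjects and 300 edges, the largest
chance correlation among null edges is around 0.4; features at that
level can survive any within-sample selection procedure, so a handful
of false selections accompany the recovered pathway. Second, under a
*permuted* outcome the same mechanism — in-sample chance correlations,
preserved by bootstrap resampling of the same subjects and genuinely
predictive within cross-validation — yields stable spurious candidate
sets of roughly ten edges rather than the empty set one might hope
for. This is a property of cross-validated bootstrap selection at this
n/p ratio, not of this implementation (the keepX grid reaches a third
of the feature space here, where in feature spaces of several thousand
edges the same grid caps selection below 4%); permutation runs should
therefore be used to calibrate expectations, and candidate sets from
cohorts of this size read as enriched-for-signal, not noise-free.

## Numerical conventions

Symmetry tolerance `1e-9`; score-degeneracy cutoff `1e-12`; VIP
identity tolerance `1e-6`; route-equivalence tolerance `1e-10`;
standard-deviation denominators `n-1` throughout; ties in
soft-thresholding shrink together; ties in cross-validation go to the
sparser model; candidate ranking ties break lexicographically on the
edge label. Every random stage derives its seed deterministically from
a global seed plus a stage tag, so any stage can be rerun in isolation
and reproduce its in-pipeline draws.
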