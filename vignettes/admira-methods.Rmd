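---
title: "Methods: multimodal MRI feature-set ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal MRI feature-set ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`admira` asks a deliberately narrow question with deliberately heavy
machinery: given three families of MRI-derived features — morphometric
(MO), microstructural (MS) and graph-theoretical (GT) — which of the
seven combinations (MO, MS, GT, MO+MS, MO+GT, MS+GT, MO+MS+GT) best
supports (a) staging a subject along the cognitively-normal → mild
cognitive impairment → Alzheimer's dementia continuum and (b) predicting
annualized cognitive decline, and are the incremental gains from adding
modalities statistically real? This vignette records the models,
parameter choices and numerical decisions behind each stage, and what
the synthetic test bed does and does not establish.

## The synthetic cohort generator

Real staging cohorts of this kind come from controlled-access imaging
repositories and multi-hour image-processing pipelines (FreeSurfer
surface reconstruction, probabilistic tractography, tract-based spatial
statistics). The generator replaces that entire upstream with a
statistical emulation whose parameters are the quantities the downstream
analysis actually consumes:

* **Demographics.** Per-group age, education, baseline MMSE and sex
  ratios are sampled from the group-wise means/sds of a 394-subject
  staging cohort (228 CN, 120 MCI, 46 ADD; ages truncated to [55, 96]
  years). Amyloid-positive prevalence defaults per group (CN 138/228,
  MCI 60/120, ADD 37/46) preserve the feature's class association.
  eTIV is drawn at 1.55 × 10⁶ ± 1.5 × 10⁵ mm³, sex-neutral by default.
* **Features.** Each of the 96 imaging features is
  baseline + effect·group + age/sex loading + noise, expressed in
  feature-sd units. Subcortical volumes are generated as
  fraction-of-eTIV × eTIV so that eTIV normalization is meaningful;
  cortical thickness is eTIV-independent. Default disease effects are
  standardized shifts a neuroradiologist would recognize: hippocampal
  and amygdalar atrophy (−1.2 and −0.9 sd in ADD), entorhinal and
  temporal cortical thinning, ventricular enlargement (+0.9 sd), raised
  mean diffusivity (+1.0 sd) and reduced FA; MCI sits halfway. Age/sex
  confounds are injected **linearly** (default −0.02 sd/year, +0.1 sd
  for female), matching the linear model the residualizer fits, so
  adjustment can remove them exactly in expectation.
* **Connectomes.** A shared 82-node template is built from random 3-D
  coordinates with exponentially distance-penalized weights, thresholded
  to density 0.30 — dense enough that clustering, path-length and
  modularity are non-degenerate. Disease is a multiplicative attenuation
  (ADD 0.7, MCI 0.85 by default) on edges touching medial/lateral
  temporal regions; subject noise is log-normal with unit mean
  (σ_log = 0.25). Symmetry and a zero diagonal are enforced.
* **MMSE trajectories.** Each subject gets ≥ 2 visits; score follows
  baseline + rate·years + noise, clipped to [0, 30], with default annual
  rates CN −0.1, MCI −0.9, ADD −2.8 points/year and a final follow-up
  drawn around 79.2 months so the mean follow-up is ≈ 6.6 years.
* **Reproducibility.** Every subject draws from an RNG substream keyed
  by (seed, subject index), so enlarging a cohort never perturbs
  existing subjects, and all outputs are bit-identical for a fixed seed.

What the generator does **not** emulate: voxel-level images, scanner and
site effects, non-linear age trajectories, topological (edge
presence/absence) variability between subjects, non-Gaussian feature
distributions, and missingness. Tests that pass on this bed certify the
*machinery* — leakage safety, bookkeeping, statistical calibration,
recoverability of planted effects — not clinical performance on real
data.

## Graph metrics

Graphs are weighted and undirected; an edge exists wherever the
connectivity matrix is positive. Shortest-path-based metrics (closeness,
betweenness, characteristic path length, diameter, global efficiency,
small-worldness) use distances equal to inverse weights; weights are
first rescaled by the maximum so distances are ≥ 1, which keeps
closeness and efficiency in [0, 1] and leaves shortest-path *trees* (and
hence betweenness) unchanged. Specifics:

* clustering coefficient: geometric-mean weighted variant
  (max-rescaled weights, cube-rooted triangle intensities, normalized by
  k(k−1));
* degree centrality: degree/(n−1); node strength: incident weight sum;
* eigenvector centrality: leading eigenvector of the weighted adjacency,
  unit 2-norm; PageRank with damping 0.85 on weighted transitions;
* modularity: greedy agglomerative maximization on weights — chosen over
  Louvain for determinism;
* weighted degree assortativity: Pearson correlation of endpoint
  strengths over the edge list (each edge counted in both directions);
* small-worldness: the ratio form (C/C_rand)/(L/L_rand) against 10
  degree-preserving rewired references (10×|E| swap attempts each,
  seeded); original edge weights are permuted onto the rewired edges.
  The ratio form and the weight-permutation null are design choices —
  the metric's weighted variant is not standardized;
* degree-distribution entropy: Shannon entropy (natural log) over the
  observed distinct unweighted degrees;
* disconnected graphs: path length and diameter are computed on the
  largest connected component, closeness within each node's own
  component scaled by reachable-set size, and unreachable pairs
  contribute 0 to global efficiency — avoiding infinities.

The feature order (7 nodal blocks of 82, then 17 globals) is frozen so
tables are column-stable across runs: 591 features at 82 nodes, 7n + 17
in general.

## Covariate adjustment and the leakage contract

Volumetric features (including brain parenchymal volume, which sits with
the volumes although its tag is "other" — a toggleable choice) are
divided by the subject's eTIV; cortical thickness and MS/GT features are
not. This is per-subject arithmetic and safely precedes any split. All
imaging features are then residualized per feature on age and sex
(ordinary least squares; sex coded M = 0, F = 1) and z-scored. Both
transforms are **fitted on the training fold only** and applied frozen
to held-out data; the standardizer uses the population (divide-by-n) sd
convention with a sample-sd toggle. Constant training features are
flagged at fit time and standardized to zero — with the default
connectome generator this is routine for degree-based GT columns, since
subject noise perturbs weights but not topology. Amyloid status is
appended raw after adjustment: it is a binary biomarker, not an
imaging-derived measurement. Rank-deficient designs (single-sex folds,
constant age) fall back to the pseudoinverse with a warning rather than
failing.

For the longitudinal target, the visit pair per subject is (first, last)
— the rule that maximizes elapsed time; with multiple follow-ups any
consecutive-pair rule is equally defensible, but endpoints use the most
signal and match the ≈ 6.6-year mean follow-up the generator targets.
Subjects with fewer than two visits are excluded with a typed condition.

## Nested cross-validation and the ablation

Each task (CN–ADD, CN–MCI, MCI–ADD classification with the impaired
class positive; ΔMMSE regression) runs per feature set as: stratified
80/20 hold-out (per-class test count = round-half-up of 0.2 × class
size, which reproduces 219/55, 278/70, 133/33 and 124/31 on cohorts of
274, 348, 166 and 155), then 5 outer folds on the training portion;
within each outer fold the adjustment pipeline is fitted on the outer
training fold, and a 3-fold inner grid search selects hyperparameters by
balanced accuracy (classification) or negative MAE (regression) — the
inner folds reuse the outer fold's transforms, since the leakage
contract targets the outer test folds. The winner is refit on the outer
training fold and predictions are recorded on the outer test fold, so
each training subject has exactly one out-of-fold (OOF) prediction per
learner.

The learner registry wraps established implementations — regularized
logistic regression and ridge (glmnet), LDA (MASS), decision trees
(rpart), random forests (ranger, 200 trees), gradient boosting
(xgboost), SVM/SVR (e1071), Gaussian process regression (kernlab) — plus
a native SAMME/AdaBoost.R2 boosting pair on rpart stumps. Default grids
are small published-style grids (ridge penalties over log-spaced values,
tree depths {3, 5, 10}, SVM cost {0.1, 1, 10}, 50–100 boosting rounds)
and are overridable per learner; the registry, not any individual
learner, is the package's contract. Metrics are reported as mean ± sd
over the five outer folds; hold-out evaluation (retained base models
refit on the full training portion with their modal hyperparameters) is
reported separately and never mixed with the fold-wise numbers.

## Diversity-aware stacking

Pairwise Pearson correlations between the base models' OOF prediction
vectors measure redundancy. Pairs above τ = 0.85 are processed greedily
in descending correlation; the member with inferior cross-validated
performance is discarded (ties: the lexicographically later learner id).
Constant prediction vectors are treated as maximally redundant (ρ := 1)
so degenerate models are pruned first; the pool never empties. A
logistic (classification) or ridge (regression) meta-model with default
regularization strength 1 is trained **exclusively on pooled OOF
predictions** — never on in-fold fitted values — using the class-1
probability column per base model. Per-feature importance is propagated
as I_j = Σ_m |w_m|·|β_j^(m)|, normalized to sum to one: |β| is the
absolute coefficient vector for linear models, the native normalized
impurity/gain importances for tree ensembles (a pragmatic reading, since
"coefficients" are undefined for trees), and a primal-style
|t(α) × SV| magnitude for SVMs; the Gaussian process regressor exposes
no attribution and is excluded from the sum with a warning. A
model-agnostic permutation importance is available as an independent
check.

## Fold-wise statistics

The a-priori comparisons — MO vs. MO+MS and MO+MS vs. MO+MS+GT per task
— use paired one-sided Wilcoxon signed-rank tests on fold-wise ensemble
metrics: balanced accuracy for classification (higher is better), MAE
for the regression task (differences negated so improvement is
positive). Zero differences are dropped; tied absolute differences get
average ranks. For n ≤ 12 usable differences the p-value is exact,
computed from the rank generating function over all 2ⁿ sign assignments
(ranks doubled to keep tied half-ranks on an integer lattice); above
that a continuity-corrected normal approximation with tie-adjusted
variance is used. With five folds the smallest attainable exact p is
1/32 = 0.03125 — the test is conservative at this n, which the report
footer records. No multiplicity correction is applied to the planned
comparisons. Uncertainty on OOF metrics uses percentile bootstrap
intervals (default 1,000 subject-level resamples; classification
resamples that lose a class are redrawn, capped at 100 retries) — the
percentile method makes the fewest assumptions for the bounded,
sometimes skewed metrics involved; ROC bands are pointwise percentile
intervals on a fixed false-positive-rate grid.

## Problem sizes and determinism

The test suite and the acceptance script run the full machinery at
reduced scale, a deliberate design point of the package's own test bed:
cohorts of 40–80 subjects per task, two-learner pools with single-point
or two-point grids for the 28-run cardinality check, and a
two-learner (LogR + RF) pool at 35 + 35 subjects for the planted-signal
recovery run. The statistical properties checked at these sizes —
split bookkeeping, leakage invariance, exact-test calibration, ordering
of feature sets under planted MO-only signal within one fold-sd — are
size-stable; the absolute performance numbers are not, and are not
asserted. Every stochastic component (generator substreams, fold
assignment, rewired small-world references, bootstrap, permutation
importance) is seeded, and identical seeds give bit-identical outputs.

## Known limitations

* The connectome null keeps topology fixed across subjects, so
  degree-based GT features carry no between-subject signal under the
  default generator; weighted metrics do.
* Meta-model fold metrics evaluate the pooled-OOF-trained meta-model on
  each fold's OOF block, so the ensemble's fold-wise sd is mildly
  optimistic relative to a fully nested meta-fit.
* The exact Wilcoxon test at 5 folds cannot reach p < 0.03125, and the
  one-sided design answers only the "does adding features help"
  direction.
* LDA on p ≫ n standardized features relies on MASS's collinearity
  handling; its discriminant axis is regularization-free and can be
  unstable on very small folds.
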