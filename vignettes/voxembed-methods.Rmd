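---
title: "Co-occurrence embeddings and voxel-wise encoding models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence embeddings and voxel-wise encoding models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`voxembed` implements a complete analysis chain for asking whether brain
responses to isolated objects carry information about the *contexts* those
objects appear in: learn a low-dimensional embedding of object labels from
their co-occurrence across annotated scenes, design stimuli whose nuisance
features are decorrelated from the models of interest, and test the
embedding against voxel-wise responses with cross-validated encoding models
and permutation inference.  This vignette explains each stage, its
assumptions, the tunable parameters, and the design decisions taken where
the procedure was genuinely open.

## 1. Object co-occurrence embeddings (CBOW over scenes)

**Corpus model.**  A scene is reduced to the *set* of object labels
annotated in it (repeats dropped; `scene_from_tokens()`).  Label variants
are harmonized to canonical names (`canonical_first_name()`, `harmonize()`)
before training.  Scene multiplicity never enters downstream computation.

**Training objective.**  `train_cbow()` adapts the continuous bag-of-words
objective to scenes: for each object in a scene, predict it from the mean
of the input vectors of *all other objects in the same scene*, with equal
context weights.  There is no positional window — a scene annotation has no
order — and no character n-grams.  The objective is optimized by negative
sampling: each positive example is contrasted with `negatives` noise labels
drawn from the unigram (scenes-containing) distribution raised to
`noise_power`, excluding the current target.

Parameters (`train_config()`):

* `dim` (default 10): embedding width.  Pairwise RSA of averaged RDMs
  across widths (`dimensionality_rsa()`) is the tool for checking that a
  small width already carries the shared representational content.
* `epochs` (default 1000) and `learning_rate` (default 0.05, linear decay
  to 1e-4 of its initial value over all updates): standard CBOW practice.
  The appropriate epoch count depends strongly on corpus size and density;
  see §6 on the synthetic corpus.
* `negatives` (default 20), `noise_power` (default 0.75), `min_count`
  (default 1): negative-sampling configuration.
* `seed`: the trainer uses its own deterministic generator (xorshift128+
  seeded from this integer), so identical corpus + config + seed give
  bit-identical embeddings regardless of R's RNG state.

The *input-side* (context-average) matrix is returned as "the embeddings".
Scenes with fewer than two trainable labels contribute no updates but stay
in the corpus for counting.

**Ensembles and aggregation.**  Stochastic training makes individual
embeddings noisy and axis-arbitrary.  `train_ensemble()` trains `n_inits`
versions with consecutive seeds; `aggregate_pca()` concatenates their
dimensions (rows restricted to the labels of interest), mean-centers
columns, and keeps the leading principal-component scores — the latent
dimensions identified consistently across initializations.  Component
signs follow one convention everywhere: the largest-magnitude loading of
each component is positive.  PCA throughout the package centers but never
rescales columns, because embedding dimensions share a scale.

A caution learned from the synthetic experiments: on a small, dense corpus
(every label seen hundreds of times per epoch), prolonged CBOW training
*over-differentiates* labels that share a context — the objective can
separate individually predictable labels, which blurs coarse context
structure.  Deterministic tiny corpora (e.g. two labels that always and
only co-occur) are the extreme case: their context sets are complementary,
not shared, and the learned vectors spread apart rather than align.  The
co-occurrence structure one wants lives in the regime where scenes sparsely
sample a larger context vocabulary; epoch counts should be modest relative
to corpus density.

## 2. Representational similarity tools

Dissimilarity between category representations is the Pearson distance,
`1 - r` (`pearson_distance()`, range [0, 2]); `make_rdm()` assembles the
category-by-category RDM in a fixed category order.  RSA correlation
(`rsa_correlation()`) is the Spearman correlation of the strictly-upper
triangles (`n(n-1)/2` values; the zero diagonal is excluded; ties get
average ranks).  `r_max()` is the maximum — signed, not absolute — RSA
correlation over all target × nuisance RDM pairs.  Constant vectors have
no defined correlation; they raise classed errors rather than silently
producing `NA`.

Embeddings move between tools in the word2vec text format
(`read_embedding_text()` / `write_embedding_text()`; spaces in labels are
encoded as underscores).  `average_names()` maps a name list per category
(label synonyms, plural forms) onto one vector per category by unweighted
averaging of the names present in the table, and `pca_reduce()` gives the
reduced representation used for wide embedding tables (e.g. retaining ~30
components of a 300-dimensional language model, where the scree elbow
sits).

## 3. Stimulus-design optimization

When stimuli are composites (an object over a synthesized background
texture), low/mid-level features of the composite can accidentally
correlate with the representational models under study.
`init_assignment()` / `optimize_assignment()` implement a
two-stage minimization of `r_max`:

1. sample a pool of candidate backgrounds (`candidate_pool_size`, default
   3000) via a user-supplied `feature_sampler`, draw
   `n_random_assignments` (default 1000) random item-to-candidate
   assignments, and keep the one with the smallest `r_max` (nuisance RDMs
   are built per feature layer from category-averaged item features);
2. hill-climb: each proposal resamples a *fresh* candidate for one
   uniformly chosen item and is accepted only if `r_max` strictly
   decreases; ties are rejected.  The search stops at the proposal budget
   or at the first accepted state with `r_max` below `stop_threshold`
   (default 0.05, the conventional stopping criterion).

The candidate pool is open-ended — proposals are new samples, not pool
members — which is why the sampler is a function, not a matrix.  The
optional `item_baseline` represents the fixed feature contribution of the
item itself: composite features are baseline plus assigned candidate.
Without a baseline, randomly sampled candidate features are already nearly
orthogonal to any fixed target model, and the best of 1000 random
assignments typically starts *below* 0.05; the baseline is what makes the
problem real, exactly as object content does for composite photographs.
In the synthetic acceptance instance the baseline mixes the target
embeddings into each feature layer at an object-to-background scale ratio
of 0.08, chosen so that the initial `r_max` (~0.15) is well above the
stopping criterion while background features dominate the composite — the
situation the real design needed to correct.  With that instance the
20,000-proposal budget reaches the 0.05 criterion with room to spare.

Degenerate evaluations (every category sharing one candidate, hence a
constant RDM with no defined rank correlation) are skipped as possible
minimizers; if *every* random assignment is degenerate the initialization
fails with an undefined-distance error.  The accepted-`r_max` trace is
non-increasing by construction, and the whole trajectory is reproducible
from the seed (the optimizer stores and restores the RNG state between
calls).

## 4. Spatial-property ratings

Panels of ordinal ratings (real-world size on a 1–8 picture scale,
spatial stability on a 1–5 scale) are aggregated per category after an
outlier-rater filter (`filter_subjects()`): compute all pairwise Pearson
correlations of subjects' rating vectors, each subject's mean pairwise
correlation, and remove — in one pass, two-sided — subjects farther than
1.5 SD from the mean of those means.  Edge cases are fixed by decision:
zero dispersion removes nobody; constant-rating subjects (undefined
correlations) are flagged and removed with a warning before the criterion
is applied.  Retained ratings are averaged per category
(`aggregate_ratings()`) and bound unscaled into a two-column model matrix
(`spatial_design()`); centering is left to the encoding stage's intercept.

## 5. Response data, reliability and voxel selection

Responses are beta values per voxel × category × run, where each run
presents the categories of one fold of the design (`make_folds()`, default
9 folds).  `zscore_within_run()` standardizes each (voxel, run) slice over
its categories; voxels with a constant slice are removed and recorded, not
zero-filled, because silent zeros would bias reliability masks downstream.

`split_half_reliability()` correlates, per voxel, the category means of
odd and even runs; odd/even is defined on 1-based chronological position
within each fold's run list.  The analytic threshold for selecting
reliable voxels is `critical_r(n, alpha)` — the correlation whose
one-sided p equals `alpha` under the null, `r = t / sqrt(t^2 + n - 2)`;
with `n = 81` categories and `alpha = 0.05` this is 0.1841.
`reliability_mask()` retains voxels whose *cross-subject mean* reliability
meets the threshold, comparing unrounded values; a voxel with undefined
reliability in any subject is excluded.

## 6. Voxel-wise encoding models

`fit_predict_cv()` fits, per cross-validation fold, ordinary least squares
of the training categories' (run-averaged) responses on
`[intercept | model | nuisance]`, and predicts held-out categories from
the intercept and model columns only.  Nuisance regressors (e.g. ~20
principal components of image features) therefore clean the model weights
without ever contributing to predictions.  Training designs are checked
for full column rank per fold.  Accuracy is the per-voxel Pearson
correlation of concatenated out-of-sample predictions with the actual
responses, which makes it invariant to any positive affine transform of a
voxel's responses.

**Inference.**  `make_fold_permutations()` draws category-label
permutations restricted to within-fold shuffles; `permutation_null()`
permutes the *predicted* responses' labels, recomputes accuracies (the
permutation leaves each profile's mean and SD unchanged, so this is
vectorized over voxels and replicates), and converts to one-sided
p-values with the add-one convention `p = (1 + #{null >= obs}) /
(1 + n_perm)` — the floor at 5000 permutations is 1/5001 ≈ 2.0e-4.
One permutation stream is shared across voxels, and — crucially — across
the two models of any comparison: `preference_map()` (accuracies floored
at zero before differencing, two one-sided tests each FDR-corrected) and
`interaction_test()` (difference-of-differences across two ROIs) both
require jointly permuted replicates, and refuse mismatched streams.
`fdr_adjust()` is Benjamini–Hochberg.  `roi_test()` averages accuracy over
voxels × subjects and applies identical averaging to each null replicate;
`bootstrap_se()` resamples categories with replacement within folds,
paired across actual and predicted, and reports the SD of ROI-mean
replicates, redrawing (and counting) degenerate replicates.

**A calibration caveat.**  Permuting the *predictions'* labels after a
single fit — rather than refitting the model for each of the 5000
permutations, which is computationally prohibitive — is an approximation,
and the validation suite quantifies its cost: under a strict global null
(responses carrying no model signal at all), the observed concatenated
cross-validated correlation is slightly shifted (mean ≈ −0.02 to −0.07 at
8 regressors and 81 categories) and heavy-tailed relative to this
permutation null, because out-of-fold predictions still encode the
training alignment of the held-out labels through the global centring.
Voxel-level p-values are therefore approximately, not exactly, uniform
under the null (the empirical false-positive rate at nominal 0.05 runs
near 0.07–0.10 in the package's strict-null simulations).  The package
implements the standard permute-after-fit scheme; analyses that need exact voxel-level
calibration should interpret marginal q-values with this in mind.

For group preference maps, flooring happens before averaging across
subjects (floor-then-average); `weights_pca()` analyses subject- and
fold-averaged model weights (`average_weights()`; intercept excluded) over
the significant voxel set, and projects the original regressors on the
loadings to obtain per-category component scores.

## 7. Synthetic data: what it emulates and what it does not

`generate_corpus()` draws scenes from latent contexts: the vocabulary is
split evenly across `n_contexts`; each context has a Dirichlet-distributed
label preference (`concentration = 1`, giving the heavy-tailed label
frequencies typical of dense scene annotations); scene sizes follow a
shifted negative binomial (mean 8, minimum 2); with probability
`1 - purity` a label comes from a random other context.  Ground truth
(scene contexts, dominant label contexts) is returned for recovery tests.

`generate_responses()` plants a linear encoding: noiseless response =
intercept + embedding × weights (optionally plus correlated nuisance
features), observed per run with additive Gaussian noise — noise enters at
the beta level because betas are this package's input contract; no time
series or HRF structure is modelled.  `generate_rating_panel()` makes
honest raters (truth + rounded Gaussian noise, clipped to scale) plus
uniform-random outliers.

Study-condition defaults used in the validation suite: 2000 scenes,
vocabulary 120 over 4 contexts, purity 0.9; ensembles of 8 ×
10-dimensional embeddings aggregated to 8 components; 25 training epochs —
deliberately modest because this corpus is an order of magnitude smaller
and far denser per label than a real annotation corpus, and longer
training over-differentiates within-context labels (§1).  Encoding
validation uses 81 categories in 9 folds, 100–500 voxels, 2–4 runs per
fold, and permutation counts of 1000–5000.  These synthetic data share the
real data's *statistical* structure (fold designs, run noise, reliability
attenuation, label frequency skew) but none of its content: no visual
features, no spatial voxel structure, no between-voxel correlation, and
Gaussian rather than physiological noise — so passing tests validate the
machinery and its calibration, not claims about any particular brain.

## 8. Numerical conventions and limitations

* Error conditions are classed (`voxembed_*`) so callers can discriminate
  alignment, rank, coverage, and degeneracy failures programmatically.
* PCA sign convention: largest-magnitude loading positive; tolerance for
  rank decisions is `1e-10` relative to the largest singular value.
* "Accuracy equals 1" assertions in the validation suite use `1e-10`
  relative tolerance; z-scoring idempotence is checked at `1e-12`.
* The permutation engine assumes exchangeability of category labels within
  folds under the null, which the fold-matched run design provides.
* OLS only: no regularization, so the number of regressors must stay well
  below the training-fold size (checked).  Group-level inference is
  fixed-effects averaging over subjects, as in small-n deep-sampling
  designs; no mixed-effects generalization is attempted.
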