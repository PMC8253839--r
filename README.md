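# voxembed

Object representations in visual cortex may reflect not just what an object
looks like, but the *company it keeps* — the statistical structure of object
co-occurrence in natural scenes.  `voxembed` is an R package for testing
that idea end to end:

1. **Learn object co-occurrence embeddings** from annotation corpora of
   scenes (one scene = the set of object labels present), using a
   continuous bag-of-words (CBOW) model with negative sampling in which
   each object's context window is *all other objects in the same scene*.
   Multi-initialization ensembles are aggregated by PCA into a compact
   embedding ("object2vec"-style).
2. **Compare representational models** with RSA: Pearson-distance
   representational dissimilarity matrices (RDMs), Spearman RSA
   correlations, and the `r_max` criterion (the maximum RSA correlation
   between target models and nuisance feature models).
3. **Design stimuli** by stochastic optimization: assign background
   candidates to items so that `r_max` between target-model RDMs and
   nuisance-feature RDMs falls below a stopping criterion (random
   initialization followed by single-item resampling hill-climbing that
   accepts only strict improvements).
4. **Relate models to voxel responses** with cross-validated voxel-wise
   encoding models: per-fold OLS with nuisance regressors confined to the
   training folds, out-of-sample Pearson accuracy, label-permutation nulls
   with FDR correction, bootstrap SEs, ROI and interaction tests,
   preference maps, and PCA of regression weights.  Split-half reliability
   with an analytic critical-r threshold selects voxels.
5. **Validate with synthetic ground truth**: generators for
   context-structured corpora, linear voxel responses with run/fold
   structure, and rating panels with outlier subjects, so the whole
   pipeline is exercised with known answers.

The core model: for responses $y_v \in \mathbb{R}^{81}$ of voxel $v$ to 81
object categories and a feature matrix $X$ (e.g. 8 embedding components),
each cross-validation fold fits $y_v = \beta_0 + X\beta + Z\gamma +
\varepsilon$ on 72 training categories ($Z$ = nuisance features), predicts
the 9 held-out categories from $\hat\beta_0 + X\hat\beta$ only, and scores
the concatenated predictions by Pearson $r$.  Significance comes from
permuting category labels within folds (5000 replicates, one-sided
$p = (1+b)/(1+m)$, Benjamini–Hochberg FDR across voxels).

## Worked example

```r
library(voxembed)

# scene corpus with four latent contexts
corp <- generate_corpus(n_scenes = 2000, vocab_size = 120, n_contexts = 4,
                        purity = 0.9, seed = 1)
print(corp$corpus)

# ensemble of co-occurrence embeddings, aggregated by PCA
ens <- train_ensemble(corp$corpus, train_config(dim = 10, epochs = 25, seed = 1),
                      n_inits = 8)
o2v <- aggregate_pca(ens, n_components = 8,
                     labels_of_interest = rownames(ens[[1]]))

# synthetic voxel responses linear in the embedding
resp <- generate_responses(o2v, n_voxels = 200, noise_sd = 1,
                           n_runs_per_fold = 4, seed = 2)
rel <- split_half_reliability(resp$data)
mask <- reliability_mask(cbind(rel), alpha = 0.05, n = nrow(o2v))

# cross-validated encoding model with permutation inference
Y <- average_runs(resp$data)
fit <- fit_predict_cv(unclass(o2v), Y, resp$folds)
perm <- permutation_null(fit, Y, n_perm = 1000, seed = 3)
q <- fdr_adjust(perm$p_values)
roi_test(fit$accuracy, perm$null_accuracy, roi = mask$voxels, name = "reliable")
```

Output:

```
annotation_corpus: 2000 scenes, 120 distinct labels
embedding_table: 120 labels x 8 dimensions
variance explained by 8 PCs: 77.9%
voxel_mask: 200 voxels at threshold 0.1509
encoding_result: 200 voxels, 120 categories, 8 folds; mean r = 0.995
voxels with q < 0.05: 200 of 200
roi_stat 'reliable': mean r = 0.9950, p = 0.001 (1000 permutations)
```

Reading the numbers: the 8 aggregated components capture 77.9% of the
variance of the concatenated ensemble; the reliability mask keeps voxels
whose split-half correlation clears the analytic one-sided threshold for
120 paired observations (0.1509; with 81 categories the same
formula gives 0.1841, `critical_r(81, 0.05)`); because these synthetic
responses are built from the very embedding used to predict them, accuracy
approaches its noise ceiling and every voxel survives FDR; the ROI-level
permutation p is at its floor, $1/(1000+1)$.

The methods vignette (`vignettes/voxembed-methods.Rmd`) documents the
models, parameter choices, numerical conventions, and the limits of what
synthetic validation shows.

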