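#' Synthetic data generators with known ground truth
#'
#' Generators that reproduce the statistical structure each pipeline stage
#' assumes — scenes drawn from latent context categories, voxel responses
#' linear in a known embedding with additive run-level noise, and rating
#' panels with injected outlier subjects — so the full pipeline can be run
#' and validated end-to-end without any external data.
#'
#' @name synth
NULL

#' Generate a context-structured annotation corpus
#'
#' Each scene draws a latent context category, then samples object labels
#' without replacement from that context's label-preference distribution (a
#' Dirichlet draw per context).  With probability `1 - purity` an individual
#' label is instead drawn from a uniformly chosen other context, diluting
#' the block structure.  Scene sizes follow a shifted negative binomial
#' (minimum 2 objects), mimicking the variable object counts of densely
#' annotated scene photographs.
#'
#' @param n_scenes number of scenes.
#' @param vocab_size total number of distinct labels, split evenly across
#'   contexts.
#' @param n_contexts number of latent contexts.
#' @param purity probability that a label is drawn from the scene's own
#'   context.
#' @param concentration Dirichlet concentration of the per-context label
#'   preferences (1 = flat prior over strongly uneven preferences).
#' @param scene_size_mean,scene_size_dispersion mean and negative-binomial
#'   size parameter of the objects-per-scene distribution (shifted by 2).
#' @param seed integer seed.
#' @return list with `corpus` (an [annotation_corpus()]),
#'   `scene_context` (latent context of each scene), and `label_context`
#'   (named vector: dominant context of each label).
#' @export
generate_corpus <- function(n_scenes = 2000L, vocab_size = 120L,
                            n_contexts = 4L, purity = 0.9,
                            concentration = 1, scene_size_mean = 8,
                            scene_size_dispersion = 5, seed = 1L) {
  if (purity < 0 || purity > 1) err_spec("purity must lie in [0, 1]")
  if (n_contexts < 1L) err_spec("need at least one context")
  per_ctx <- vocab_size %/% n_contexts
  if (scene_size_mean > per_ctx)
    err_spec("vocabulary too small for the requested objects-per-scene")
  set.seed(seed)
  labels <- sprintf("obj%03d", seq_len(per_ctx * n_contexts))
  label_context <- rep(seq_len(n_contexts), each = per_ctx)
  names(label_context) <- labels
  ctx_labels <- split(labels, label_context)
  ctx_prob <- lapply(ctx_labels, function(l) {
    g <- stats::rgamma(length(l), shape = concentration)
    stats::setNames(g / sum(g), l)
  })
  scene_context <- sample.int(n_contexts, n_scenes, replace = TRUE)
  sizes <- pmin(2L + stats::rnbinom(n_scenes, size = scene_size_dispersion,
                                    mu = scene_size_mean - 2),
                per_ctx)
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    own <- scene_context[i]
    picked <- character(0)
    for (slot in seq_len(sizes[i])) {
      src <- own
      if (n_contexts > 1L && stats::runif(1) > purity)
        src <- sample(setdiff(seq_len(n_contexts), own), 1L)
      avail <- setdiff(names(ctx_prob[[src]]), picked)
      if (!length(avail)) next
      pr <- ctx_prob[[src]][avail]
      picked <- c(picked, sample(avail, 1L, prob = pr))
    }
    scenes[[i]] <- picked
  }
  list(corpus = annotation_corpus(scenes), scene_context = scene_context,
       label_context = label_context)
}

#' Generate voxel responses linear in a known embedding
#'
#' Noiseless voxel responses are `intercept + embedding %*% weights`
#' (optionally plus a nuisance-feature contribution); each run observes the
#' categories of its fold with additive Gaussian noise of SD `noise_sd`.
#' The planted weights and noiseless responses are returned for recovery
#' tests.
#'
#' @param embedding an [embedding_table()] (or matrix with category
#'   rownames): the ground-truth regressors.
#' @param n_voxels number of voxels.
#' @param weight_scale SD of the planted weights, scalar or one value per
#'   embedding dimension.
#' @param noise_sd run-level observation noise SD (0 gives perfectly
#'   reliable, perfectly predictable responses).
#' @param n_runs_per_fold runs observing each fold (use an even number of
#'   at least 2 so odd/even split-half reliability is defined).
#' @param folds fold design; default a seeded 9-fold split of the
#'   categories (or the largest even divisor available).
#' @param intercept_sd SD of the per-voxel intercept.
#' @param nuisance_p number of nuisance feature columns (0 = none).
#' @param nuisance_cor correlation of the nuisance features with a random
#'   mixture of the model features.
#' @param nuisance_weight_scale SD of the nuisance weights contributing to
#'   the responses.
#' @param seed integer seed.
#' @return list with `data` (a [response_data()]), `truth` (list:
#'   `weights` voxel x p, `intercept`, `noiseless` voxel x category,
#'   `nuisance_features`, `nuisance_weights`), and `folds`.
#' @export
generate_responses <- function(embedding, n_voxels = 200L, weight_scale = 1,
                               noise_sd = 1, n_runs_per_fold = 4L,
                               folds = NULL, intercept_sd = 1,
                               nuisance_p = 0L, nuisance_cor = 0,
                               nuisance_weight_scale = 0, seed = 1L) {
  E <- as.matrix(embedding)
  categories <- rownames(E)
  if (is.null(categories)) err_spec("embedding needs category rownames")
  set.seed(seed)
  if (is.null(folds)) {
    # default: the divisor of n_categories closest to a 9-fold design,
    # with at least 2 folds of at least 2 categories each
    n_cat <- length(categories)
    div <- which(n_cat %% seq_len(n_cat) == 0L)
    div <- div[div >= 2L & n_cat %/% div >= 2L]
    if (!length(div))
      err_spec("no valid fold design; pass `folds` explicitly")
    folds <- make_folds(categories, div[which.min(abs(div - 9L))])
  }
  p <- ncol(E)
  W <- matrix(stats::rnorm(p * n_voxels, sd = weight_scale), p, n_voxels)
  intercept <- stats::rnorm(n_voxels, sd = intercept_sd)
  noiseless <- t(E %*% W) + intercept  # voxel x category
  nuisance_features <- NULL
  nuisance_weights <- NULL
  if (nuisance_p > 0L) {
    mix <- E %*% matrix(stats::rnorm(p * nuisance_p), p, nuisance_p)
    mix <- scale(mix)
    g <- matrix(stats::rnorm(length(categories) * nuisance_p),
                length(categories), nuisance_p)
    nuisance_features <- nuisance_cor * mix +
      sqrt(1 - nuisance_cor^2) * scale(g)
    rownames(nuisance_features) <- categories
    colnames(nuisance_features) <- sprintf("nuis%02d", seq_len(nuisance_p))
    if (nuisance_weight_scale > 0) {
      nuisance_weights <- matrix(
        stats::rnorm(nuisance_p * n_voxels, sd = nuisance_weight_scale),
        nuisance_p, n_voxels)
      noiseless <- noiseless + t(nuisance_features %*% nuisance_weights)
    }
  }
  voxels <- sprintf("v%04d", seq_len(n_voxels))
  rownames(noiseless) <- voxels
  colnames(noiseless) <- categories
  n_runs <- length(folds) * n_runs_per_fold
  run_fold <- rep(seq_along(folds), each = n_runs_per_fold)
  betas <- array(NA_real_, c(n_voxels, length(categories), n_runs),
                 dimnames = list(voxels, categories,
                                 sprintf("run%02d", seq_len(n_runs))))
  for (r in seq_len(n_runs)) {
    cats <- folds[[run_fold[r]]]
    betas[, cats, r] <- noiseless[, cats] +
      stats::rnorm(n_voxels * length(cats), sd = noise_sd)
  }
  list(data = response_data(betas, run_fold, folds),
       truth = list(weights = t(W), intercept = intercept,
                    noiseless = noiseless,
                    nuisance_features = nuisance_features,
                    nuisance_weights = nuisance_weights),
       folds = folds)
}

#' Generate a rating panel with outlier subjects
#'
#' Honest raters report the true score plus Gaussian noise, rounded and
#' clipped to the scale; outlier subjects rate uniformly at random across
#' the scale.
#'
#' @param n_subjects total subjects, including outliers.
#' @param true_scores named numeric vector of per-category ground-truth
#'   scores (within the scale).
#' @param scale length-2 inclusive scale bounds.
#' @param rater_noise_sd SD of honest raters' noise, in scale units.
#' @param n_outliers number of uniform-random raters.
#' @param seed integer seed.
#' @return list with `panel` (a [rating_panel()]) and `outliers`
#'   (subject ids of the injected outliers).
#' @export
generate_rating_panel <- function(n_subjects, true_scores, scale = c(1, 8),
                                  rater_noise_sd = 0.5, n_outliers = 0L,
                                  seed = 1L) {
  stopifnot(n_outliers <= n_subjects, !is.null(names(true_scores)))
  set.seed(seed)
  n_cat <- length(true_scores)
  outlier_rows <- sort(sample.int(n_subjects, n_outliers))
  ratings <- matrix(NA_real_, n_subjects, n_cat,
                    dimnames = list(sprintf("s%03d", seq_len(n_subjects)),
                                    names(true_scores)))
  for (s in seq_len(n_subjects)) {
    ratings[s, ] <- if (s %in% outlier_rows)
      sample(seq(scale[1L], scale[2L]), n_cat, replace = TRUE)
    else
      pmin(pmax(round(true_scores +
                        stats::rnorm(n_cat, sd = rater_noise_sd)),
                scale[1L]), scale[2L])
  }
  list(panel = rating_panel(ratings, "synthetic", scale),
       outliers = rownames(ratings)[outlier_rows])
}
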