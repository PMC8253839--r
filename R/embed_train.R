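#' Training configuration for object co-occurrence embeddings
#'
#' Hyper-parameters for the continuous bag-of-words (CBOW) trainer with
#' negative sampling.  Defaults follow the training regime established for
#' annotation corpora: 10-dimensional embeddings trained for 1000 epochs
#' with 20 negative samples per positive.  The initial learning rate and
#' the noise-distribution smoothing power are standard word2vec/fastText
#' practice (0.05 and 0.75); they are exposed here because the original
#' training run did not pin them down.
#'
#' @param dim embedding dimension.
#' @param epochs full passes over the corpus; scene order is reshuffled
#'   each epoch by the seeded generator.
#' @param negatives noise labels drawn per positive example.
#' @param learning_rate initial step size; decays linearly to 1e-4 of its
#'   initial value across all training steps.
#' @param min_count minimum scenes-containing count for a label to be
#'   trained; rarer labels are dropped from scenes before training.
#' @param noise_power exponent applied to unigram counts for the
#'   negative-sampling noise distribution.
#' @param seed integer seed; identical seed and corpus give bit-identical
#'   embeddings.
#' @return a list of class `train_config`.
#' @export
train_config <- function(dim = 10L, epochs = 1000L, negatives = 20L,
                         learning_rate = 0.05, min_count = 1L,
                         noise_power = 0.75, seed = 1L) {
  stopifnot(dim >= 1L, epochs >= 1L, negatives >= 1L, learning_rate > 0,
            min_count >= 0L, seed == as.integer(seed))
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 negatives = as.integer(negatives),
                 learning_rate = learning_rate,
                 min_count = as.integer(min_count),
                 noise_power = noise_power, seed = as.integer(seed)),
            class = "train_config")
}

#' Target/context training pairs of a scene
#'
#' Under the whole-scene context window, every object in a scene is a
#' prediction target whose context is the set of all other objects in the
#' same scene, equally weighted.  Scenes with fewer than two labels yield
#' no pairs.
#'
#' @param scene character vector of deduplicated labels.
#' @return list of `list(target =, context =)` pairs.
#' @examples
#' training_pairs(c("A", "B", "C"))
#' @export
training_pairs <- function(scene) {
  scene <- scene_from_tokens(scene)
  if (length(scene) < 2L) return(list())
  lapply(seq_along(scene), function(i)
    list(target = scene[i], context = scene[-i]))
}

# Deterministic vocabulary order: decreasing scene count, ties alphabetical.
trainable_vocab <- function(corpus, min_count) {
  counts <- corpus$vocabulary
  counts <- counts[counts >= min_count]
  counts[order(-counts, names(counts))]
}

#' Train object co-occurrence embeddings (CBOW with negative sampling)
#'
#' Adapts the CBOW objective to annotation corpora: predict each object from
#' the mean of the input vectors of all other objects in its scene,
#' optimized by negative sampling (noise labels drawn from the unigram
#' scene-count distribution raised to `cfg$noise_power`, excluding the
#' current target).  Optimization is by stochastic gradient descent with a
#' linearly decaying learning rate; scenes are shuffled every epoch by the
#' seeded generator.  The input-side (context-average) vectors are returned
#' as the embeddings.
#'
#' @param corpus an [annotation_corpus()] with at least one scene of two or
#'   more labels after `min_count` filtering.
#' @param cfg a [train_config()].
#' @return an [embedding_table()] over the trained vocabulary.
#' @export
train_cbow <- function(corpus, cfg = train_config()) {
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(cfg, "train_config"))
  vocab <- trainable_vocab(corpus, cfg$min_count)
  if (!length(vocab)) err_no_data("vocabulary empty after min_count filtering")
  idx <- stats::setNames(seq_along(vocab) - 1L, names(vocab))
  scenes <- lapply(corpus$scenes, function(s) {
    s <- s[s %in% names(idx)]
    unname(idx[s])
  })
  if (!any(lengths(scenes) >= 2L))
    err_no_data("no scene with at least 2 trainable labels")
  vecs <- .cbow_train(scenes, as.numeric(vocab), cfg$dim, cfg$epochs,
                      cfg$negatives, cfg$learning_rate, cfg$noise_power,
                      as.numeric(cfg$seed))
  embedding_table(vecs, names(vocab))
}

#' Ensemble of embeddings from different random initializations
#'
#' Trains `n_inits` embedding tables with consecutive seeds
#' `cfg$seed, cfg$seed + 1, ...`; all other hyper-parameters shared.
#'
#' @inheritParams train_cbow
#' @param n_inits number of ensemble members.
#' @return list of [embedding_table()]s in seed order.
#' @export
train_ensemble <- function(corpus, cfg = train_config(), n_inits = 100L) {
  stopifnot(n_inits >= 1L)
  lapply(seq_len(n_inits) - 1L, function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    train_cbow(corpus, cfg_k)
  })
}

ensemble_mean_rdm <- function(tables, labels_of_interest) {
  missing <- setdiff(labels_of_interest, rownames(tables[[1L]]))
  if (length(missing))
    err_unknown_label(paste0("labels not in trained vocabulary: ",
                             paste(missing, collapse = ", ")))
  rdms <- lapply(tables, make_rdm, categories = labels_of_interest)
  m <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  class(m) <- c("rdm", class(m))
  m
}

#' Compare embedding dimensionalities by RSA
#'
#' For each candidate dimension, trains an ensemble, averages the
#' Pearson-distance RDMs (over the labels of interest) across ensemble
#' members, and returns the matrix of pairwise Spearman RSA correlations
#' between the averaged RDMs of every dimension pair.  Used to pick the
#' smallest dimensionality that carries the same representational content
#' as larger ones.
#'
#' @inheritParams train_cbow
#' @param dims integer vector of embedding dimensions to compare.
#' @param n_inits ensemble size per dimension.
#' @param labels_of_interest labels over which RDMs are built.
#' @return `length(dims)` square matrix of RSA correlations, with the
#'   averaged RDMs attached as attribute `rdms`.
#' @export
dimensionality_rsa <- function(corpus, dims, n_inits, labels_of_interest,
                               cfg = train_config()) {
  rdms <- lapply(dims, function(d) {
    cfg_d <- cfg
    cfg_d$dim <- as.integer(d)
    ensemble_mean_rdm(train_ensemble(corpus, cfg_d, n_inits),
                      labels_of_interest)
  })
  n <- length(dims)
  out <- diag(1, n)
  dimnames(out) <- list(as.character(dims), as.character(dims))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    out[i, j] <- out[j, i] <- rsa_correlation(rdms[[i]], rdms[[j]])
  attr(out, "rdms") <- rdms
  out
}

#' Aggregate an embedding ensemble by PCA
#'
#' Concatenates the dimensions of all ensemble members (rows restricted to
#' the labels of interest), mean-centers the columns, and keeps the top
#' principal-component scores as the final embedding — extracting the latent
#' dimensions that are common across random initializations.  Component
#' signs are fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param tables list of [embedding_table()]s sharing a vocabulary that
#'   covers `labels_of_interest`.
#' @param n_components components to retain; must not exceed the rank of
#'   the concatenated matrix.
#' @param labels_of_interest rows of the output.
#' @return an [embedding_table()] with attributes `loadings` and
#'   `explained`.
#' @export
aggregate_pca <- function(tables, n_components, labels_of_interest) {
  missing <- unique(unlist(lapply(tables, function(t)
    setdiff(labels_of_interest, rownames(t)))))
  if (length(missing))
    err_unknown_label(paste0("labels missing from ensemble vocabulary: ",
                             paste(missing, collapse = ", ")))
  concat <- do.call(cbind, lapply(tables, function(t)
    unclass(t)[labels_of_interest, , drop = FALSE]))
  p <- pca_scores(concat, n_components)
  out <- embedding_table(p$scores, labels_of_interest)
  attr(out, "loadings") <- p$loadings
  attr(out, "explained") <- p$explained
  out
}
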