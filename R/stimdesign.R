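#' Stimulus-design optimization by RSA minimization
#'
#' Tools for assigning one nuisance-feature candidate (e.g. a synthesized
#' background texture, represented by its feature vectors in one or more
#' feature layers) to each stimulus item so that the maximum RSA correlation
#' (`r_max`) between the target models' RDMs and the nuisance-feature RDMs
#' is as small as possible.  The search is a two-stage
#' procedure: a large batch of random assignments drawn from a sampled
#' candidate pool, followed by hill-climbing in which a single randomly
#' chosen item gets a freshly sampled candidate and the move is kept only if
#' it strictly lowers `r_max`.
#'
#' @name stimdesign
NULL

# Fast r_max evaluation used inside the optimizer.  Semantically identical
# to make_rdm() + rsa_correlation() + r_max() (verified against them in the
# test suite) but avoids per-call validation: item features are averaged
# within category, turned into Pearson-distance RDMs per layer, and the
# upper triangles rank-correlated against the precomputed standardized
# target ranks.
eval_rmax_fast <- function(features, cat_index, cat_counts, ut, target_z) {
  best <- -Inf
  for (l in seq_along(features)) {
    cm <- rowsum(features[[l]], cat_index, reorder = TRUE) / cat_counts
    cmc <- cm - rowMeans(cm)
    ss <- rowSums(cmc * cmc)
    if (any(ss == 0))
      err_undefined_distance("constant category-mean nuisance feature vector")
    d_upper <- (1 - tcrossprod(cmc / sqrt(ss)))[ut]
    # snap numerically-zero distances (identical vectors) exactly to zero,
    # as make_rdm does, so rank ties agree between both code paths
    d_upper[abs(d_upper) < .Machine$double.eps * 100] <- 0
    r_lay <- rank(d_upper)
    r_lay <- r_lay - mean(r_lay)
    nrm <- sqrt(sum(r_lay * r_lay))
    # an assignment whose RDM is constant (e.g. every category sharing one
    # candidate) has no defined rank correlation; it can never be a
    # minimizer, so the caller skips it
    if (nrm == 0) return(NA_real_)
    for (t in seq_along(target_z)) {
      r <- sum(r_lay * target_z[[t]]) / nrm
      if (r > best) best <- r
    }
  }
  best
}

# standardized target ranks: Pearson on these equals Spearman on the RDMs
standardize_ranks <- function(target_ranks) {
  lapply(target_ranks, function(r) {
    rc <- r - mean(r)
    rc / sqrt(sum(rc * rc))
  })
}

#' Gaussian candidate feature sampler
#'
#' Returns a sampler conforming to the `feature_sampler` contract used by
#' [init_assignment()] and [optimize_assignment()]: a function of `n` that
#' draws `n` fresh candidates and returns one `n x d` matrix per feature
#' layer, filled with standard normal deviates from R's RNG stream.
#'
#' @param layer_dims integer vector, one feature dimension per layer.
#' @return `function(n)` returning a list of `n x d_l` matrices.
#' @export
gaussian_feature_sampler <- function(layer_dims) {
  stopifnot(all(layer_dims >= 3L))
  function(n) lapply(layer_dims, function(d)
    matrix(stats::rnorm(n * d), nrow = n, ncol = d))
}

new_assignment_state <- function(items, cat_index, categories, assignment,
                                 features, r_max, trace, target_ranks,
                                 feature_sampler, item_baseline, seed) {
  structure(list(items = items, cat_index = cat_index,
                 categories = categories, assignment = assignment,
                 features = features, r_max = r_max, trace = trace,
                 target_ranks = target_ranks,
                 feature_sampler = feature_sampler,
                 item_baseline = item_baseline, seed = seed,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "assignment_state")
}

#' @export
print.assignment_state <- function(x, ...) {
  cat(sprintf(
    "assignment_state: %d items, %d categories, r_max = %.4f (%d accepted)\n",
    length(x$items), length(x$categories), x$r_max, nrow(x$trace) - 1L))
  invisible(x)
}

#' Initialize an item-to-candidate assignment
#'
#' Samples a pool of candidate nuisance features, draws
#' `n_random_assignments` random item-to-candidate assignments, evaluates
#' `r_max` for each (nuisance RDMs are built per feature layer from the
#' category-averaged assigned features), and returns the assignment with
#' the smallest `r_max`.
#'
#' @param items character vector of stimulus item ids.
#' @param target_rdms list of target-model RDMs over the item categories.
#' @param feature_sampler `function(n)` returning a list of `n x d` feature
#'   matrices, one per layer (see [gaussian_feature_sampler()]).
#' @param categories category of each item, matching the target RDM labels;
#'   defaults to one item per category.
#' @param candidate_pool_size candidates sampled into the initial pool.
#' @param n_random_assignments random assignments evaluated.
#' @param item_baseline optional list of per-layer item x d matrices added
#'   to the assigned candidate features: the fixed feature contribution of
#'   the stimulus item itself (the object in an object-plus-background
#'   composite), which the candidate assignment must counteract.  `NULL`
#'   when item features come from the candidates alone.
#' @param seed integer seed for all randomness.
#' @return an `assignment_state` with fields `assignment` (item ->
#'   candidate id), `features` (per-layer composite item feature matrices,
#'   baseline plus assigned candidate), `r_max`, and `trace` (data frame of
#'   accepted `r_max` values; proposal 0 is the initialization).
#' @export
init_assignment <- function(items, target_rdms, feature_sampler,
                            categories = items,
                            candidate_pool_size = 3000L,
                            n_random_assignments = 1000L,
                            item_baseline = NULL,
                            seed = 1L) {
  stopifnot(candidate_pool_size >= 1L, n_random_assignments >= 1L,
            length(categories) == length(items))
  cat_levels <- rownames(target_rdms[[1L]])
  for (t in target_rdms) check_rdm_aligned(target_rdms[[1L]], t)
  if (!setequal(unique(categories), cat_levels))
    err_alignment("item categories do not match the target RDM categories")
  cat_index <- factor(categories, levels = cat_levels)
  n_cat <- length(cat_levels)
  cat_counts <- as.vector(table(cat_index))
  ut <- upper.tri(diag(n_cat))
  target_ranks <- lapply(target_rdms, function(t) rank(rdm_upper(t)))
  target_z <- standardize_ranks(target_ranks)

  set.seed(seed)
  pool <- feature_sampler(candidate_pool_size)
  n_items <- length(items)
  best <- NULL
  for (a in seq_len(n_random_assignments)) {
    idx <- sample.int(candidate_pool_size, n_items, replace = TRUE)
    feats <- lapply(pool, function(m) m[idx, , drop = FALSE])
    # item features = fixed item component (if any) + assigned candidate
    comb <- if (is.null(item_baseline)) feats else
      Map(`+`, item_baseline, feats)
    r <- eval_rmax_fast(comb, cat_index, cat_counts, ut, target_z)
    if (is.na(r)) next  # degenerate assignment: undefined RSA, skipped
    if (is.null(best) || r < best$r) best <- list(idx = idx, feats = comb, r = r)
  }
  if (is.null(best))
    err_undefined_distance(
      "every random assignment produced a degenerate (constant) RDM")
  new_assignment_state(
    items = items, cat_index = cat_index, categories = cat_levels,
    assignment = stats::setNames(sprintf("pool-%04d", best$idx), items),
    features = best$feats, r_max = best$r,
    trace = data.frame(proposal = 0L, r_max = best$r),
    target_ranks = target_ranks, feature_sampler = feature_sampler,
    item_baseline = item_baseline, seed = seed)
}

#' Hill-climb an assignment to minimize r_max
#'
#' Each proposal samples a fresh candidate for one uniformly chosen item and
#' recomputes `r_max`; the proposal is accepted only if it is strictly lower
#' than the current best.  The search stops at `max_iterations` proposals or
#' at the first accepted state with `r_max < stop_threshold` (and
#' immediately, with no proposals, if the state already satisfies the
#' threshold).
#'
#' @param state an `assignment_state` from [init_assignment()].
#' @param max_iterations proposal budget.
#' @param stop_threshold stop once `r_max` drops below this value.
#' @return the updated `assignment_state`; `trace` gains one row per
#'   accepted proposal and is non-increasing in `r_max`.
#' @export
optimize_assignment <- function(state, max_iterations = 20000L,
                                stop_threshold = 0.05) {
  stopifnot(inherits(state, "assignment_state"))
  assign(".Random.seed", state$rng_state, envir = globalenv())
  n_items <- length(state$items)
  n_cat <- length(state$categories)
  cat_counts <- as.vector(table(state$cat_index))
  ut <- upper.tri(diag(n_cat))
  target_z <- standardize_ranks(state$target_ranks)
  features <- state$features
  best <- state$r_max
  trace <- state$trace
  accepted_assignment <- state$assignment
  offset <- max(trace$proposal)
  iter <- 0L
  while (best >= stop_threshold && iter < max_iterations) {
    iter <- iter + 1L
    item <- sample.int(n_items, 1L)
    cand <- state$feature_sampler(1L)
    proposal <- features
    for (l in seq_along(proposal))
      proposal[[l]][item, ] <- cand[[l]][1L, ] +
        (if (is.null(state$item_baseline)) 0 else
           state$item_baseline[[l]][item, ])
    r <- eval_rmax_fast(proposal, state$cat_index, cat_counts, ut, target_z)
    if (!is.na(r) && r < best) {
      best <- r
      features <- proposal
      accepted_assignment[item] <- sprintf("prop-%06d", iter)
      trace <- rbind(trace, data.frame(proposal = offset + iter, r_max = r))
    }
  }
  out <- state
  out$features <- features
  out$r_max <- best
  out$assignment <- accepted_assignment
  out$trace <- trace
  out$rng_state <- get(".Random.seed", envir = globalenv())
  out
}

#' Write the optimizer outputs
#'
#' `write_assignment()` writes the item-to-candidate table (two tab-separated
#' columns: item, candidate id); `write_trace()` writes the accepted `r_max`
#' trace as CSV.
#'
#' @param state an `assignment_state`.
#' @param path output file.
#' @export
write_assignment <- function(state, path) {
  utils::write.table(
    data.frame(item = state$items, candidate = unname(state$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
write_trace <- function(state, path) {
  utils::write.csv(state$trace, path, row.names = FALSE)
  invisible(path)
}
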