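#' Voxel-wise encoding models
#'
#' Cross-validated ordinary-least-squares encoding: regression weights
#' mapping stimulus features to voxel responses are estimated on training
#' folds (optionally with nuisance regressors that absorb low-level stimulus
#' variance) and applied to held-out categories to generate out-of-sample
#' predictions.  Inference is by permutation of category labels within
#' cross-validation folds, with false-discovery-rate correction across
#' voxels.
#'
#' @name encode
NULL

align_model <- function(model, categories, what = "model") {
  model <- as.matrix(model)
  if (is.null(rownames(model)))
    err_alignment(sprintf("%s matrix needs category rownames", what))
  missing <- setdiff(categories, rownames(model))
  if (length(missing))
    err_alignment(sprintf("%s matrix lacks categories: %s", what,
                          paste(missing, collapse = ", ")))
  model[categories, , drop = FALSE]
}

#' Cross-validated encoding-model fit and prediction
#'
#' For each fold, fits OLS (with intercept) of the training categories'
#' responses on `[model | nuisance]` regressors, then predicts the held-out
#' categories from the intercept and the model regressors only — nuisance
#' regressors serve solely to clean the weight estimates and never enter
#' the predictions.  Held-out predictions are concatenated in the canonical
#' category order of `Y`.
#'
#' @param model feature matrix, categories x p, with category rownames
#'   (e.g. the 8 object-co-occurrence components, 30 language-embedding
#'   components, or the 2 spatial-property columns).
#' @param Y voxel x category response matrix (typically run-averaged), with
#'   voxel rownames and category colnames.
#' @param folds a [make_folds()] design over `colnames(Y)`.
#' @param nuisance optional nuisance feature matrix, categories x q.
#' @return an `encoding_result`: list with `predicted` (voxel x category),
#'   `accuracy` (per-voxel Pearson r of predicted vs actual), `weights`
#'   (voxel x (1 + p) x fold array, intercept first), `folds`,
#'   `categories`.
#' @export
fit_predict_cv <- function(model, Y, folds, nuisance = NULL) {
  Y <- as.matrix(Y)
  categories <- colnames(Y)
  if (is.null(categories) || is.null(rownames(Y)))
    err_alignment("Y needs voxel rownames and category colnames")
  validate_folds(folds, categories)
  M <- align_model(model, categories)
  if (is.null(colnames(M))) colnames(M) <- sprintf("b%d", seq_len(ncol(M)))
  N <- if (is.null(nuisance)) NULL else
    align_model(nuisance, categories, "nuisance")
  p <- ncol(M)
  A <- t(Y)  # category x voxel
  predicted <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  weights <- array(NA_real_,
                   c(nrow(Y), p + 1L, length(folds)),
                   dimnames = list(rownames(Y),
                                   c("(intercept)", colnames(M)),
                                   NULL))
  for (f in seq_along(folds)) {
    test <- categories %in% folds[[f]]
    n_train <- sum(!test)
    X <- cbind(`(intercept)` = 1, M[!test, , drop = FALSE],
               if (!is.null(N)) N[!test, , drop = FALSE])
    if (n_train <= ncol(X))
      err_singular(sprintf(
        "fold %d: %d training categories for %d regressors", f, n_train,
        ncol(X)))
    qx <- qr(X)
    if (qx$rank < ncol(X))
      err_singular(sprintf("rank-deficient training design on fold %d", f))
    coef <- qr.coef(qx, A[!test, , drop = FALSE])
    predicted[, test] <-
      t(cbind(1, M[test, , drop = FALSE]) %*%
          coef[seq_len(p + 1L), , drop = FALSE])
    weights[, , f] <- t(coef[seq_len(p + 1L), , drop = FALSE])
  }
  structure(list(predicted = predicted,
                 accuracy = prediction_accuracy(predicted, Y),
                 weights = weights, folds = folds, categories = categories),
            class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf(
    "encoding_result: %d voxels, %d categories, %d folds; mean r = %.3f\n",
    nrow(x$predicted), ncol(x$predicted), length(x$folds),
    mean(x$accuracy, na.rm = TRUE)))
  invisible(x)
}

rowwise_cor <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(Xc^2))
  sy <- sqrt(rowSums(Yc^2))
  r <- rowSums(Xc * Yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

#' Prediction accuracy (per-voxel Pearson r)
#'
#' @param predicted,actual voxel x category matrices in the same category
#'   order.
#' @return named per-voxel correlations; voxels with a constant vector get
#'   `NA` with a warning.
#' @export
prediction_accuracy <- function(predicted, actual) {
  if (!identical(dim(predicted), dim(actual)) ||
      !identical(colnames(predicted), colnames(actual)))
    err_alignment("predicted and actual matrices are not aligned")
  r <- rowwise_cor(as.matrix(predicted), as.matrix(actual))
  names(r) <- rownames(predicted)
  if (anyNA(r))
    warning(sprintf("%d voxel(s) with constant responses flagged as NA",
                    sum(is.na(r))))
  r
}

#' Category-label permutations within folds
#'
#' Generates the shared permutation stream used by all permutation-based
#' tests: each column is a permutation of the category positions that only
#' shuffles categories within their own cross-validation fold.  Reusing one
#' stream across encoding models is what makes difference and interaction
#' tests on accuracy scores valid.
#'
#' @param folds a [make_folds()] design.
#' @param categories canonical category order (e.g. `colnames(Y)`).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return `length(categories) x n_perm` integer matrix with attribute
#'   `seed`.
#' @export
make_fold_permutations <- function(folds, categories, n_perm = 5000L,
                                   seed = 1L) {
  validate_folds(folds, categories)
  set.seed(seed)
  idx <- seq_along(categories)
  out <- matrix(0L, length(categories), n_perm)
  pos <- lapply(folds, function(f) which(categories %in% f))
  for (k in seq_len(n_perm)) {
    perm <- idx
    for (p in pos) perm[p] <- p[sample.int(length(p))]
    out[, k] <- perm
  }
  attr(out, "seed") <- seed
  out
}

# null accuracies: categories of the *predicted* responses permuted within
# folds, correlated against the actual responses.  Vectorized by
# pre-standardizing category profiles (permutation within a voxel's profile
# leaves its mean and SD unchanged).
null_accuracies <- function(predicted, actual, perms) {
  P <- t(as.matrix(predicted))  # category x voxel
  A <- t(as.matrix(actual))
  n <- nrow(P)
  zs <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    s <- sqrt(colSums(m^2) / (n - 1))
    s[s == 0] <- NA_real_
    sweep(m, 2L, s, "/")
  }
  Pz <- zs(P)
  Az <- zs(A)
  t(vapply(seq_len(ncol(perms)), function(k)
    colSums(Pz[perms[, k], , drop = FALSE] * Az) / (n - 1),
    numeric(ncol(Pz))))  # n_perm x voxel
}

perm_pvalue <- function(observed, null) {
  n_perm <- nrow(null)
  (1 + colSums(sweep(null, 2L, observed, `>=`), na.rm = TRUE)) / (1 + n_perm)
}

#' Permutation null distribution and p-values for prediction accuracy
#'
#' For each permutation, the category labels of the predicted responses are
#' permuted within each cross-validation fold and the voxel-wise Pearson
#' correlation with the actual responses recomputed.  One-sided p-values use
#' the add-one convention `p = (1 + #\{null >= observed\}) / (1 + n_perm)`,
#' so the smallest attainable p with 5000 permutations is 1/5001 ~ 2.0e-4.
#'
#' @param result an `encoding_result` from [fit_predict_cv()] (or a
#'   voxel x category predicted matrix).
#' @param Y the actual voxel x category responses.
#' @param n_perm number of permutations (ignored when `perms` is given).
#' @param seed seed for the permutation stream (ignored when `perms` is
#'   given).
#' @param perms optional precomputed [make_fold_permutations()] stream, for
#'   sharing permutations across models.
#' @param folds fold design; taken from `result` when available.
#' @return list with `null_accuracy` (n_perm x voxel), `p_values`
#'   (per voxel), and the permutation `seed`.
#' @export
permutation_null <- function(result, Y, n_perm = 5000L, seed = 1L,
                             perms = NULL, folds = NULL) {
  if (inherits(result, "encoding_result")) {
    predicted <- result$predicted
    accuracy <- result$accuracy
    if (is.null(folds)) folds <- result$folds
  } else {
    predicted <- as.matrix(result)
    accuracy <- suppressWarnings(prediction_accuracy(predicted, Y))
  }
  if (is.null(folds)) err_domain("a fold design is required")
  if (is.null(perms))
    perms <- make_fold_permutations(folds, colnames(Y), n_perm, seed)
  null <- null_accuracies(predicted, Y, perms)
  colnames(null) <- rownames(predicted)
  attr(null, "perm_seed") <- attr(perms, "seed")
  p <- perm_pvalue(accuracy, null)
  names(p) <- rownames(predicted)
  p[is.na(accuracy)] <- NA_real_
  structure(list(null_accuracy = null, p_values = p,
                 seed = attr(perms, "seed")),
            class = "permutation_result")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1.
#' `NA` entries (e.g. flagged voxels) propagate as `NA` and do not count
#' toward the number of tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and names.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    err_domain("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Bootstrap standard error of an ROI-mean accuracy
#'
#' Each replicate resamples category indices with replacement independently
#' within each cross-validation fold (the same resample applied, paired, to
#' actual and predicted responses of every voxel), recomputes the voxel-wise
#' correlations and the ROI mean.  The standard error is the standard
#' deviation of the replicate means.  Replicates in which some voxel's
#' resampled profile is constant are redrawn (counted and warned about).
#'
#' @param predicted,actual voxel x category matrices.
#' @param folds fold design over the categories.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param roi voxel ids to average over; default all voxels.
#' @return the bootstrap SE, with the replicate means as attribute
#'   `replicates`.
#' @export
bootstrap_se <- function(predicted, actual, folds, n_boot = 5000L,
                         seed = 1L, roi = rownames(predicted)) {
  if (!identical(colnames(predicted), colnames(actual)))
    err_alignment("predicted and actual matrices are not aligned")
  P <- as.matrix(predicted)[roi, , drop = FALSE]
  A <- as.matrix(actual)[roi, , drop = FALSE]
  categories <- colnames(P)
  pos <- lapply(folds, function(f) which(categories %in% f))
  set.seed(seed)
  redraws <- 0L
  reps <- vapply(seq_len(n_boot), function(b) {
    for (try in 1:100) {
      idx <- unlist(lapply(pos, function(p)
        p[sample.int(length(p), length(p), replace = TRUE)]))
      r <- rowwise_cor(P[, idx, drop = FALSE], A[, idx, drop = FALSE])
      if (!anyNA(r)) return(mean(r))
      redraws <<- redraws + 1L
    }
    err_domain("could not draw a non-degenerate bootstrap replicate")
  }, 0)
  if (redraws > 0L)
    warning(sprintf("%d degenerate bootstrap replicate(s) redrawn", redraws))
  structure(stats::sd(reps), replicates = reps)
}

as_subject_list <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)

check_shared_stream <- function(null_a, null_b) {
  sa <- attr(null_a, "perm_seed"); sb <- attr(null_b, "perm_seed")
  if (nrow(null_a) != nrow(null_b))
    err_contract("permutation streams differ in length across models")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    err_contract("models were permuted with different label streams")
}

#' ROI permutation test of mean prediction accuracy
#'
#' The observed statistic is the mean accuracy over all ROI voxels in all
#' subjects; identical averaging is applied to every permutation replicate
#' of the null accuracies, and the one-sided p-value uses the add-one
#' convention.
#'
#' @param accuracy per-subject list of named per-voxel accuracy vectors (a
#'   bare vector is treated as one subject).
#' @param null_accuracy per-subject list of n_perm x voxel null matrices,
#'   all generated from one shared permutation stream.
#' @param roi character vector of ROI voxel ids.
#' @param name ROI label carried into the result.
#' @return a `roi_stat`: list with `name`, `voxels`, `mean_accuracy`, `p`,
#'   `n_perm`, `null`.
#' @export
roi_test <- function(accuracy, null_accuracy, roi, name = "roi") {
  accuracy <- as_subject_list(accuracy)
  null_accuracy <- as_subject_list(null_accuracy)
  if (length(roi) == 0L) err_domain("empty ROI")
  obs <- mean(unlist(lapply(accuracy, function(a) a[roi])))
  null_stat <- rowMeans(do.call(cbind, lapply(null_accuracy, function(n)
    n[, roi, drop = FALSE])))
  p <- (1 + sum(null_stat >= obs)) / (1 + length(null_stat))
  structure(list(name = name, voxels = roi, mean_accuracy = obs, p = p,
                 n_perm = length(null_stat), null = null_stat),
            class = "roi_stat")
}

#' @export
print.roi_stat <- function(x, ...) {
  cat(sprintf("roi_stat '%s': mean r = %.4f, p = %.2g (%d permutations)\n",
              x$name, x$mean_accuracy, x$p, x$n_perm))
  invisible(x)
}

#' Permutation interaction test between two models and two ROIs
#'
#' Statistic: the voxel-wise accuracy difference (model A minus model B),
#' averaged over voxels x subjects within each ROI, contrasted between the
#' ROIs — `mean_roi1(A - B) - mean_roi2(A - B)`.  The same statistic is
#' computed on every joint permutation replicate (both models permuted with
#' one shared label stream), giving a one-sided p-value.
#'
#' @param acc_a,acc_b per-subject lists of per-voxel accuracies for the two
#'   models.
#' @param null_a,null_b per-subject lists of n_perm x voxel null matrices
#'   computed with the *same* permutation stream for both models.
#' @param roi_1,roi_2 voxel id sets of the two ROIs.
#' @return list with `statistic`, `p`, `n_perm`, `null`.
#' @export
interaction_test <- function(acc_a, acc_b, null_a, null_b, roi_1, roi_2) {
  acc_a <- as_subject_list(acc_a); acc_b <- as_subject_list(acc_b)
  null_a <- as_subject_list(null_a); null_b <- as_subject_list(null_b)
  Map(check_shared_stream, null_a, null_b)
  roi_mean <- function(acc_pair, roi)
    mean(unlist(Map(function(a, b) a[roi] - b[roi],
                    acc_pair$a, acc_pair$b)))
  obs <- roi_mean(list(a = acc_a, b = acc_b), roi_1) -
    roi_mean(list(a = acc_a, b = acc_b), roi_2)
  null_roi <- function(roi)
    rowMeans(do.call(cbind, Map(function(na, nb)
      na[, roi, drop = FALSE] - nb[, roi, drop = FALSE], null_a, null_b)))
  null_stat <- null_roi(roi_1) - null_roi(roi_2)
  p <- (1 + sum(null_stat >= obs)) / (1 + length(null_stat))
  list(statistic = obs, p = p, n_perm = length(null_stat), null = null_stat)
}

floor_diff <- function(a, b) pmax(a, 0) - pmax(b, 0)

#' Voxel-wise model preference map
#'
#' The preference score is the difference of prediction accuracies after
#' flooring negative accuracies at zero (so an apparent preference cannot be
#' driven by the comparison model correlating negatively).  Each direction
#' (A > B and B > A) gets a one-sided permutation p-value from the shared
#' label stream, FDR-corrected separately; a voxel is assigned to whichever
#' direction is significant.
#'
#' @param acc_a,acc_b per-voxel accuracies (per-subject lists are averaged
#'   after flooring).
#' @param null_a,null_b n_perm x voxel null accuracy matrices (per-subject
#'   lists allowed) from one shared permutation stream.
#' @param alpha FDR level for the preference assignment.
#' @return list with `difference`, `p_a`, `p_b`, `q_a`, `q_b`, and
#'   `preferred` (factor with levels `"A"`, `"B"`, `"none"`).
#' @export
preference_map <- function(acc_a, acc_b, null_a, null_b, alpha = 0.05) {
  acc_a <- as_subject_list(acc_a); acc_b <- as_subject_list(acc_b)
  null_a <- as_subject_list(null_a); null_b <- as_subject_list(null_b)
  Map(check_shared_stream, null_a, null_b)
  diff <- Reduce(`+`, Map(floor_diff, acc_a, acc_b)) / length(acc_a)
  null_diff <- Reduce(`+`, Map(function(na, nb)
    floor_diff(na, nb), null_a, null_b)) / length(null_a)
  p_a <- perm_pvalue(diff, null_diff)
  m <- nrow(null_diff)
  p_b <- (1 + colSums(sweep(null_diff, 2L, diff, `<=`), na.rm = TRUE)) /
    (1 + m)
  names(p_a) <- names(p_b) <- names(diff)
  q_a <- fdr_adjust(p_a)
  q_b <- fdr_adjust(p_b)
  preferred <- factor(ifelse(q_a < alpha, "A",
                             ifelse(q_b < alpha, "B", "none")),
                      levels = c("A", "B", "none"))
  names(preferred) <- names(diff)
  list(difference = diff, p_a = p_a, p_b = p_b, q_a = q_a, q_b = q_b,
       preferred = preferred)
}

#' Fold-averaged model weights of an encoding result
#'
#' Averages each voxel's per-fold regression weights across folds and drops
#' the intercept, yielding one weight vector per voxel for the model
#' regressors.
#'
#' @param result an `encoding_result`.
#' @return voxel x p matrix.
#' @export
average_weights <- function(result) {
  stopifnot(inherits(result, "encoding_result"))
  w <- apply(result$weights, c(1L, 2L), mean)
  w[, -1L, drop = FALSE]
}

#' PCA of encoding-model regression weights
#'
#' Treats voxels as observations and the model-weight dimensions as
#' variables (intercept and nuisance weights excluded), restricted to the
#' significant voxel set; performs mean-centered PCA and applies the
#' component loadings to the original regressors to obtain a score per
#' category and component.  Component signs follow the convention that each
#' component's largest-magnitude loading is positive.
#'
#' @param weights voxel x p matrix of subject- and fold-averaged model
#'   weights (see [average_weights()]).
#' @param voxels significant voxel ids; needs at least
#'   `n_components + 1` of them.
#' @param model the categories x p feature matrix the weights refer to.
#' @param n_components components to retain.
#' @return list with `loadings` (p x k), `scores` (categories x k),
#'   `explained`.
#' @export
weights_pca <- function(weights, voxels = rownames(weights), model,
                        n_components = 4L) {
  if (length(voxels) < n_components + 1L)
    err_rank(sprintf("need at least %d significant voxels, have %d",
                     n_components + 1L, length(voxels)))
  w <- as.matrix(weights)[voxels, , drop = FALSE]
  p <- pca_scores(w, n_components)
  model <- as.matrix(model)
  if (ncol(model) != nrow(p$loadings))
    err_alignment("model columns do not match the weight dimensions")
  scores <- model %*% p$loadings
  list(loadings = p$loadings, scores = scores, explained = p$explained)
}
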