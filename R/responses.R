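#' Cross-validation fold designs
#'
#' A fold design partitions the stimulus categories into disjoint folds.
#' The same partition defines both the run structure (each run presents the
#' categories of one fold) and the cross-validation scheme of the encoding
#' models.
#'
#' @param categories character vector of category labels.
#' @param n_folds number of folds; must divide `length(categories)` evenly
#'   unless `sizes` is given.
#' @param seed optional seed; when given, categories are shuffled before
#'   partitioning (a typical design randomizes 81 categories into 9 folds
#'   of 9).
#' @return list of character vectors of class `fold_design`.
#' @export
make_folds <- function(categories, n_folds = 9L, seed = NULL) {
  if (length(categories) %% n_folds != 0L)
    err_domain("n_folds must divide the number of categories")
  if (!is.null(seed)) {
    set.seed(seed)
    categories <- sample(categories)
  }
  folds <- split(categories, rep(seq_len(n_folds),
                                 each = length(categories) / n_folds))
  structure(unname(folds), class = "fold_design")
}

validate_folds <- function(folds, categories) {
  all_cats <- unlist(folds, use.names = FALSE)
  if (anyDuplicated(all_cats) || !setequal(all_cats, categories))
    err_domain("folds must be disjoint and cover every category exactly once")
}

#' Voxel-wise response data
#'
#' Beta responses organized as a voxel x category x run array.  Each run
#' presents exactly the categories of one fold; cells for categories outside
#' a run's fold are `NA` by construction.
#'
#' @param betas 3-dimensional numeric array with dimnames
#'   `(voxel, category, run)`.
#' @param run_fold integer vector mapping each run (in array order, taken as
#'   chronological) to its fold index.
#' @param folds a [make_folds()] design over the category dimension.
#' @return a `response_data` object.
#' @export
response_data <- function(betas, run_fold, folds) {
  stopifnot(length(dim(betas)) == 3L, length(run_fold) == dim(betas)[3L])
  if (is.null(dimnames(betas)) || any(vapply(dimnames(betas), is.null, TRUE)))
    err_format("betas array needs voxel, category and run dimnames")
  categories <- dimnames(betas)[[2L]]
  validate_folds(folds, categories)
  for (r in seq_along(run_fold)) {
    have <- categories[!is.na(betas[1L, , r])]
    if (!setequal(have, folds[[run_fold[r]]]))
      err_domain(sprintf(
        "run %d does not contain exactly the categories of fold %d",
        r, run_fold[r]))
  }
  structure(list(betas = betas, run_fold = as.integer(run_fold),
                 folds = folds),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf(
    "response_data: %d voxels x %d categories x %d runs (%d folds)\n",
    d[1L], d[2L], d[3L], length(x$folds)))
  invisible(x)
}

#' Z-score betas within run
#'
#' For every voxel and run, subtracts the mean and divides by the standard
#' deviation over that run's categories, so each (voxel, run) slice has mean
#' 0 and unit SD.  Voxels with a constant slice have no defined z-score;
#' they are removed from the data and recorded in the `flagged` attribute
#' (silent zero-filling would bias downstream masks).  The transform is
#' idempotent up to numerical noise.
#'
#' @param data a [response_data()].
#' @return a `response_data` with z-scored betas and attribute `flagged`
#'   (character vector of removed voxel ids).
#' @export
zscore_within_run <- function(data) {
  stopifnot(inherits(data, "response_data"))
  b <- data$betas
  flagged <- logical(dim(b)[1L])
  for (r in seq_len(dim(b)[3L])) {
    slice <- b[, , r, drop = FALSE]
    dim(slice) <- dim(b)[1:2]
    keep <- !is.na(slice[1L, ])
    m <- rowMeans(slice[, keep, drop = FALSE])
    s <- apply(slice[, keep, drop = FALSE], 1L, stats::sd)
    flagged <- flagged | (s == 0)
    s[s == 0] <- NA
    b[, keep, r] <- (slice[, keep] - m) / s
  }
  if (any(flagged))
    warning(sprintf("removing %d voxel(s) with constant within-run responses",
                    sum(flagged)))
  out <- response_data(b[!flagged, , , drop = FALSE], data$run_fold,
                       data$folds)
  attr(out, "flagged") <- dimnames(data$betas)[[1L]][flagged]
  out
}

#' Average responses across runs
#'
#' Per voxel and category, the mean beta over the selected runs that contain
#' that category.
#'
#' @param data a [response_data()].
#' @param run_subset optional integer vector of run indices; every category
#'   must appear in at least one selected run.
#' @return voxel x category matrix.
#' @export
average_runs <- function(data, run_subset = NULL) {
  stopifnot(inherits(data, "response_data"))
  if (is.null(run_subset)) run_subset <- seq_along(data$run_fold)
  covered <- unique(unlist(data$folds[data$run_fold[run_subset]]))
  missing <- setdiff(dimnames(data$betas)[[2L]], covered)
  if (length(missing))
    err_coverage(paste0("categories absent from the selected runs: ",
                        paste(missing, collapse = ", ")))
  apply(data$betas[, , run_subset, drop = FALSE], c(1L, 2L), mean,
        na.rm = TRUE)
}

# run indices of one fold, split into odd and even chronological positions
fold_run_halves <- function(data, fold) {
  runs <- which(data$run_fold == fold)
  pos <- seq_along(runs)
  list(odd = runs[pos %% 2L == 1L], even = runs[pos %% 2L == 0L])
}

#' Split-half reliability of voxel responses
#'
#' Per voxel, the Pearson correlation between mean responses to all
#' categories in odd and even runs (odd/even by chronological position
#' within each fold's run list).  A proxy for the explainable variance of a
#' voxel's category response profile.
#'
#' @param data a [response_data()] with at least one odd and one even run
#'   per fold.
#' @return named numeric vector of per-voxel correlations; voxels whose
#'   half-profiles are constant get `NA` with a warning.
#' @export
split_half_reliability <- function(data) {
  stopifnot(inherits(data, "response_data"))
  halves <- lapply(seq_along(data$folds), fold_run_halves, data = data)
  if (any(vapply(halves, function(h)
    length(h$odd) == 0L || length(h$even) == 0L, TRUE)))
    err_domain("every fold needs at least one odd and one even run")
  odd <- average_runs(data, unlist(lapply(halves, `[[`, "odd")))
  even <- average_runs(data, unlist(lapply(halves, `[[`, "even")))
  r <- vapply(seq_len(nrow(odd)), function(v) {
    if (stats::sd(odd[v, ]) == 0 || stats::sd(even[v, ]) == 0)
      return(NA_real_)
    stats::cor(odd[v, ], even[v, ])
  }, 0)
  names(r) <- rownames(odd)
  if (anyNA(r))
    warning(sprintf("%d voxel(s) with constant half-profiles flagged as NA",
                    sum(is.na(r))))
  r
}

#' Critical correlation for a one-sided significance level
#'
#' The correlation value whose one-sided p-value equals `alpha` under the
#' null of zero correlation with `n` paired observations:
#' `r = t / sqrt(t^2 + n - 2)` with `t` the `1 - alpha` Student-t quantile
#' at `n - 2` degrees of freedom.  With `n = 81` category responses and
#' `alpha = 0.05` this gives the voxel-selection threshold 0.1841.
#'
#' @param n number of paired observations (>= 3).
#' @param alpha one-sided level in (0, 1).
#' @return the critical correlation.
#' @examples
#' round(critical_r(81, 0.05), 4)  # 0.1841
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3L) err_domain("critical_r needs n >= 3")
  if (alpha <= 0 || alpha >= 1) err_domain("alpha must be in (0, 1)")
  t <- stats::qt(1 - alpha, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Reliability-based voxel mask
#'
#' Retains voxels whose mean split-half reliability across subjects is at
#' least the threshold (computed from [critical_r()] when `alpha` and `n`
#' are given).  Voxels with an undefined (NA) reliability in any subject are
#' excluded.
#'
#' @param reliabilities voxel x subject matrix of per-subject reliabilities
#'   (named rows), or a list of identically named per-subject vectors.
#' @param threshold explicit reliability threshold; overrides `alpha`/`n`.
#' @param alpha,n one-sided level and number of paired observations for the
#'   analytic threshold.
#' @return a `voxel_mask`: list with `voxels`, `threshold`, `alpha`,
#'   `reliability` (cross-subject means over all voxels).
#' @export
reliability_mask <- function(reliabilities, threshold = NULL,
                             alpha = 0.05, n = NULL) {
  if (is.list(reliabilities)) {
    nm <- lapply(reliabilities, names)
    if (any(!vapply(nm, identical, TRUE, y = nm[[1L]])))
      err_alignment("per-subject reliability vectors are not voxel-aligned")
    reliabilities <- do.call(cbind, reliabilities)
  }
  reliabilities <- as.matrix(reliabilities)
  if (is.null(rownames(reliabilities)))
    err_alignment("reliability matrix needs voxel rownames")
  if (is.null(threshold)) {
    if (is.null(n))
      err_domain("give either an explicit threshold or alpha and n")
    threshold <- critical_r(n, alpha)
  } else {
    alpha <- NA_real_
  }
  mean_rel <- rowMeans(reliabilities)  # NA in any subject propagates
  keep <- !is.na(mean_rel) & mean_rel >= threshold
  structure(list(voxels = rownames(reliabilities)[keep],
                 threshold = threshold, alpha = alpha,
                 reliability = mean_rel),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d voxels at threshold %.4f\n",
              length(x$voxels), x$threshold))
  invisible(x)
}

#' Read / write response betas as long-format CSV
#'
#' Columns `voxel, category, run, value`; the fold of each run is inferred
#' from the categories it contains.
#'
#' @param data a [response_data()].
#' @param path file path.
#' @export
write_betas <- function(data, path) {
  b <- data$betas
  long <- expand.grid(voxel = dimnames(b)[[1L]], category = dimnames(b)[[2L]],
                      run = dimnames(b)[[3L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(b)
  long <- long[!is.na(long$value), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @param folds the [make_folds()] design the runs follow.
#' @rdname write_betas
#' @export
read_betas <- function(path, folds) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("voxel", "category", "run", "value")
  if (!all(need %in% names(long)))
    err_format("betas CSV needs columns voxel, category, run, value")
  voxels <- unique(long$voxel)
  categories <- unlist(folds, use.names = FALSE)
  runs <- unique(long$run)
  b <- array(NA_real_, c(length(voxels), length(categories), length(runs)),
             dimnames = list(voxels, categories, runs))
  b[cbind(match(long$voxel, voxels), match(long$category, categories),
          match(long$run, runs))] <- long$value
  run_fold <- vapply(runs, function(r) {
    have <- unique(long$category[long$run == r])
    hit <- which(vapply(folds, setequal, TRUE, y = have))
    if (length(hit) != 1L)
      err_domain(sprintf("run %s does not match exactly one fold", r))
    hit
  }, 0L, USE.NAMES = FALSE)
  response_data(b, run_fold, folds)
}

#' Write a voxel mask
#'
#' Newline-delimited voxel ids plus a JSON sidecar recording the threshold
#' and level.
#'
#' @param mask a `voxel_mask`.
#' @param path path of the id file; the sidecar gets the extension `.json`.
#' @export
write_voxel_mask <- function(mask, path) {
  writeLines(mask$voxels, path)
  jsonlite::write_json(list(threshold = mask$threshold, alpha = mask$alpha,
                            n_voxels = length(mask$voxels)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
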