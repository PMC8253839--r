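#' Rating panels of object spatial properties
#'
#' A rating panel holds ordinal ratings of one spatial property (e.g.
#' real-world size on a 1-8 picture scale, or spatial stability on a 1-5
#' scale) as a subjects x categories matrix with no missing cells.
#'
#' @param ratings numeric matrix, subjects in rows (named), categories in
#'   columns (named).
#' @param property property name (e.g. `"size"`).
#' @param scale length-2 numeric, the inclusive scale bounds.
#' @return a `rating_panel`.
#' @export
rating_panel <- function(ratings, property, scale) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) err_format("rating panel has missing cells")
  if (any(ratings < scale[1L] | ratings > scale[2L]))
    err_format("ratings outside the declared scale bounds")
  if (is.null(rownames(ratings)))
    rownames(ratings) <- sprintf("s%03d", seq_len(nrow(ratings)))
  if (is.null(colnames(ratings)))
    err_format("rating panel needs category column names")
  structure(list(ratings = ratings, property = property, scale = scale),
            class = "rating_panel")
}

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf("rating_panel '%s': %d subjects x %d categories, scale %g-%g\n",
              x$property, nrow(x$ratings), ncol(x$ratings),
              x$scale[1L], x$scale[2L]))
  invisible(x)
}

#' Read / write rating panels as CSV
#'
#' Subjects are rows (first column holds subject ids), categories are header
#' columns.
#'
#' @param path file path.
#' @param property,scale passed to [rating_panel()].
#' @export
read_rating_panel <- function(path, property, scale) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  rating_panel(as.matrix(df), property, scale)
}

#' @param panel a [rating_panel()].
#' @rdname read_rating_panel
#' @export
write_rating_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel$ratings), path, row.names = TRUE)
  invisible(path)
}

#' Filter discordant rating subjects
#'
#' Computes all pairwise Pearson correlations between subjects' rating
#' vectors and each subject's mean pairwise correlation, then removes (in a
#' single pass) any subject whose mean is more than `sd_multiplier` standard
#' deviations away (two-sided) from the mean of these per-subject means.
#' Subjects with constant ratings have no defined correlation; they are
#' flagged and removed with a warning before the criterion is applied.  If
#' the per-subject means have zero dispersion, nobody is removed.
#'
#' @param panel a [rating_panel()] with at least 3 subjects.
#' @param sd_multiplier the exclusion threshold in standard-deviation units.
#' @return list with `panel` (retained subjects), `removed` (subject ids),
#'   and `mean_correlation` (named vector over non-constant subjects).
#' @export
filter_subjects <- function(panel, sd_multiplier = 1.5) {
  stopifnot(inherits(panel, "rating_panel"))
  x <- panel$ratings
  if (nrow(x) < 3L) err_domain("subject filtering needs at least 3 subjects")
  const <- apply(x, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("removing %d constant-rating subject(s): %s",
                    sum(const), paste(rownames(x)[const], collapse = ", ")))
    x <- x[!const, , drop = FALSE]
  }
  cm <- stats::cor(t(x))
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  s <- stats::sd(mean_cor)
  out <- if (s == 0) rep(FALSE, length(mean_cor)) else
    abs(mean_cor - mean(mean_cor)) > sd_multiplier * s
  removed <- c(rownames(panel$ratings)[const], names(mean_cor)[out])
  kept <- x[!out, , drop = FALSE]
  list(panel = rating_panel(kept, panel$property, panel$scale),
       removed = removed, mean_correlation = mean_cor)
}

#' Mean rating per category
#'
#' @param panel a [rating_panel()].
#' @return named numeric vector of unweighted per-category means over the
#'   panel's subjects.
#' @export
aggregate_ratings <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  colMeans(panel$ratings)
}

#' Spatial-properties feature model
#'
#' Binds per-category mean size and stability ratings into the two-column
#' model matrix used as regressors in voxel-wise encoding models.  Values
#' pass through unscaled; the encoding stage handles centering.
#'
#' @param size_means,stability_means named numeric vectors over the same
#'   categories in the same order.
#' @return categories x 2 matrix with columns `size`, `stability`.
#' @export
spatial_design <- function(size_means, stability_means) {
  if (!identical(names(size_means), names(stability_means)) ||
      is.null(names(size_means)))
    err_alignment("size and stability ratings must share one category order")
  cbind(size = size_means, stability = stability_means)
}
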