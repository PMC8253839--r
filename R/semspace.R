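#' Embedding tables
#'
#' An embedding table maps labels to real vectors of a common dimension.  It
#' is represented as a numeric matrix (labels in rows, named) of class
#' `embedding_table`.
#'
#' @param vectors numeric matrix, one row per label.
#' @param labels character vector of row labels (defaults to existing
#'   rownames).
#' @return an `embedding_table`.
#' @export
embedding_table <- function(vectors, labels = rownames(vectors)) {
  vectors <- as.matrix(vectors)
  if (is.null(labels) || length(labels) != nrow(vectors))
    err_format("one label per embedding row is required")
  if (anyDuplicated(labels)) err_format("duplicated labels in embedding table")
  if (any(!is.finite(vectors))) err_format("non-finite embedding entries")
  storage.mode(vectors) <- "double"
  rownames(vectors) <- labels
  class(vectors) <- c("embedding_table", class(vectors))
  vectors
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d labels x %d dimensions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read and write embedding tables in word2vec text format
#'
#' The text format is the one used by word2vec-style tools: a header line
#' `"<n_labels> <dim>"`, then one line per label with the label first
#' (internal spaces encoded as underscores) followed by `dim` numbers,
#' space-separated.
#'
#' @param path file path.
#' @param vocabulary_filter optional character vector; when given, only
#'   labels in the filter are retained (emulating a lexicon restriction).
#' @return an [embedding_table()].
#' @export
read_embedding_text <- function(path, vocabulary_filter = NULL) {
  if (!file.exists(path)) err_io(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) err_format("empty embedding file")
  hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) err_format("malformed word2vec header line")
  n <- hdr[1L]; dim <- hdr[2L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != n)
    err_format(sprintf("header declares %d labels but file has %d rows",
                       n, length(body)))
  parts <- strsplit(body, " +")
  labels <- character(n)
  vecs <- matrix(NA_real_, n, dim)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != dim + 1L)
      err_format(sprintf("line %d: expected %d values, found %d",
                         i + 1L, dim, length(p) - 1L))
    labels[i] <- gsub("_", " ", p[1L], fixed = TRUE)
    vecs[i, ] <- as.numeric(p[-1L])
  }
  if (anyNA(vecs)) err_format("non-numeric embedding value")
  tab <- embedding_table(vecs, labels)
  if (!is.null(vocabulary_filter)) tab <- tab[labels %in% vocabulary_filter, , drop = FALSE]
  embedding_table(unclass(tab))
}

#' @param table an [embedding_table()].
#' @rdname read_embedding_text
#' @export
write_embedding_text <- function(table, path) {
  labels <- gsub(" ", "_", rownames(table), fixed = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%d %d", nrow(table), ncol(table)),
               paste(labels, apply(table, 1L, function(r)
                 paste(formatC(r, format = "g", digits = 17), collapse = " ")))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Average name-list embeddings into category vectors
#'
#' Each stimulus category is associated with an ordered list of names (its
#' annotation label plus synonyms and plural forms).  The category vector is
#' the unweighted mean of the embedding vectors of the names that are present
#' in the table.
#'
#' @param table an [embedding_table()] over names.
#' @param names named list: category label -> character vector of names.
#' @return an [embedding_table()] over categories.
#' @export
average_names <- function(table, names) {
  if (!length(names) || is.null(base::names(names)))
    err_format("`names` must be a named list of name vectors")
  present <- lapply(names, function(nm) nm[nm %in% rownames(table)])
  missing <- base::names(names)[vapply(present, length, 1L) == 0L]
  if (length(missing))
    abort_voxembed(paste0("categories with no resolvable name: ",
                          paste(missing, collapse = ", ")),
                   "voxembed_unresolved_category")
  vecs <- t(vapply(present, function(nm)
    colMeans(table[nm, , drop = FALSE]), numeric(ncol(table))))
  embedding_table(vecs, base::names(names))
}

# PCA with centering only and a deterministic sign convention: each
# component is flipped so that its largest-magnitude loading is positive.
pca_scores <- function(x, k) {
  x <- as.matrix(x)
  if (k < 1L) err_rank("need at least one component")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank)
    err_rank(sprintf("requested %d components but data rank is %d", k, rank))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  var_expl <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  list(scores = sco, loadings = rot, explained = var_expl)
}

#' PCA reduction of an embedding table
#'
#' Columns are mean-centered (not scaled: embedding dimensions share a
#' scale), and the top-`k` principal-component scores become the reduced
#' embedding.  Component signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param table an [embedding_table()].
#' @param k number of components; must not exceed `min(n_labels - 1, dim)`.
#' @return an [embedding_table()] of `k` columns with attributes `loadings`
#'   and `explained` (proportion of variance per retained component).
#' @export
pca_reduce <- function(table, k) {
  if (k > min(nrow(table) - 1L, ncol(table)))
    err_rank(sprintf("k = %d exceeds min(n_labels - 1, dim) = %d",
                     k, min(nrow(table) - 1L, ncol(table))))
  p <- pca_scores(unclass(table), k)
  out <- embedding_table(p$scores, rownames(table))
  attr(out, "loadings") <- p$loadings
  attr(out, "explained") <- p$explained
  out
}

#' Pearson distance between two representational vectors
#'
#' One minus the Pearson correlation coefficient; ranges over \[0, 2\].
#' Constant vectors have no defined correlation and raise an error.
#'
#' @param u,v numeric vectors of equal length (at least 3), non-constant.
#' @return a scalar in \[0, 2\].
#' @export
pearson_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3L)
    err_domain("vectors must share a length of at least 3")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    err_undefined_distance("Pearson distance undefined for a constant vector")
  1 - stats::cor(u, v)
}

#' Representational dissimilarity matrix (RDM)
#'
#' Pairwise Pearson distances between the representational vectors of a set
#' of categories, in the given category order.
#'
#' @param x an [embedding_table()] or numeric matrix with labelled rows
#'   (categories x features).
#' @param categories category order; defaults to all rows of `x`.
#' @return symmetric `n x n` matrix of class `rdm`, zero diagonal.
#' @export
make_rdm <- function(x, categories = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- categories
  missing <- setdiff(categories, rownames(x))
  if (length(missing))
    err_unknown_label(paste0("categories absent from feature matrix: ",
                             paste(missing, collapse = ", ")))
  f <- x[categories, , drop = FALSE]
  if (ncol(f) < 3L)
    err_domain("need at least 3 feature dimensions for Pearson distance")
  sds <- apply(f, 1L, stats::sd)
  if (any(sds == 0))
    err_undefined_distance(paste0(
      "constant representational vector for: ",
      paste(categories[sds == 0], collapse = ", ")))
  d <- 1 - stats::cor(t(f))
  d[abs(d) < .Machine$double.eps * 100] <- 0
  diag(d) <- 0
  dimnames(d) <- list(categories, categories)
  class(d) <- c("rdm", class(d))
  d
}

rdm_upper <- function(a) a[upper.tri(a)]

check_rdm_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)))
    err_alignment("RDMs are not aligned on the same ordered category set")
}

#' RSA correlation between two RDMs
#'
#' The Spearman rank correlation of the strictly-upper-triangle entries of
#' two category-aligned RDMs (`n(n-1)/2` values; ties get average ranks).
#'
#' @param a,b `rdm` matrices over the same ordered categories, `n >= 4`.
#' @return Spearman correlation in \[-1, 1\].
#' @export
rsa_correlation <- function(a, b) {
  check_rdm_aligned(a, b)
  if (nrow(a) < 4L) err_domain("RSA needs at least 4 categories")
  stats::cor(rdm_upper(a), rdm_upper(b), method = "spearman")
}

#' Maximum RSA correlation between target and nuisance models
#'
#' The criterion minimized during stimulus design: the maximum (signed)
#' Spearman RSA correlation over all pairs of target-model RDMs and
#' nuisance-feature RDMs.
#'
#' @param target_rdms,nuisance_rdms non-empty lists of aligned `rdm`
#'   matrices.
#' @return the maximum pairwise [rsa_correlation()].
#' @export
r_max <- function(target_rdms, nuisance_rdms) {
  if (!length(target_rdms) || !length(nuisance_rdms))
    err_domain("both RDM lists must be non-empty")
  max(vapply(target_rdms, function(t)
    vapply(nuisance_rdms, rsa_correlation, 0, a = t),
    numeric(length(nuisance_rdms))))
}

#' Read / write RDMs as delimited text
#'
#' Square CSV with category names as header row and first column.
#'
#' @param rdm an `rdm` matrix.
#' @param path file path.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    err_format("RDM file is not a labelled square matrix")
  class(m) <- c("rdm", class(m))
  m
}
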