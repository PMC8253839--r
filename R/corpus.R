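#' Annotation corpora of object-labelled scenes
#'
#' An annotation corpus is an ordered collection of scenes, each reduced to
#' the *set* of object labels present (repeats of an object within one scene
#' are dropped at construction).  The corpus is the training input for the
#' object co-occurrence embeddings: each object's context is the set of all
#' other objects annotated in the same scene.
#'
#' @param scenes list of character vectors, one per scene; each is
#'   deduplicated preserving first-occurrence order.
#' @return An object of class `annotation_corpus`: a list with elements
#'   `scenes` (list of character vectors) and `vocabulary` (named integer
#'   vector of scenes-containing counts, i.e. in how many scenes each label
#'   occurs).
#' @examples
#' corp <- annotation_corpus(list(c("cup", "cup", "table"), "door"))
#' corp$vocabulary
#' @export
annotation_corpus <- function(scenes) {
  if (!is.list(scenes)) err_malformed_label("`scenes` must be a list of character vectors")
  scenes <- lapply(scenes, scene_from_tokens)
  vocab <- sort(table(unlist(lapply(scenes, unique), use.names = FALSE)),
                decreasing = TRUE)
  vocabulary <- stats::setNames(as.integer(vocab), names(vocab))
  structure(list(scenes = scenes, vocabulary = vocabulary),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d scenes, %d distinct labels\n",
              length(x$scenes), length(x$vocabulary)))
  invisible(x)
}

#' @export
format.annotation_corpus <- function(x, ...) {
  sprintf("<annotation_corpus: %d scenes, %d labels>",
          length(x$scenes), length(x$vocabulary))
}

#' Build a scene from a token list
#'
#' Deduplicates object labels while preserving the order of first occurrence,
#' mirroring the reduction of dense scene annotations to label sets.
#'
#' @param tokens character vector of object labels; must be non-empty strings.
#' @return character vector with duplicates removed.
#' @examples
#' scene_from_tokens(c("cup", "cup", "table"))  # "cup" "table"
#' @export
scene_from_tokens <- function(tokens) {
  if (length(tokens) == 0L || !is.character(tokens))
    err_malformed_label("a scene needs at least one character label")
  if (anyNA(tokens) || any(!nzchar(tokens)))
    err_malformed_label("empty or missing object label in scene")
  unique(tokens)
}

#' Canonical label from a comma-separated name list
#'
#' Annotation datasets often attach several alternative names to one object
#' class ("bathtub, bathing tub, bath, tub"); the first listed name is taken
#' as the canonical label, whitespace-trimmed.
#'
#' @param label_list_string a single string of comma-separated names.
#' @return the first name, trimmed.
#' @examples
#' canonical_first_name("bathtub, bathing tub, bath, tub")  # "bathtub"
#' @export
canonical_first_name <- function(label_list_string) {
  if (length(label_list_string) != 1L || is.na(label_list_string) ||
      !is.character(label_list_string))
    err_malformed_label("expected a single character string of names")
  first <- trimws(strsplit(label_list_string, ",", fixed = TRUE)[[1L]][1L])
  if (is.na(first) || !nzchar(first))
    err_malformed_label("name list is empty")
  first
}

#' Variant-to-canonical label maps
#'
#' @param variant,canonical character vectors of equal length: each `variant`
#'   label is rewritten to its `canonical` label.  The map must be idempotent:
#'   no canonical label may itself be a variant of something else (chains and
#'   cycles are rejected).
#' @return named character vector of class `label_map` (names = variants).
#' @export
label_map <- function(variant, canonical) {
  if (length(variant) != length(canonical))
    err_invalid_map("variant and canonical must have equal length")
  if (anyDuplicated(variant))
    err_invalid_map("duplicated variant labels in map")
  m <- stats::setNames(as.character(canonical), as.character(variant))
  # idempotency: a canonical that is also a variant must map to itself
  bad <- intersect(unname(m), names(m))
  bad <- bad[m[bad] != bad]
  if (length(bad))
    err_invalid_map(paste0("map is not idempotent; chained/cyclic labels: ",
                           paste(bad, collapse = ", ")))
  class(m) <- "label_map"
  m
}

apply_label_map <- function(labels, map) {
  hit <- labels %in% names(map)
  labels[hit] <- unname(map[labels[hit]])
  labels
}

#' Harmonize label variants in a corpus
#'
#' Replaces every variant label with its canonical label and re-deduplicates
#' each scene (merging two variants present in one scene yields a single
#' label), then recounts the vocabulary.
#'
#' @param corpus an [annotation_corpus()].
#' @param map a [label_map()].
#' @return a new `annotation_corpus`.
#' @examples
#' corp <- annotation_corpus(list(c("notepad", "desk")))
#' harmonize(corp, label_map("notepad", "notebook"))$scenes[[1]]
#' @export
harmonize <- function(corpus, map) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!inherits(map, "label_map")) map <- label_map(names(map), unname(map))
  annotation_corpus(lapply(corpus$scenes, apply_label_map, map = map))
}

#' Read / write annotation corpora
#'
#' Plain-text format: UTF-8, one scene per line, labels tab-separated (labels
#' may contain spaces but not tabs or newlines).  Blank lines are skipped with
#' a warning.  `write_corpus()` followed by `read_corpus()` reproduces the
#' corpus exactly.
#'
#' @param path file path.
#' @return `read_corpus()`: an [annotation_corpus()]; `write_corpus()`:
#'   `path`, invisibly.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) err_io(paste0("no such file: ", path))
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) err_io(conditionMessage(e)))
  if (!all(validEnc(lines)))
    err_io("undecodable bytes in corpus file")
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("skipping %d blank line(s) in %s", sum(blank), path))
    lines <- lines[!blank]
  }
  annotation_corpus(strsplit(lines, "\t", fixed = TRUE))
}

#' @param corpus an [annotation_corpus()].
#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(corpus$scenes, paste, "", collapse = "\t"),
             con, useBytes = TRUE)
  invisible(path)
}
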