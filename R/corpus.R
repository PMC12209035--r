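#' Token corpora for topic-model estimation
#'
#' A corpus is a list of pre-tokenized documents (character vectors of
#' tokens); tokenization — including morphological analysis for
#' languages without whitespace word boundaries — is an upstream concern
#' and is consumed as-is. The object caches the vocabulary and the
#' per-word document counts used by [filter_corpus()].
#'
#' @param documents list of character vectors, one per document.
#' @param doc_ids optional document identifiers; defaults to `doc_1 ...`.
#' @return an object of class `vft_corpus`: list with `documents`,
#'   `doc_ids`, `vocabulary`, `doc_count_per_word`.
#' @export
corpus <- function(documents, doc_ids = NULL) {
  stopifnot(is.list(documents))
  documents <- lapply(documents, as.character)
  if (is.null(doc_ids)) doc_ids <- paste0("doc_", seq_along(documents))
  stopifnot(length(doc_ids) == length(documents))
  vocabulary <- sort(unique(unlist(documents, use.names = FALSE)))
  dc <- doc_counts(documents, vocabulary)
  structure(list(documents = documents, doc_ids = as.character(doc_ids),
                 vocabulary = vocabulary, doc_count_per_word = dc),
            class = "vft_corpus")
}

doc_counts <- function(documents, vocabulary) {
  tab <- table(unlist(lapply(documents, unique), use.names = FALSE))
  out <- stats::setNames(integer(length(vocabulary)), vocabulary)
  out[names(tab)] <- as.integer(tab)
  out
}

#' @export
print.vft_corpus <- function(x, ...) {
  cat(sprintf("vft_corpus: %d documents, %d tokens, vocabulary %d\n",
              length(x$documents),
              sum(lengths(x$documents)), length(x$vocabulary)))
  invisible(x)
}

#' Read a corpus from disk
#'
#' Two UTF-8 plain-text layouts are supported: `"lines"` — one document
#' per line, whitespace-separated tokens; `"table"` — a two-column CSV
#' `doc_id, token`, one token per row, document order = first-appearance
#' order of `doc_id`.
#'
#' @param path input file.
#' @param format `"lines"` or `"table"`.
#' @return a [corpus()].
#' @export
read_corpus <- function(path, format = c("lines", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "lines") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    docs <- stringi::stri_split_regex(lines, "\\s+", omit_empty = TRUE)
    corpus(docs)
  } else {
    df <- utils::read.csv(path, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
    if (!all(c("doc_id", "token") %in% names(df)))
      stop("format error: table corpus needs columns doc_id, token")
    ids <- unique(df$doc_id)
    docs <- split(df$token, factor(df$doc_id, levels = ids))
    corpus(unname(docs), doc_ids = ids)
  }
}

#' Filter a corpus by target-word occurrence
#'
#' Mirrors the construction of a category-specific training set from a
#' general encyclopedia dump: (i) targets are retained only if their
#' document count in the *original* corpus is strictly greater than
#' `min_docs` (the default 10 mirrors "appeared in more than ten
#' articles"); (ii) documents are retained if they contain at least one
#' retained target. Document order is preserved.
#'
#' @param corp a [corpus()].
#' @param targets character vector of target words (non-empty).
#' @param min_docs strict lower bound on the per-target document count.
#' @return list with `corpus` (the filtered sub-corpus) and `targets`
#'   (the retained target words, in input order).
#' @export
filter_corpus <- function(corp, targets, min_docs = 10L) {
  stopifnot(inherits(corp, "vft_corpus"))
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("targets must be non-empty")
  counts <- corp$doc_count_per_word[targets]
  counts[is.na(counts)] <- 0L
  kept_targets <- targets[counts > min_docs]
  keep_doc <- vapply(corp$documents,
                     function(d) any(kept_targets %in% d), logical(1))
  if (!any(keep_doc))
    warning("no documents contain a retained target; result is empty")
  list(corpus = corpus(corp$documents[keep_doc],
                       doc_ids = corp$doc_ids[keep_doc]),
       targets = kept_targets)
}
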