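#' Topic-probability lexicons
#'
#' A topic lexicon maps each word of a semantic category (e.g. animal
#' names) to a vector of K topic probabilities: `probs[w, k]` is
#' P(topic k | word w), the probability that latent topic k underlies the
#' use of word w. Each row sums to 1 — the lexicon is the model's semantic
#' representation, and cluster detection operates on it directly.
#'
#' @param probs numeric matrix, one row per word, K columns of topic
#'   probabilities in `[0, 1]`; rows must sum to 1 within `tol`.
#' @param words character vector of unique word strings (UTF-8). Defaults
#'   to `rownames(probs)`.
#' @param metadata named list of free-form provenance notes (corpus id,
#'   K, alpha, seed, ...).
#' @param normalization word-normalization policy: `"nfkc"` (Unicode NFKC
#'   plus whitespace trimming, the default) or `"none"`. Kana/kanji or
#'   other script variants are never conflated.
#' @param tol sum-to-one tolerance used at construction.
#' @return an object of class `topic_lexicon`: a list with elements
#'   `words`, `K`, `probs` (matrix with words as rownames) and `metadata`.
#' @examples
#' lex <- topic_lexicon(rbind(dog = c(0.7, 0.3), cat = c(0.6, 0.4)))
#' lex$K
#' @seealso [read_lexicon()], [validate_lexicon()], [derive_threshold()]
#' @export
topic_lexicon <- function(probs, words = rownames(probs), metadata = list(),
                          normalization = c("nfkc", "none"), tol = 1e-6) {
  normalization <- match.arg(normalization)
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  if (is.null(words)) stop("`words` must be supplied (or set as rownames)")
  words <- normalize_words(as.character(words), normalization)
  if (length(words) != nrow(probs))
    stop("length(words) must equal nrow(probs)")
  if (anyDuplicated(words))
    stop("duplicate words after normalization: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  rownames(probs) <- words
  if (is.null(colnames(probs)))
    colnames(probs) <- paste0("topic_", seq_len(ncol(probs)))
  lex <- structure(
    list(words = words, K = ncol(probs), probs = probs,
         metadata = c(metadata, list(normalization = normalization))),
    class = "topic_lexicon")
  rep_ <- validate_lexicon(lex, tol = tol)
  if (nrow(rep_) > 0L)
    stop("invalid lexicon:\n", format_validation(rep_))
  lex
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat(sprintf("topic_lexicon: %d words x %d topics\n", length(x$words), x$K))
  if (length(x$words) > 0L)
    cat("  words: ", paste(utils::head(x$words, 5L), collapse = ", "),
        if (length(x$words) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# NFKC + trim; exact surface-form matching otherwise (no script conversion)
normalize_words <- function(words, normalization = "nfkc") {
  if (identical(normalization, "none")) return(words)
  stringi::stri_trim_both(stringi::stri_trans_nfkc(words))
}

#' Validate a topic lexicon
#'
#' Checks every lexicon invariant and returns a report of violations
#' rather than raising: rows must sum to 1 within `tol`, all entries must
#' lie in `[0, 1]`, words must be unique and non-empty. An empty report
#' means the lexicon is valid at `tol`.
#'
#' @param lex a [topic_lexicon()] (or a bare list with the same fields,
#'   so that files can be checked before construction succeeds).
#' @param tol sum-to-one tolerance. Use `1e-6` for internally generated
#'   lexicons; published tables are rounded, so `1e-3` is appropriate
#'   for files read from disk.
#' @return a data frame with columns `word`, `row`, `invariant`,
#'   `detail`; zero rows iff all invariants hold.
#' @examples
#' lex <- simulate_lexicon(20, K = 5, concentration = 0.2, seed = 1)
#' nrow(validate_lexicon(lex))  # 0
#' @export
validate_lexicon <- function(lex, tol = 1e-6) {
  probs <- lex$probs
  words <- lex$words
  out <- list()
  add <- function(word, row, invariant, detail)
    out[[length(out) + 1L]] <<- data.frame(
      word = word, row = row, invariant = invariant, detail = detail,
      stringsAsFactors = FALSE)
  dup <- duplicated(words)
  for (i in which(dup))
    add(words[i], i, "unique-words", "duplicate of an earlier word")
  for (i in which(!nzchar(words)))
    add(words[i], i, "nonempty-word", "empty word string")
  bad_lo <- which(apply(probs, 1L, function(r) any(r < 0)))
  for (i in bad_lo)
    add(words[i], i, "nonnegative",
        sprintf("entry %.6g < 0", min(probs[i, ])))
  bad_hi <- which(apply(probs, 1L, function(r) any(r > 1)))
  for (i in bad_hi)
    add(words[i], i, "at-most-one",
        sprintf("entry %.6g > 1", max(probs[i, ])))
  sums <- rowSums(probs)
  for (i in which(abs(sums - 1) > tol))
    add(words[i], i, "sum-to-one",
        sprintf("row sums to %.6g (tol %.1e)", sums[i], tol))
  if (length(out) == 0L)
    return(data.frame(word = character(), row = integer(),
                      invariant = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

format_validation <- function(report) {
  paste(sprintf("  row %d (%s): %s — %s", report$row, report$word,
                report$invariant, report$detail), collapse = "\n")
}

#' Read a topic lexicon from CSV
#'
#' Expects a UTF-8 CSV with a header row: one word column (default
#' `word`) and K probability columns (default any columns other than the
#' word column, in file order). K is inferred from the header.
#'
#' @param path file path.
#' @param word_col name of the word column.
#' @param topic_cols optional character vector naming the probability
#'   columns, for files with extra columns or different headers.
#' @param normalization passed to [topic_lexicon()].
#' @param tol sum-to-one tolerance; default `1e-3` absorbs published
#'   rounding.
#' @return a validated [topic_lexicon()].
#' @export
read_lexicon <- function(path, word_col = "word", topic_cols = NULL,
                         normalization = c("nfkc", "none"), tol = 1e-3) {
  normalization <- match.arg(normalization)
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  if (!word_col %in% names(df))
    stop("format error: no word column '", word_col, "' in ", path)
  if (sum(names(df) == word_col) > 1L)
    stop("format error: duplicate word column '", word_col, "'")
  if (is.null(topic_cols)) topic_cols <- setdiff(names(df), word_col)
  if (length(topic_cols) < 1L)
    stop("format error: no topic-probability columns found")
  missing_cols <- setdiff(topic_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("format error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  mat <- as.matrix(df[topic_cols])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[topic_cols], is.numeric, logical(1)))
    for (j in bad) {
      col <- topic_cols[j]
      row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))[1L]
      stop(sprintf("parse error: non-numeric probability at row %d, column '%s'",
                   row, col))
    }
  }
  topic_lexicon(mat, words = df[[word_col]],
                metadata = list(source = path),
                normalization = normalization, tol = tol)
}

#' Write a topic lexicon to CSV
#'
#' Inverse of [read_lexicon()]: UTF-8 CSV with columns
#' `word, topic_1 ... topic_K`, probabilities rounded to `digits`
#' decimals (default 6, the declared round-trip precision).
#'
#' @param lex a [topic_lexicon()].
#' @param path output file path.
#' @param digits decimal precision of the written probabilities.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, digits = 6) {
  stopifnot(inherits(lex, "topic_lexicon"))
  df <- data.frame(word = lex$words,
                   round(lex$probs, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("word", paste0("topic_", seq_len(lex$K)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Derive the clustering criterion from a lexicon
#'
#' Returns the lowest, over words, of the maximum topic probability —
#' the largest threshold below which every word can still exceed the
#' criterion on at least one topic and hence participate in a cluster.
#' The exact minimum is returned; see [criterion()] for the fixed
#' published default.
#'
#' @param lex a non-empty, valid [topic_lexicon()].
#' @return a single probability.
#' @examples
#' lex <- topic_lexicon(matrix(0.1, 1, 10, dimnames = list("w", NULL)))
#' derive_threshold(lex)  # 0.1
#' @export
derive_threshold <- function(lex) {
  stopifnot(inherits(lex, "topic_lexicon"))
  if (length(lex$words) == 0L) stop("empty lexicon")
  min(apply(lex$probs, 1L, max))
}

#' Clustering criterion
#'
#' The probability threshold used by [link_adjacent()] and
#' [detect_clusters()]: two consecutive responses are linked when both
#' strictly exceed the threshold on a shared topic. The default 0.13 is
#' the published fixed criterion, chosen just below the lexicon-wide
#' minimum of the per-word maximum topic probability so that every word
#' can form a cluster; `derived-from-lexicon` instead uses
#' [derive_threshold()] on a supplied lexicon.
#'
#' @param threshold probability in (0, 1); ignored when `lex` is given.
#' @param lex optional [topic_lexicon()]; when supplied the threshold is
#'   derived from it and `derivation` is set accordingly.
#' @param strict logical; compare strictly (`>`, the default — responses
#'   must *exceed* the criterion) or inclusively (`>=`, for sensitivity
#'   checks).
#' @return an object of class `vft_criterion` with fields `threshold`,
#'   `derivation` and `strict`.
#' @examples
#' criterion()              # the published default, 0.13
#' @export
criterion <- function(threshold = 0.13, lex = NULL, strict = TRUE) {
  derivation <- "fixed"
  if (!is.null(lex)) {
    threshold <- derive_threshold(lex)
    derivation <- "derived-from-lexicon"
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single probability in (0, 1)")
  structure(list(threshold = threshold, derivation = derivation,
                 strict = isTRUE(strict)),
            class = "vft_criterion")
}

#' @export
print.vft_criterion <- function(x, ...) {
  cat(sprintf("criterion: threshold = %g (%s, %s)\n", x$threshold,
              x$derivation, if (x$strict) "strict >" else "inclusive >="))
  invisible(x)
}

as_criterion <- function(x) {
  if (inherits(x, "vft_criterion")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(criterion(x))
  stop("expected a criterion() or a single numeric threshold")
}

#' Check a published lexicon file against its documented properties
#'
#' Convenience checker for the deposited animal-name lexicon (661 words,
#' 10 topics, rows summing to 1 at printed precision, lexicon-wide
#' minimum of the per-word maximum topic probability 0.136). The file is
#' not redistributed with this package; supply its path, or set
#' `options(semfluency.published_lexicon = <path>)`.
#'
#' @param path path to the published lexicon CSV.
#' @param word_col,topic_cols passed to [read_lexicon()].
#' @return a list with `n_words`, `K`, `max_row_sum_error`,
#'   `min_max_topic_probability` and the loaded `lexicon`.
#' @export
check_published_lexicon <- function(path = getOption("semfluency.published_lexicon"),
                                    word_col = "word", topic_cols = NULL) {
  if (is.null(path) || !file.exists(path %||% ""))
    stop("published lexicon file not available; supply `path` or set ",
         "options(semfluency.published_lexicon = ...)")
  lex <- read_lexicon(path, word_col = word_col, topic_cols = topic_cols,
                      tol = 1e-3)
  list(n_words = length(lex$words), K = lex$K,
       max_row_sum_error = max(abs(rowSums(lex$probs) - 1)),
       min_max_topic_probability = derive_threshold(lex),
       lexicon = lex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
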