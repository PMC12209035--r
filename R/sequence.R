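#' Verbal-fluency response sequences
#'
#' One participant's ordered, timestamped responses in a timed verbal
#' fluency trial (produce as many category members as possible, default
#' 60 s). Onsets are the manually or automatically determined start
#' times of each spoken response, in seconds from trial start, and must
#' be strictly increasing. Each response may carry one error flag:
#' `correct`, `repetition` (word already produced earlier in the trial)
#' or `intrusion` (word outside the target category); see
#' [annotate_errors()].
#'
#' @param words character vector of response words, in production order.
#' @param onsets numeric vector of onset times in seconds, strictly
#'   increasing, within `[0, task_duration]`.
#' @param participant_id identifier string.
#' @param flags optional character vector (`"correct"`, `"repetition"`,
#'   `"intrusion"`) or `NA` when not yet annotated.
#' @param task_duration trial length in seconds (default 60).
#' @param normalization word-normalization policy, as in
#'   [topic_lexicon()].
#' @return an object of class `response_sequence`: list with `words`,
#'   `onsets`, `flags`, `participant_id`, `task_duration`.
#' @examples
#' response_sequence(c("dog", "cat"), c(1.2, 2.0), "p01")
#' @export
response_sequence <- function(words, onsets, participant_id = "p1",
                              flags = NULL, task_duration = 60,
                              normalization = c("nfkc", "none")) {
  normalization <- match.arg(normalization)
  words <- normalize_words(as.character(words), normalization)
  onsets <- as.numeric(onsets)
  if (length(words) != length(onsets))
    stop("words and onsets must have equal length")
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  if (length(onsets) > 0L && (any(onsets < 0) || any(onsets > task_duration)))
    stop("onsets must lie in [0, task_duration]")
  if (is.null(flags)) flags <- rep(NA_character_, length(words))
  flags <- as.character(flags)
  ok <- is.na(flags) | flags %in% c("correct", "repetition", "intrusion")
  if (!all(ok)) stop("flags must be correct/repetition/intrusion or NA")
  structure(list(words = words, onsets = onsets, flags = flags,
                 participant_id = as.character(participant_id),
                 task_duration = task_duration),
            class = "response_sequence")
}

#' @export
print.response_sequence <- function(x, ...) {
  cat(sprintf("response_sequence '%s': %d responses in %g s\n",
              x$participant_id, length(x$words), x$task_duration))
  invisible(x)
}

#' @export
length.response_sequence <- function(x) length(x$words)

#' Read VFT transcripts from CSV
#'
#' Expects a UTF-8 CSV with columns `participant_id`, `word`, `onset_s`
#' and, optionally, a `flag` column and any number of manual-coder
#' cluster-id columns (their names given in `coder_cols`, or
#' auto-detected as columns matching `coder_`). Rows are grouped by
#' participant in file order.
#'
#' @param path transcript CSV.
#' @param coder_cols names of manual cluster-id columns; `NULL`
#'   auto-detects columns whose names start with `coder`.
#' @param task_duration trial length in seconds.
#' @param normalization word-normalization policy.
#' @return a named list, one element per participant: list with
#'   `sequence` (a [response_sequence()]) and `manual` (named list of
#'   integer cluster-id vectors, one per coder column; empty if none).
#' @export
read_transcripts <- function(path, coder_cols = NULL, task_duration = 60,
                             normalization = "nfkc") {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        stringsAsFactors = FALSE)
  need <- c("participant_id", "word", "onset_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("transcript missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("transcript file has no data rows")
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$onset_s))))
  if (length(bad) > 0L)
    stop("malformed onset_s at data row ", bad[1L])
  if (is.null(coder_cols))
    coder_cols <- grep("^coder", names(df), value = TRUE)
  ids <- unique(df$participant_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$participant_id == id, , drop = FALSE]
    seq_ <- response_sequence(
      rows$word, as.numeric(rows$onset_s), participant_id = id,
      flags = if ("flag" %in% names(rows)) rows$flag else NULL,
      task_duration = task_duration, normalization = normalization)
    manual <- lapply(rows[coder_cols], as.integer)
    list(sequence = seq_, manual = manual)
  })
  stats::setNames(out, ids)
}
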