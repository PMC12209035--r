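#' Are two responses linked on a shared topic?
#'
#' The core linking rule: two consecutive responses form part of the
#' same semantic cluster when there exists a topic on which both topic
#' probabilities exceed the criterion. The comparison is strict (`>`) by
#' default — the probabilities must *exceed* the criterion — so a
#' criterion of 0.13 still links a word whose maximum probability is
#' 0.136. Words absent from the lexicon carry the zero vector and can
#' never link.
#'
#' @param a,b numeric topic-probability vectors of equal length K.
#' @param crit a [criterion()] or a bare numeric threshold.
#' @return single logical.
#' @examples
#' link_adjacent(c(0.14, 0.86), c(0.14, 0.86), criterion(0.13))  # TRUE
#' link_adjacent(c(0.13, 0.87), c(0.87, 0.13), criterion(0.13))  # FALSE
#' @export
link_adjacent <- function(a, b, crit = criterion()) {
  crit <- as_criterion(crit)
  if (length(a) != length(b))
    stop("topic-probability vectors differ in length")
  if (crit$strict) any(a > crit$threshold & b > crit$threshold)
  else any(a >= crit$threshold & b >= crit$threshold)
}

#' Detect semantic clusters in a response sequence
#'
#' Computes the pairwise link flags with [link_adjacent()] and chains
#' linked pairs into maximal runs. The chaining is Markovian: the topic
#' that binds pair (i, i+1) need not be the topic that binds pair
#' (i+1, i+2), so a single cluster can drift across topics through
#' words with overlapping above-threshold probabilities. All responses
#' participate, including those flagged as repetitions or intrusions.
#' Responses absent from the lexicon receive the zero vector (they never
#' link) and are reported via the `unknown_words` attribute.
#'
#' @param seq_ a [response_sequence()].
#' @param lex a [topic_lexicon()].
#' @param crit a [criterion()] or numeric threshold.
#' @return an object of class `cluster_segmentation`: list with
#'   `run_id` (integer per response, 1-based, non-decreasing),
#'   `link_flags` (logical, one per adjacent pair), `runs` (integer
#'   matrix with columns `start`, `end`: 0-based half-open index spans),
#'   `threshold_used`, `strict`, `participant_id`, `n`.
#' @examples
#' lex <- simulate_lexicon(50, K = 5, concentration = 0.1, seed = 2)
#' s <- response_sequence(lex$words[1:4], 1:4)
#' detect_clusters(s, lex, criterion(0.13))
#' @export
detect_clusters <- function(seq_, lex, crit = criterion()) {
  stopifnot(inherits(seq_, "response_sequence"),
            inherits(lex, "topic_lexicon"))
  crit <- as_criterion(crit)
  n <- length(seq_$words)
  if (n == 0L) stop("empty response sequence")
  idx <- match(seq_$words, lex$words)
  unknown <- unique(seq_$words[is.na(idx)])
  probs <- matrix(0, n, lex$K)
  hit <- !is.na(idx)
  probs[hit, ] <- lex$probs[idx[hit], , drop = FALSE]
  above <- if (crit$strict) probs > crit$threshold else probs >= crit$threshold
  link_flags <- if (n > 1L)
    rowSums(above[-n, , drop = FALSE] & above[-1L, , drop = FALSE]) > 0
  else logical(0)
  segmentation_from_links(link_flags, n,
                          threshold_used = crit$threshold,
                          strict = crit$strict,
                          participant_id = seq_$participant_id,
                          unknown_words = unknown)
}

#' Build a segmentation from pairwise link flags
#'
#' Low-level constructor: given the logical link flag of each adjacent
#' response pair, chains linked pairs into maximal runs. Used by
#' [detect_clusters()] and [segmentation_from_ids()], and handy for
#' constructing segmentations directly in analyses and tests.
#'
#' @param link_flags logical vector, one flag per adjacent pair
#'   (length `n - 1`).
#' @param n number of responses.
#' @param threshold_used,strict,participant_id,unknown_words metadata
#'   carried into the result.
#' @return a `cluster_segmentation` (see [detect_clusters()]).
#' @export
segmentation_from_links <- function(link_flags, n, threshold_used = NA_real_,
                                    strict = TRUE, participant_id = NA_character_,
                                    unknown_words = character()) {
  stopifnot(length(link_flags) == max(n - 1L, 0L))
  run_id <- cumsum(c(1L, as.integer(!link_flags)))
  starts <- which(!duplicated(run_id)) - 1L            # 0-based
  ends <- c(starts[-1L], n)
  runs <- cbind(start = starts, end = ends)
  structure(list(run_id = run_id, link_flags = as.logical(link_flags),
                 runs = runs, threshold_used = threshold_used,
                 strict = strict, participant_id = participant_id,
                 n = as.integer(n), unknown_words = unknown_words),
            class = "cluster_segmentation")
}

#' Rebuild a segmentation from manual cluster ids
#'
#' Converts a human coder's per-response cluster-id column into a
#' `cluster_segmentation`: consecutive responses with the same id are
#' linked (ids are only compared between neighbours, so non-adjacent
#' reuse of an id does not merge runs).
#'
#' @param ids vector of cluster ids, one per response.
#' @param participant_id identifier carried into the result.
#' @return a `cluster_segmentation`.
#' @export
segmentation_from_ids <- function(ids, participant_id = NA_character_) {
  n <- length(ids)
  if (n == 0L) stop("empty id vector")
  link_flags <- if (n > 1L) ids[-n] == ids[-1L] & !is.na(ids[-n]) & !is.na(ids[-1L])
  else logical(0)
  segmentation_from_links(as.logical(link_flags), n,
                          participant_id = participant_id)
}

#' @export
print.cluster_segmentation <- function(x, ...) {
  cat(sprintf("cluster_segmentation '%s': %d responses, %d clusters (threshold %s)\n",
              x$participant_id, x$n, nrow(x$runs),
              format(x$threshold_used)))
  invisible(x)
}

run_sizes <- function(seg) as.integer(seg$runs[, "end"] - seg$runs[, "start"])

#' Mean cluster size
#'
#' Average number of responses per cluster. By default singleton runs
#' count as clusters of size 1 (so MCS = n responses / n clusters);
#' `include_singletons = FALSE` averages over runs of size >= 2 only and
#' returns `NA` when there are none.
#'
#' @param seg a `cluster_segmentation`.
#' @param include_singletons logical, default `TRUE`.
#' @return a single number, or `NA_real_`.
#' @examples
#' seg <- segmentation_from_links(c(TRUE, TRUE, FALSE, TRUE), 5)
#' mean_cluster_size(seg)  # runs of sizes 3 and 2 -> 2.5
#' @export
mean_cluster_size <- function(seg, include_singletons = TRUE) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  sizes <- run_sizes(seg)
  if (!include_singletons) {
    sizes <- sizes[sizes >= 2L]
    if (length(sizes) == 0L) return(NA_real_)
  }
  mean(sizes)
}

#' Cluster counts and switches
#'
#' @param seg a `cluster_segmentation`.
#' @return list with `n_runs` (all clusters, singletons included),
#'   `n_multi` (clusters of size >= 2) and `n_switches` (transitions
#'   between clusters = unlinked adjacent pairs = `n_runs - 1`).
#' @export
cluster_counts <- function(seg) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  sizes <- run_sizes(seg)
  list(n_runs = length(sizes), n_multi = sum(sizes >= 2L),
       n_switches = sum(!seg$link_flags))
}

#' Write a segmentation to JSON or CSV
#'
#' JSON carries `participant_id`, `threshold_used`, `runs` as 0-based
#' half-open `[start, end)` pairs and the per-pair `link_flags`; the CSV
#' form is flat: one row per response with its 0-based index, word (if
#' supplied), run id and linked-to-next flag.
#'
#' @param seg a `cluster_segmentation`.
#' @param path output path; format chosen by extension (`.json`/`.csv`).
#' @param words optional response words for the CSV form.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, words = NULL) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(participant_id = seg$participant_id,
                    threshold_used = seg$threshold_used,
                    n = seg$n,
                    runs = unname(apply(seg$runs, 1L, as.list)),
                    link_flags = seg$link_flags)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(index = seq_len(seg$n) - 1L,
                     word = if (is.null(words)) NA_character_ else words,
                     run_id = seg$run_id,
                     linked_to_next = c(seg$link_flags, NA),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
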