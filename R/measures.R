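#' Inter-response onset intervals
#'
#' The n-1 differences between consecutive response onsets; interval i
#' separates responses i and i+1 and is the quantity split into
#' within-cluster and out-of-cluster sets by [wci_oci()].
#'
#' @param seq_ a [response_sequence()].
#' @return numeric vector of positive interval lengths (seconds);
#'   empty for a single response.
#' @examples
#' s <- response_sequence(letters[1:5], c(0, 1, 2, 10, 11))
#' response_intervals(s)  # 1 1 8 1
#' @export
response_intervals <- function(seq_) {
  stopifnot(inherits(seq_, "response_sequence"))
  if (length(seq_$onsets) > 1L && any(diff(seq_$onsets) <= 0))
    stop("onsets must be strictly increasing")
  diff(seq_$onsets)
}

#' Within-cluster and out-of-cluster intervals
#'
#' WCI is the mean onset-to-onset interval between consecutive
#' responses inside the same cluster; OCI the mean interval between
#' consecutive responses in different clusters (i.e. across switches).
#' Each is the flat mean over the participant's intervals of that kind;
#' when one set is empty (e.g. the whole sequence is a single cluster,
#' so there are no switches) the corresponding value is `NA`, to be
#' excluded — with its count reported — from cohort summaries rather
#' than silently zeroed.
#'
#' @param seg a `cluster_segmentation` over the same sequence.
#' @param intervals the [response_intervals()] of that sequence.
#' @return list with `wci`, `oci` (seconds or `NA_real_`), and the
#'   contributing interval counts `n_within`, `n_between`.
#' @examples
#' seg <- segmentation_from_links(c(TRUE, TRUE, FALSE, TRUE), 5)
#' wci_oci(seg, c(1, 1, 8, 1))  # wci 1, oci 8
#' @export
wci_oci <- function(seg, intervals) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  if (length(intervals) != length(seg$link_flags))
    stop("intervals length must equal the number of adjacent pairs")
  within <- intervals[seg$link_flags]
  between <- intervals[!seg$link_flags]
  list(wci = if (length(within)) mean(within) else NA_real_,
       oci = if (length(between)) mean(between) else NA_real_,
       n_within = length(within), n_between = length(between))
}

#' Word-frequency decay over the trial
#'
#' Participants tend to produce high-frequency category members first
#' and rarer ones later; the frequency effect is the ordinary
#' least-squares slope of log word frequency on response onset, in log
#' units per second (negative = decay). The log base (default 10) and
#' the provenance of the frequency norms determine the slope's scale,
#' so both are the caller's choice; responses without a known frequency
#' are excluded and counted.
#'
#' @param seq_ a [response_sequence()].
#' @param freq named numeric vector or two-column data frame
#'   (`word`, `count`) of frequency counts (> 0).
#' @param log_base base of the logarithm (default 10).
#' @return list with `slope` (or `NA_real_` when fewer than 2 usable
#'   responses), `n_used`, `n_unknown`, `log_base`.
#' @examples
#' s <- response_sequence(c("a", "b"), c(0, 10))
#' frequency_effect(s, c(a = 1e5, b = 1e4))  # slope -0.1
#' @export
frequency_effect <- function(seq_, freq, log_base = 10) {
  stopifnot(inherits(seq_, "response_sequence"))
  if (is.data.frame(freq)) {
    stopifnot(all(c("word", "count") %in% names(freq)))
    freq <- stats::setNames(as.numeric(freq$count),
                            normalize_words(as.character(freq$word)))
  }
  f <- freq[seq_$words]
  usable <- !is.na(f) & f > 0
  n_unknown <- sum(!usable)
  if (sum(usable) < 2L)
    return(list(slope = NA_real_, n_used = sum(usable),
                n_unknown = n_unknown, log_base = log_base))
  y <- log(as.numeric(f[usable]), base = log_base)
  x <- seq_$onsets[usable]
  slope <- if (stats::var(x) == 0) NA_real_
  else unname(stats::coef(stats::lm(y ~ x))[2L])
  list(slope = slope, n_used = sum(usable), n_unknown = n_unknown,
       log_base = log_base)
}

#' Annotate repetitions and intrusions
#'
#' Flags each response: `repetition` if the (normalized) word already
#' occurred earlier in the trial — the later occurrence is flagged —
#' else `intrusion` if the word is absent from the category word list,
#' else `correct`. Lexicon absence is a proxy for "outside the target
#' category"; pass a dedicated category word list via `category_words`
#' to override.
#'
#' @param seq_ a [response_sequence()].
#' @param lex a [topic_lexicon()] whose words define category
#'   membership.
#' @param category_words optional character vector replacing the
#'   lexicon as the membership list.
#' @return the sequence with `flags` filled in.
#' @examples
#' lex <- topic_lexicon(matrix(c(.5, .5, .4, .6), 2, byrow = TRUE,
#'                             dimnames = list(c("dog", "cat"), NULL)))
#' s <- annotate_errors(response_sequence(c("dog", "cat", "dog"), 1:3), lex)
#' s$flags
#' @export
annotate_errors <- function(seq_, lex, category_words = NULL) {
  stopifnot(inherits(seq_, "response_sequence"))
  members <- if (!is.null(category_words))
    normalize_words(as.character(category_words))
  else {
    stopifnot(inherits(lex, "topic_lexicon"))
    lex$words
  }
  flags <- ifelse(duplicated(seq_$words), "repetition",
                  ifelse(seq_$words %in% members, "correct", "intrusion"))
  seq_$flags <- flags
  seq_
}

#' Assemble the per-participant measure battery
#'
#' One row of scalar outcomes per participant and coding source:
#' response counts by error type, mean cluster size, cluster and switch
#' counts, within-/out-of-cluster intervals, and the frequency-effect
#' slope. Undefined measures propagate as `NA`, never as 0.
#'
#' @param seq_ an annotated [response_sequence()] (run
#'   [annotate_errors()] first; unannotated responses count as correct
#'   with a warning).
#' @param seg the `cluster_segmentation` of the same sequence.
#' @param freq optional frequency table for [frequency_effect()].
#' @param coder_label source of the segmentation (e.g. `"LDA"`,
#'   `"coder1"`).
#' @param include_singletons passed to [mean_cluster_size()].
#' @param log_base passed to [frequency_effect()].
#' @return a one-row data frame with columns `participant_id`, `coder`,
#'   `n_responses`, `n_correct`, `n_repetitions`, `n_intrusions`,
#'   `mcs`, `n_runs`, `n_multi`, `n_switches`, `wci`, `oci`,
#'   `freq_slope`.
#' @export
compute_measures <- function(seq_, seg, freq = NULL, coder_label = "LDA",
                             include_singletons = TRUE, log_base = 10) {
  stopifnot(inherits(seq_, "response_sequence"),
            inherits(seg, "cluster_segmentation"))
  if (length(seq_$words) != seg$n)
    stop("segmentation does not correspond to the sequence")
  flags <- seq_$flags
  if (anyNA(flags)) {
    warning("unannotated responses treated as correct")
    flags[is.na(flags)] <- "correct"
  }
  counts <- cluster_counts(seg)
  iv <- response_intervals(seq_)
  wo <- wci_oci(seg, iv)
  fe <- if (is.null(freq)) list(slope = NA_real_)
  else frequency_effect(seq_, freq, log_base = log_base)
  data.frame(participant_id = seq_$participant_id, coder = coder_label,
             n_responses = length(seq_$words),
             n_correct = sum(flags == "correct"),
             n_repetitions = sum(flags == "repetition"),
             n_intrusions = sum(flags == "intrusion"),
             mcs = mean_cluster_size(seg, include_singletons),
             n_runs = counts$n_runs, n_multi = counts$n_multi,
             n_switches = counts$n_switches,
             wci = wo$wci, oci = wo$oci, freq_slope = fe$slope,
             stringsAsFactors = FALSE)
}

#' Score a cohort of response sequences
#'
#' Applies error annotation, cluster detection and the full measure
#' battery to every participant; manual coder cluster ids, when
#' supplied, yield additional rows per participant.
#'
#' @param transcripts a list as returned by [read_transcripts()], or a
#'   bare list of [response_sequence()] objects.
#' @param lex a [topic_lexicon()].
#' @param crit a [criterion()].
#' @param freq optional frequency table.
#' @param include_singletons,log_base passed through.
#' @return a data frame, one row per participant x coding source.
#' @export
score_cohort <- function(transcripts, lex, crit = criterion(), freq = NULL,
                         include_singletons = TRUE, log_base = 10) {
  rows <- lapply(transcripts, function(entry) {
    if (inherits(entry, "response_sequence"))
      entry <- list(sequence = entry, manual = list())
    seq_ <- annotate_errors(entry$sequence, lex)
    seg <- detect_clusters(seq_, lex, crit)
    out <- list(compute_measures(seq_, seg, freq = freq,
                                 coder_label = "LDA",
                                 include_singletons = include_singletons,
                                 log_base = log_base))
    for (coder in names(entry$manual)) {
      mseg <- segmentation_from_ids(entry$manual[[coder]],
                                    participant_id = seq_$participant_id)
      out[[length(out) + 1L]] <-
        compute_measures(seq_, mseg, freq = freq, coder_label = coder,
                         include_singletons = include_singletons,
                         log_base = log_base)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of the measure battery
#'
#' Mean, SD and n per coding source for each numeric measure, with `NA`
#' values excluded listwise per measure and the exclusion visible in
#' `n` (participants whose sequence forms, e.g., a single cluster have
#' no out-of-cluster interval and drop out of the OCI summary).
#'
#' @param measures output of [score_cohort()].
#' @return a data frame with columns `coder`, `measure`, `mean`, `sd`,
#'   `n`.
#' @export
cohort_summary <- function(measures) {
  num_cols <- c("n_responses", "n_correct", "n_repetitions",
                "n_intrusions", "mcs", "n_runs", "n_multi", "n_switches",
                "wci", "oci", "freq_slope")
  num_cols <- intersect(num_cols, names(measures))
  out <- list()
  for (coder in unique(measures$coder)) {
    sub <- measures[measures$coder == coder, , drop = FALSE]
    for (m in num_cols) {
      v <- sub[[m]][!is.na(sub[[m]])]
      out[[length(out) + 1L]] <- data.frame(
        coder = coder, measure = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
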