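#' Boundary labels of a segmentation
#'
#' Two clusterings of the same response sequence are compared on their
#' adjacent-pair labels: for each of the n-1 consecutive response
#' pairs, TRUE if the pair lies in the same cluster. The labels are the
#' segmentation's link flags and reconstruct the run structure exactly,
#' so they are a lossless common currency for agreement statistics.
#'
#' @param seg a `cluster_segmentation`.
#' @param source coder label carried along for reporting.
#' @return an object of class `boundary_labels`: list with `labels`
#'   (logical vector) and `source`.
#' @export
segmentation_to_labels <- function(seg, source = seg$participant_id) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  structure(list(labels = seg$link_flags, source = as.character(source)),
            class = "boundary_labels")
}

as_labels <- function(x) {
  if (inherits(x, "boundary_labels")) return(x$labels)
  if (inherits(x, "cluster_segmentation")) return(x$link_flags)
  as.logical(x)
}

#' Cohen's kappa between two boundary labelings
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where
#' p_o is the proportion of adjacent pairs on which the two labelings
#' agree and p_e the agreement expected from the two labelings'
#' marginal frequencies of same-cluster labels. When both raters are
#' constant with identical margins p_e = 1 and kappa is undefined
#' (`NA`), reported as missing rather than coerced to a number.
#'
#' @param a,b `boundary_labels`, `cluster_segmentation`s, or logical
#'   vectors of equal length >= 1.
#' @return a single number in `[-1, 1]`, or `NA_real_`.
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))  # 0
#' @export
cohen_kappa <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  if (length(a) != length(b)) stop("labelings differ in length")
  n <- length(a)
  if (n < 1L) stop("labelings must have length >= 1")
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Cohort-level inter-coder agreement
#'
#' Computes kappa per participant and summarizes: unweighted mean and
#' SD over participants, with undefined kappas excluded and counted.
#'
#' @param pairs list of length-2 lists/pairs of labelings (anything
#'   [cohen_kappa()] accepts), one per participant.
#' @return list with `kappa` (per-participant vector), `mean`, `sd`,
#'   `n` (participants with defined kappa), `n_undefined`.
#' @export
cohort_agreement <- function(pairs) {
  kap <- vapply(pairs, function(p) cohen_kappa(p[[1L]], p[[2L]]),
                numeric(1))
  ok <- !is.na(kap)
  list(kappa = kap,
       mean = if (any(ok)) mean(kap[ok]) else NA_real_,
       sd = if (sum(ok) > 1L) stats::sd(kap[ok]) else NA_real_,
       n = sum(ok), n_undefined = sum(!ok))
}

#' Agreement report across coder pairs
#'
#' Builds the per-participant kappa table for every pair of coding
#' sources present in a scored transcript list: the automatic (LDA)
#' segmentation and each manual coder column.
#'
#' @param transcripts list from [read_transcripts()].
#' @param lex a [topic_lexicon()].
#' @param crit a [criterion()].
#' @return a data frame `participant_id`, `coder_a`, `coder_b`,
#'   `kappa`.
#' @export
agreement_report <- function(transcripts, lex, crit = criterion()) {
  rows <- list()
  for (entry in transcripts) {
    seq_ <- entry$sequence
    labelings <- list(LDA = detect_clusters(seq_, lex, crit)$link_flags)
    for (coder in names(entry$manual))
      labelings[[coder]] <-
        segmentation_from_ids(entry$manual[[coder]])$link_flags
    src <- names(labelings)
    if (length(src) < 2L) next
    for (i in seq_len(length(src) - 1L)) for (j in seq(i + 1L, length(src))) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = seq_$participant_id,
        coder_a = src[i], coder_b = src[j],
        kappa = cohen_kappa(labelings[[i]], labelings[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(participant_id = character(), coder_a = character(),
                      coder_b = character(), kappa = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
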