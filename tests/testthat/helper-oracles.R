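# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force loops, union-find, contingency
# tables.

# union-find segmentation oracle: unions i with i+1 whenever a double
# nested loop over topics finds a shared above-threshold topic
oracle_segment <- function(probs, threshold, strict = TRUE) {
  n <- nrow(probs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  link <- logical(max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    linked <- FALSE
    for (k in seq_len(ncol(probs))) {
      ai <- probs[i, k]; bi <- probs[i + 1L, k]
      hit <- if (strict) ai > threshold && bi > threshold
      else ai >= threshold && bi >= threshold
      if (hit) { linked <- TRUE; break }
    }
    link[i] <- linked
    if (linked) parent[find(i + 1L)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(run_id = as.integer(factor(roots, levels = unique(roots))),
       link_flags = link)
}

# contingency-table kappa oracle (distinct algebra from the package's
# marginal-product formula)
oracle_kappa <- function(a, b) {
  tab <- table(factor(a, levels = c(FALSE, TRUE)),
               factor(b, levels = c(FALSE, TRUE)))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# probability matrix of a word sequence under a lexicon, zeros for
# unknown words (recomputed independently of detect_clusters)
lookup_probs <- function(words, lex) {
  out <- matrix(0, length(words), lex$K)
  for (i in seq_along(words)) {
    j <- match(words[i], lex$words)
    if (!is.na(j)) out[i, ] <- lex$probs[j, ]
  }
  out
}

# tiny fixed two-word lexicon used in several tests
tiny_lexicon <- function() {
  topic_lexicon(rbind(alpha = c(0.5, 0.5), beta = c(1.0, 0.0)))
}
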