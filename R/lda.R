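#' Fit a latent Dirichlet allocation model by collapsed Gibbs sampling
#'
#' Estimates the topic-word distributions of an LDA model on a token
#' corpus. The sampler integrates out the document-topic and topic-word
#' multinomials and resamples one token-topic assignment at a time from
#' the collapsed conditional; posterior means are averaged over retained
#' post-burn-in samples. Runs are fully reproducible given `seed`.
#'
#' The defaults `K = 10`, `alpha = 0.4` are the settings used for the
#' animal-category lexicon this package is built around; the topic-word
#' prior `beta` defaults to the common symmetric 0.01 and is recorded in
#' the fit. Model selection over K is deliberately not automated —
#' interpretability of the topics is a human judgment — but the
#' in-sample log-likelihood trace (`loglik`) is returned to support it.
#'
#' @param corp a [corpus()].
#' @param K number of topics (>= 1).
#' @param alpha symmetric document-topic Dirichlet prior (> 0).
#' @param beta symmetric topic-word Dirichlet prior (> 0).
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer RNG seed.
#' @return an object of class `lda_fit`: list with `K`, `alpha`, `beta`,
#'   `vocabulary`, `word_topic_weights` (K x V matrix, each row a
#'   topic's word distribution summing to 1), `topic_weights`
#'   (corpus-level topic proportions, summing to 1), `loglik`
#'   (per-sweep trace), `seed`, `iterations`, `burn_in`, `thin`,
#'   `n_samples`.
#' @examples
#' sim <- simulate_corpus(K = 2, vocab_size = 30, n_docs = 40,
#'                        doc_length = 25, seed = 1)
#' fit <- fit_lda(sim$corpus, K = 2, iterations = 200, burn_in = 50,
#'                seed = 1)
#' rowSums(fit$word_topic_weights)  # each 1
#' @export
fit_lda <- function(corp, K = 10L, alpha = 0.4, beta = 0.01,
                    iterations = 2000L, burn_in = 500L, thin = 10L,
                    seed = 1L) {
  stopifnot(inherits(corp, "vft_corpus"))
  if (length(corp$documents) == 0L) stop("corpus is empty")
  K <- as.integer(K)
  stopifnot(K >= 1L, alpha > 0, beta > 0, iterations > burn_in,
            burn_in >= 0L, thin >= 1L)
  vocab <- corp$vocabulary
  if (K > length(vocab))
    warning("K exceeds vocabulary size; topics will be degenerate")
  keep <- lengths(corp$documents) > 0L
  if (!all(keep)) {
    message(sum(!keep), " zero-length document(s) dropped")
  }
  docs <- lapply(corp$documents[keep],
                 function(d) match(d, vocab) - 1L)
  set.seed(seed)
  res <- gibbs_lda_cpp(docs, V = length(vocab), K = K, alpha = alpha,
                       beta = beta, iterations = as.integer(iterations),
                       burn_in = as.integer(burn_in),
                       thin = as.integer(thin))
  phi <- res$phi
  colnames(phi) <- vocab
  rownames(phi) <- paste0("topic_", seq_len(K))
  structure(list(K = K, alpha = alpha, beta = beta, vocabulary = vocab,
                 word_topic_weights = phi,
                 topic_weights = as.numeric(res$topic_weights),
                 loglik = as.numeric(res$loglik),
                 seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_samples = res$n_samples),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("lda_fit: K = %d, alpha = %g, beta = %g, vocab %d, %d sweeps (%d samples), seed %d\n",
              x$K, x$alpha, x$beta, length(x$vocabulary), x$iterations,
              x$n_samples, x$seed))
  invisible(x)
}

#' Convert an LDA fit into a topic-probability lexicon
#'
#' Inverts the topic-word distributions into per-word topic
#' probabilities by Bayes' rule with the corpus-level topic proportions
#' as prior:
#' \deqn{P(k \mid w) = \frac{\pi_k \, \phi_{k w}}{\sum_j \pi_j \, \phi_{j w}}}
#' so that each word's probabilities sum to 1 across topics — the
#' representation cluster detection consumes.
#'
#' @param fit an [fit_lda()] result.
#' @param words words to include; defaults to the full vocabulary.
#'   Words missing from the vocabulary, or with zero total weight, are
#'   excluded with a warning.
#' @return a [topic_lexicon()] whose metadata records K, alpha, beta and
#'   the seed.
#' @export
topic_probabilities <- function(fit, words = fit$vocabulary) {
  stopifnot(inherits(fit, "lda_fit"))
  words <- as.character(words)
  known <- words %in% fit$vocabulary
  if (!all(known)) {
    warning(sum(!known), " word(s) not in the fitted vocabulary, excluded: ",
            paste(utils::head(words[!known], 5L), collapse = ", "))
    words <- words[known]
  }
  if (length(words) == 0L) stop("no requested words are in the vocabulary")
  # joint weight pi_k * phi_kw, then normalize over topics per word
  joint <- fit$word_topic_weights[, words, drop = FALSE] * fit$topic_weights
  tot <- colSums(joint)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sum(zero), " word(s) with zero total weight excluded")
    joint <- joint[, !zero, drop = FALSE]
    words <- words[!zero]
    tot <- tot[!zero]
  }
  probs <- t(sweep(joint, 2L, tot, "/"))
  topic_lexicon(probs, words = words,
                metadata = list(K = fit$K, alpha = fit$alpha,
                                beta = fit$beta, seed = fit$seed,
                                iterations = fit$iterations))
}

#' Save / load an LDA fit archive
#'
#' The archive is a single JSON file holding the scalar header (K,
#' priors, seed, sweep counts), the vocabulary, and the full numeric
#' payload (topic-word matrix, topic weights, log-likelihood trace) at
#' full double precision; `read_lda_fit(write_lda_fit(fit))` reproduces
#' the fit.
#'
#' @param fit an `lda_fit`.
#' @param path output path (`.json`).
#' @return `path` invisibly; `read_lda_fit` returns the `lda_fit`.
#' @export
write_lda_fit <- function(fit, path) {
  stopifnot(inherits(fit, "lda_fit"))
  payload <- list(
    K = fit$K, alpha = fit$alpha, beta = fit$beta, seed = fit$seed,
    iterations = fit$iterations, burn_in = fit$burn_in, thin = fit$thin,
    n_samples = fit$n_samples, vocabulary = fit$vocabulary,
    topic_weights = fit$topic_weights, loglik = fit$loglik,
    word_topic_weights = fit$word_topic_weights)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lda_fit
#' @export
read_lda_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  phi <- p$word_topic_weights  # rowmajor JSON simplifies back to K x V
  dimnames(phi) <- list(paste0("topic_", seq_len(p$K)), p$vocabulary)
  structure(list(K = as.integer(p$K), alpha = p$alpha, beta = p$beta,
                 vocabulary = p$vocabulary, word_topic_weights = phi,
                 topic_weights = p$topic_weights, loglik = p$loglik,
                 seed = as.integer(p$seed),
                 iterations = as.integer(p$iterations),
                 burn_in = as.integer(p$burn_in),
                 thin = as.integer(p$thin),
                 n_samples = as.integer(p$n_samples)),
            class = "lda_fit")
}

#' Greedy topic matching between two topic-word matrices
#'
#' Utility for parameter-recovery checks: greedily pairs each recovered
#' topic with the unmatched planted topic of highest cosine similarity
#' and returns the matched similarities.
#'
#' @param recovered,planted K x V nonnegative matrices with aligned
#'   columns.
#' @return numeric vector of K matched cosine similarities, in recovered
#'   topic order of assignment (highest first).
#' @export
match_topics_cosine <- function(recovered, planted) {
  stopifnot(nrow(recovered) == nrow(planted),
            ncol(recovered) == ncol(planted))
  K <- nrow(recovered)
  normr <- sqrt(rowSums(recovered^2))
  normp <- sqrt(rowSums(planted^2))
  sim <- (recovered %*% t(planted)) / outer(normr, normp)
  out <- numeric(K)
  for (i in seq_len(K)) {
    best <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
    out[i] <- sim[best[1L], best[2L]]
    sim[best[1L], ] <- -Inf
    sim[, best[2L]] <- -Inf
  }
  out
}
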