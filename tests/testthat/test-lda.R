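test_that("corpus construction and document counts are consistent", {
  corp <- corpus(list(c("cat", "dog"), c("cat", "cat", "fish"), "bird"))
  expect_setequal(corp$vocabulary, c("cat", "dog", "fish", "bird"))
  expect_equal(unname(corp$doc_count_per_word["cat"]), 2L)  # per-document
  # recomputable from the documents
  recount <- vapply(corp$vocabulary, function(w)
    sum(vapply(corp$documents, function(d) w %in% d, logical(1))),
    integer(1))
  expect_equal(corp$doc_count_per_word, recount)
})

test_that("filter_corpus keeps targets strictly above min_docs", {
  corp <- corpus(list(c("cat", "x"), c("cat", "y"), c("z")))
  filt <- filter_corpus(corp, "cat", min_docs = 1)
  expect_identical(filt$targets, "cat")
  expect_length(filt$corpus$documents, 2L)

  # target in exactly min_docs documents is dropped (strict inequality)
  filt2 <- suppressWarnings(filter_corpus(corp, "cat", min_docs = 2))
  expect_length(filt2$targets, 0L)
  expect_error(filter_corpus(corp, character(0)), "non-empty")

  # planted-occurrence recount oracle on a larger random corpus
  set.seed(55)
  vocab <- paste0("t", 1:40)
  docs <- replicate(500, sample(vocab, sample(3:12, 1)), simplify = FALSE)
  big <- corpus(docs)
  targets <- sample(vocab, 10)
  min_docs <- 60
  filt3 <- filter_corpus(big, targets, min_docs = min_docs)
  oracle_counts <- vapply(targets, function(w)
    sum(vapply(docs, function(d) w %in% d, logical(1))), integer(1))
  expect_identical(filt3$targets, targets[oracle_counts > min_docs])
  oracle_docs <- vapply(docs, function(d)
    any(filt3$targets %in% d), logical(1))
  expect_identical(filt3$corpus$doc_ids, big$doc_ids[oracle_docs])
})

test_that("corpus files round-trip in both layouts", {
  dir <- withr::local_tempdir()
  lines_path <- file.path(dir, "corpus.txt")
  writeLines(c("cat dog", "fish fish bird", "dog"), lines_path)
  corp <- read_corpus(lines_path)
  expect_length(corp$documents, 3L)
  expect_equal(corp$documents[[2]], c("fish", "fish", "bird"))

  table_path <- file.path(dir, "corpus.csv")
  utils::write.csv(data.frame(doc_id = c("d1", "d1", "d2"),
                              token = c("cat", "dog", "fish")),
                   table_path, row.names = FALSE)
  corp2 <- read_corpus(table_path, format = "table")
  expect_identical(corp2$doc_ids, c("d1", "d2"))
  expect_equal(corp2$documents[[1]], c("cat", "dog"))
})

test_that("K = 1 collapses to smoothed corpus frequencies", {
  sim <- simulate_corpus(K = 1, vocab_size = 25, n_docs = 15,
                         doc_length = 40, seed = 3)
  fit <- fit_lda(sim$corpus, K = 1, beta = 0.01, iterations = 20,
                 burn_in = 5, thin = 1, seed = 1)
  expect_equal(fit$topic_weights, 1)
  tokens <- unlist(sim$corpus$documents)
  counts <- table(factor(tokens, levels = fit$vocabulary))
  expected <- (as.numeric(counts) + 0.01) /
    (length(tokens) + 0.01 * length(fit$vocabulary))
  expect_equal(unname(fit$word_topic_weights[1, ]), expected,
               tolerance = 1e-12)
  # every word maps to [1.0]
  lex <- topic_probabilities(fit)
  expect_true(all(lex$probs == 1))
})

test_that("fit_lda is deterministic given the seed", {
  sim <- simulate_corpus(K = 3, vocab_size = 40, n_docs = 30,
                         doc_length = 25, seed = 6)
  f1 <- fit_lda(sim$corpus, K = 3, iterations = 100, burn_in = 20,
                seed = 123)
  f2 <- fit_lda(sim$corpus, K = 3, iterations = 100, burn_in = 20,
                seed = 123)
  expect_identical(f1$word_topic_weights, f2$word_topic_weights)
  expect_identical(f1$topic_weights, f2$topic_weights)
  # rows are distributions
  expect_equal(unname(rowSums(f1$word_topic_weights)), rep(1, 3),
               tolerance = 1e-6)
  expect_equal(sum(f1$topic_weights), 1, tolerance = 1e-6)
})

test_that("in-sample log-likelihood improves after burn-in on average", {
  sim <- simulate_corpus(K = 4, vocab_size = 80, n_docs = 60,
                         doc_length = 40, seed = 14)
  fit <- fit_lda(sim$corpus, K = 4, iterations = 150, burn_in = 50,
                 seed = 2)
  early <- mean(fit$loglik[1:10])
  late <- mean(fit$loglik[101:150])
  expect_gt(late, early)
})

test_that("topic_probabilities applies the Bayes inversion", {
  # hand-set 2-topic fit: topic weights (0.5, 0.5); word weight 0.3 in
  # topic 1 and 0.1 in topic 2 -> P(topic|word) = (0.75, 0.25)
  fit <- structure(list(
    K = 2L, alpha = 0.4, beta = 0.01, vocabulary = c("w", "other"),
    word_topic_weights = matrix(c(0.3, 0.1, 0.7, 0.9), 2, 2,
                                dimnames = list(NULL, c("w", "other"))),
    topic_weights = c(0.5, 0.5), loglik = numeric(0), seed = 1L,
    iterations = 0L, burn_in = 0L, thin = 1L, n_samples = 1L),
    class = "lda_fit")
  lex <- topic_probabilities(fit, "w")
  expect_equal(unname(lex$probs["w", ]), c(0.75, 0.25))

  # invariant to rescaling all word-topic weights by a constant
  fit2 <- fit
  fit2$word_topic_weights <- fit$word_topic_weights * 37
  expect_equal(topic_probabilities(fit2, "w")$probs,
               lex$probs)

  # missing words are reported, output rows always sum to 1
  expect_warning(topic_probabilities(fit, c("w", "ghost")), "not in")
})

test_that("built lexicons validate at 1e-6 by construction", {
  sim <- simulate_corpus(K = 3, vocab_size = 60, n_docs = 40,
                         doc_length = 30, seed = 8)
  fit <- fit_lda(sim$corpus, K = 3, iterations = 120, burn_in = 40,
                 seed = 4)
  lex <- topic_probabilities(fit)
  expect_equal(nrow(validate_lexicon(lex, tol = 1e-6)), 0L)
})

test_that("fit archives round-trip exactly", {
  sim <- simulate_corpus(K = 2, vocab_size = 30, n_docs = 20,
                         doc_length = 20, seed = 5)
  fit <- fit_lda(sim$corpus, K = 2, iterations = 60, burn_in = 20,
                 seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_fit(fit, path)
  back <- read_lda_fit(path)
  expect_equal(back$word_topic_weights, fit$word_topic_weights)
  expect_equal(back$topic_weights, fit$topic_weights)
  expect_identical(back$vocabulary, fit$vocabulary)
  expect_identical(back$K, fit$K)
  expect_identical(back$seed, fit$seed)
})
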