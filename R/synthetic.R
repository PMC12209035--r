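#' Simulate a topic-probability lexicon
#'
#' Draws each word's topic-probability vector from a symmetric
#' Dirichlet(concentration): small concentrations give peaked,
#' near-one-topic words (strong planted cluster structure); large
#' concentrations approach the uniform 1/K vector. Deterministic given
#' `seed`, and valid at tolerance 1e-6 by construction.
#'
#' @param n_words number of words.
#' @param K number of topics.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed integer RNG seed.
#' @param words optional word strings; default `w001 ...`.
#' @return a [topic_lexicon()] whose metadata records the generator
#'   settings.
#' @examples
#' simulate_lexicon(100, K = 10, concentration = 0.1, seed = 7)
#' @export
simulate_lexicon <- function(n_words, K = 10L, concentration = 0.1,
                             seed = 1L, words = NULL) {
  stopifnot(n_words >= 1L, K >= 1L, concentration > 0)
  set.seed(seed)
  probs <- rdirichlet(n_words, rep(concentration, K))
  if (is.null(words))
    words <- sprintf("w%0*d", max(3L, nchar(n_words)), seq_len(n_words))
  topic_lexicon(probs, words = words,
                metadata = list(generator = "dirichlet",
                                concentration = concentration,
                                seed = seed))
}

# symmetric-alpha Dirichlet via normalized gamma draws
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  # guard against all-zero rows at tiny alpha (numerically possible)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, sample.int(K, sum(zero), replace = TRUE)] <- 1
  x / rowSums(x)
}

#' Generator settings for synthetic response sequences
#'
#' Encodes the statistical structure the fluency measures assume: a
#' hidden topic state that persists or switches between consecutive
#' responses, two response-interval regimes (faster transitions within
#' a topic run than across runs — semantically closer retrievals take
#' less time), and a log-linear decay of word frequency over the
#' trial. Defaults follow the study conditions the package targets:
#' 20 responses per one-minute trial, 10 topics, persistence 0.7
#' (mean planted run length 1/(1-0.7) ≈ 3.3 responses), within-run
#' intervals 1.5 s (sd 0.5), switch intervals 4.0 s (sd 1.0), peaked
#' word vectors (concentration 0.1), frequency decay -0.006 log10
#' units/s with residual sd 0.2 around a baseline of 10^5 counts.
#'
#' @param K number of topics (>= 2).
#' @param n_responses responses per sequence.
#' @param topic_persistence probability the hidden topic is retained
#'   from one response to the next.
#' @param within_interval,switch_interval `c(mean, sd)` in seconds of
#'   the two interval regimes.
#' @param concentration Dirichlet concentration for lexicon words.
#' @param freq_slope generating log10-frequency decay per second.
#' @param freq_intercept log10 frequency at trial start.
#' @param freq_noise_sd residual sd of log10 frequency.
#' @param seed integer RNG seed.
#' @return a list of class `sequence_gen_spec`.
#' @export
sequence_gen_spec <- function(K = 10L, n_responses = 20L,
                              topic_persistence = 0.7,
                              within_interval = c(1.5, 0.5),
                              switch_interval = c(4.0, 1.0),
                              concentration = 0.1,
                              freq_slope = -0.006,
                              freq_intercept = 5,
                              freq_noise_sd = 0.2,
                              seed = 1L) {
  stopifnot(K >= 2L, n_responses >= 1L,
            topic_persistence >= 0, topic_persistence <= 1,
            length(within_interval) == 2L, length(switch_interval) == 2L,
            within_interval[2L] >= 0, switch_interval[2L] >= 0,
            concentration > 0, freq_noise_sd >= 0)
  structure(list(K = as.integer(K), n_responses = as.integer(n_responses),
                 topic_persistence = topic_persistence,
                 within_interval = within_interval,
                 switch_interval = switch_interval,
                 concentration = concentration, freq_slope = freq_slope,
                 freq_intercept = freq_intercept,
                 freq_noise_sd = freq_noise_sd, seed = as.integer(seed)),
            class = "sequence_gen_spec")
}

# positive truncated-normal interval draw (floor 0.05 s)
rinterval <- function(n, mean_sd) {
  pmax(stats::rnorm(n, mean_sd[1L], mean_sd[2L]), 0.05)
}

#' Simulate one response sequence with planted cluster structure
#'
#' A hidden topic state evolves by the persistence probability; each
#' response is drawn (without replacement while possible) from the
#' lexicon words whose argmax topic equals the current state, so the
#' planted structure is unambiguous while off-argmax probability mass
#' still exercises Markovian chaining at detection time. Onsets
#' accumulate within-regime intervals while the state persists and
#' switch-regime intervals when it changes. Per-response frequency
#' counts decay log-linearly with onset at the generating slope.
#'
#' @param spec a [sequence_gen_spec()].
#' @param lex a [topic_lexicon()] with `K` matching `spec$K`; states
#'   with no argmax-assigned word are never visited (resampled, with a
#'   notice).
#' @param participant_id identifier for the generated sequence.
#' @return list with `sequence` (a [response_sequence()]), `truth`
#'   (the generating `cluster_segmentation`), `states` (hidden topic
#'   per response) and `freq` (named per-word frequency counts).
#' @export
simulate_sequence <- function(spec, lex, participant_id = "sim") {
  stopifnot(inherits(spec, "sequence_gen_spec"),
            inherits(lex, "topic_lexicon"), lex$K == spec$K)
  set.seed(spec$seed)
  argmax <- apply(lex$probs, 1L, which.max)
  pools <- split(seq_along(lex$words), factor(argmax, levels = seq_len(lex$K)))
  eligible <- which(lengths(pools) > 0L)
  if (length(eligible) < 1L) stop("no topic has an eligible word")
  if (length(eligible) < lex$K)
    message(lex$K - length(eligible),
            " topic(s) have no argmax word and are skipped")
  n <- spec$n_responses
  states <- integer(n)
  words_idx <- integer(n)
  used <- integer(0)
  draw_word <- function(state) {
    pool <- setdiff(pools[[state]], used)
    if (length(pool) == 0L) pool <- pools[[state]]  # allow reuse if exhausted
    pool[sample.int(length(pool), 1L)]
  }
  states[1L] <- eligible[sample.int(length(eligible), 1L)]
  words_idx[1L] <- draw_word(states[1L])
  used <- words_idx[1L]
  switched <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L) + 1L) {
    stay <- stats::runif(1) < spec$topic_persistence
    if (stay || length(eligible) == 1L) {
      states[i] <- states[i - 1L]
      switched[i - 1L] <- FALSE
    } else {
      others <- setdiff(eligible, states[i - 1L])
      states[i] <- others[sample.int(length(others), 1L)]
      switched[i - 1L] <- TRUE
    }
    words_idx[i] <- draw_word(states[i])
    used <- c(used, words_idx[i])
  }
  gaps <- numeric(max(n - 1L, 0L))
  if (n > 1L) {
    gaps[!switched] <- rinterval(sum(!switched), spec$within_interval)
    gaps[switched] <- rinterval(sum(switched), spec$switch_interval)
  }
  onsets <- cumsum(c(rinterval(1L, spec$within_interval), gaps))
  task_duration <- max(60, ceiling(max(onsets)))
  words <- lex$words[words_idx]
  seq_ <- response_sequence(words, onsets, participant_id = participant_id,
                            flags = rep("correct", n),
                            task_duration = task_duration)
  logf <- spec$freq_intercept + spec$freq_slope * onsets +
    stats::rnorm(n, 0, spec$freq_noise_sd)
  freq <- stats::setNames(10^logf, words)
  freq <- freq[!duplicated(names(freq))]
  truth <- segmentation_from_links(!switched, n,
                                   participant_id = participant_id)
  list(sequence = seq_, truth = truth, states = states, freq = freq)
}

#' Simulate a planted-topic corpus
#'
#' Generates documents by the standard LDA generative process: per-topic
#' word distributions drawn once from Dirichlet(beta) over the
#' vocabulary, a per-document topic mixture from Dirichlet(alpha), then
#' `doc_length` tokens per document. The planted distributions are
#' returned for parameter-recovery checks.
#'
#' @param K topics; `vocab_size` vocabulary size; `n_docs` documents;
#'   `doc_length` tokens per document.
#' @param vocab_size,n_docs,doc_length sizes (>= 1).
#' @param alpha document-topic Dirichlet prior.
#' @param beta topic-word Dirichlet prior.
#' @param seed integer RNG seed.
#' @return list with `corpus` (a [corpus()]) and `phi` (K x vocab_size
#'   planted topic-word matrix, columns named like the vocabulary).
#' @export
simulate_corpus <- function(K = 5L, vocab_size = 200L, n_docs = 300L,
                            doc_length = 100L, alpha = 0.4, beta = 0.05,
                            seed = 1L) {
  stopifnot(K >= 1L, vocab_size >= 1L, n_docs >= 1L, doc_length >= 1L,
            alpha > 0, beta > 0)
  set.seed(seed)
  vocab <- sprintf("v%0*d", max(3L, nchar(vocab_size)), seq_len(vocab_size))
  phi <- rdirichlet(K, rep(beta, vocab_size))
  colnames(phi) <- vocab
  rownames(phi) <- paste0("topic_", seq_len(K))
  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    theta <- rdirichlet(1L, rep(alpha, K))[1L, ]
    z <- sample.int(K, doc_length, replace = TRUE, prob = theta)
    w <- vapply(z, function(k)
      sample.int(vocab_size, 1L, prob = phi[k, ]), integer(1))
    docs[[d]] <- vocab[w]
  }
  list(corpus = corpus(docs), phi = phi)
}

#' Simulate a complete synthetic fluency study
#'
#' A self-contained study bundle: one simulated lexicon and, for each
#' participant, a response sequence with its planted segmentation and
#' frequency counts. Sub-seeds are derived deterministically from
#' `seed` (lexicon: `seed`; participant i: `seed + i`), so any single
#' participant is reproducible in isolation.
#'
#' @param n_participants cohort size (default 49, a typical young-adult
#'   sample for this task).
#' @param n_words lexicon size.
#' @param spec a [sequence_gen_spec()] template; its `seed` field is
#'   overridden per participant.
#' @param seed master integer seed.
#' @return list with `lexicon`, `transcripts` (a [read_transcripts()]-
#'   shaped list whose `manual` slot carries the planted segmentation
#'   as coder `truth`), `truths` (named list of `cluster_segmentation`)
#'   and `freq` (merged named frequency vector).
#' @export
simulate_study <- function(n_participants = 49L, n_words = 300L,
                           spec = sequence_gen_spec(), seed = 1L) {
  lex <- simulate_lexicon(n_words, K = spec$K,
                          concentration = spec$concentration, seed = seed)
  transcripts <- list()
  truths <- list()
  freq <- numeric(0)
  for (i in seq_len(n_participants)) {
    spec_i <- spec
    spec_i$seed <- seed + i
    id <- sprintf("p%03d", i)
    sim <- simulate_sequence(spec_i, lex, participant_id = id)
    transcripts[[id]] <- list(sequence = sim$sequence,
                              manual = list(truth = sim$truth$run_id))
    truths[[id]] <- sim$truth
    freq <- c(freq, sim$freq[setdiff(names(sim$freq), names(freq))])
  }
  list(lexicon = lex, transcripts = transcripts, truths = truths,
       freq = freq)
}

#' Write a synthetic study to disk
#'
#' Emits the four plain-text artifacts of a study: lexicon CSV,
#' transcript CSV (planted cluster ids included as a `coder_truth`
#' column), frequency CSV (`word, count`) and a ground-truth JSON of
#' planted segmentations.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lexicon = file.path(dir, "lexicon.csv"),
             transcripts = file.path(dir, "transcripts.csv"),
             freq = file.path(dir, "frequency.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_lexicon(study$lexicon, paths[["lexicon"]])
  rows <- lapply(study$transcripts, function(entry) {
    s <- entry$sequence
    data.frame(participant_id = s$participant_id, word = s$words,
               onset_s = s$onsets, flag = s$flags,
               coder_truth = entry$manual$truth,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), paths[["transcripts"]],
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(data.frame(word = names(study$freq),
                              count = unname(study$freq),
                              stringsAsFactors = FALSE),
                   paths[["freq"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  truth <- lapply(study$truths, function(seg)
    list(runs = unname(apply(seg$runs, 1L, as.list)),
         link_flags = seg$link_flags))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
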