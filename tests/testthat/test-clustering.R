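test_that("link_adjacent applies a strict shared-topic threshold", {
  th <- criterion(0.13)
  expect_true(link_adjacent(c(0.14, 0.86), c(0.14, 0.86), th))
  # boundary (equal to threshold) and disjoint topics never link
  expect_false(link_adjacent(c(0.13, 0.87), c(0.87, 0.13), th))
  # a word whose maximum probability is 0.136 can link with itself at
  # 0.13 — the criterion sits below every word's maximum on purpose
  v <- c(0.136, rep((1 - 0.136) / 9, 9))
  expect_true(link_adjacent(v, v, th))
  expect_error(link_adjacent(c(0.5, 0.5), c(1, 0, 0), th), "length")
  # inclusive mode available for sensitivity checks
  expect_true(link_adjacent(c(0.13, 0.87), c(0.13, 0.87),
                            criterion(0.13, strict = FALSE)))
})

test_that("detect_clusters chains linked pairs into maximal runs", {
  # two words sharing topic 1 above threshold, one orthogonal word
  lex <- topic_lexicon(rbind(a = c(0.9, 0.1, 0), b = c(0.5, 0.5, 0),
                             c = c(0, 0.05, 0.95)))
  s <- response_sequence(c("a", "b", "c"), 1:3)
  seg <- detect_clusters(s, lex, criterion(0.3))
  expect_equal(seg$link_flags, c(TRUE, FALSE))
  expect_equal(seg$run_id, c(1L, 1L, 2L))
  expect_equal(unname(seg$runs), cbind(c(0L, 2L), c(2L, 3L)),
               ignore_attr = TRUE)

  # Markovian chaining: a-b share topic 1, b-c share topic 2, a-c share
  # nothing, yet one cluster spans all three
  lex2 <- topic_lexicon(rbind(a = c(0.9, 0.1), b = c(0.5, 0.5),
                              c = c(0.1, 0.9)))
  s2 <- response_sequence(c("a", "b", "c"), 1:3)
  seg2 <- detect_clusters(s2, lex2, criterion(0.3))
  expect_equal(length(unique(seg2$run_id)), 1L)

  # pairwise-unlinkable vectors give all singletons
  lexs <- topic_lexicon(diag(5), words = letters[1:5])
  s3 <- response_sequence(c("a", "c", "e", "b", "d"), 1:5)
  seg3 <- detect_clusters(s3, lexs, criterion(0.5))
  expect_equal(seg3$run_id, 1:5)
  expect_false(any(seg3$link_flags))
})

test_that("unknown words carry the zero vector and never link", {
  lex <- topic_lexicon(rbind(a = c(0.9, 0.1), b = c(0.8, 0.2)))
  s <- response_sequence(c("a", "mystery", "b"), 1:3)
  seg <- detect_clusters(s, lex, criterion(0.13))
  expect_false(any(seg$link_flags))
  expect_identical(seg$unknown_words, "mystery")
})

test_that("detect_clusters matches the union-find oracle on random instances", {
  set.seed(101)
  for (rep in 1:300) {
    K <- sample(2:8, 1)
    lex <- simulate_lexicon(sample(5:30, 1), K = K,
                            concentration = stats::runif(1, 0.05, 2),
                            seed = sample.int(1e6, 1))
    n <- sample(2:25, 1)
    words <- sample(lex$words, n, replace = TRUE)
    th <- stats::runif(1, 0.05, 0.6)
    s <- response_sequence(words, sort(stats::runif(n, 0, 59)),
                           normalization = "none")
    seg <- detect_clusters(s, lex, criterion(th))
    orc <- oracle_segment(lookup_probs(words, lex), th)
    expect_identical(seg$run_id, orc$run_id)
    expect_identical(seg$link_flags, orc$link_flags)
    # structural invariants of the segmentation
    expect_equal(nrow(seg$runs), n - sum(seg$link_flags))
    expect_equal(sum(seg$runs[, "end"] - seg$runs[, "start"]), n)
  }
})

test_that("segmentations refine as the threshold rises", {
  set.seed(77)
  for (rep in 1:60) {
    lex <- simulate_lexicon(20, K = 6, concentration = 0.5,
                            seed = sample.int(1e6, 1))
    n <- 15
    s <- response_sequence(sample(lex$words, n, replace = TRUE),
                           sort(stats::runif(n, 0, 59)))
    th <- sort(stats::runif(2, 0.05, 0.5))
    seg_lo <- detect_clusters(s, lex, criterion(th[1]))
    seg_hi <- detect_clusters(s, lex, criterion(th[2]))
    # every pair linked at the higher threshold is linked at the lower
    expect_true(all(!seg_hi$link_flags | seg_lo$link_flags))
    expect_gte(mean_cluster_size(seg_lo), mean_cluster_size(seg_hi))
    expect_lte(cluster_counts(seg_lo)$n_runs,
               cluster_counts(seg_hi)$n_runs)
  }
})

test_that("segmentation is invariant to permuting topic columns", {
  set.seed(5)
  lex <- simulate_lexicon(30, K = 7, concentration = 0.3, seed = 8)
  s <- response_sequence(sample(lex$words, 12), 1:12)
  seg <- detect_clusters(s, lex, criterion(0.13))
  perm <- sample(lex$K)
  lexp <- topic_lexicon(lex$probs[, perm], words = lex$words)
  segp <- detect_clusters(s, lexp, criterion(0.13))
  expect_identical(seg$run_id, segp$run_id)
})

test_that("mean cluster size and counts follow the run structure", {
  seg <- segmentation_from_links(c(TRUE, TRUE, FALSE, TRUE), 5)
  expect_equal(mean_cluster_size(seg), 2.5)
  counts <- cluster_counts(seg)
  expect_equal(counts, list(n_runs = 2L, n_multi = 2L, n_switches = 1L))

  single <- segmentation_from_links(rep(TRUE, 4), 5)
  expect_equal(cluster_counts(single),
               list(n_runs = 1L, n_multi = 1L, n_switches = 0L))

  singletons <- segmentation_from_links(rep(FALSE, 3), 4)
  expect_equal(mean_cluster_size(singletons), 1)
  expect_equal(cluster_counts(singletons),
               list(n_runs = 4L, n_multi = 0L, n_switches = 3L))
  expect_true(is.na(mean_cluster_size(singletons,
                                      include_singletons = FALSE)))
  expect_equal(mean_cluster_size(seg, include_singletons = FALSE), 2.5)

  # algebraic identities on random segmentations
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    flags <- stats::runif(n - 1) < 0.5
    sg <- segmentation_from_links(flags, n)
    cc <- cluster_counts(sg)
    expect_equal(mean_cluster_size(sg), n / cc$n_runs)
    expect_equal(cc$n_switches, cc$n_runs - 1L)
  }
})

test_that("segmentation JSON uses 0-based half-open spans", {
  seg <- segmentation_from_links(c(TRUE, FALSE, TRUE), 4,
                                 threshold_used = 0.13,
                                 participant_id = "p9")
  path <- withr::local_tempfile(fileext = ".json")
  write_segmentation(seg, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$participant_id, "p9")
  expect_equal(j$runs$start, c(0L, 2L))
  expect_equal(j$runs$end, c(2L, 4L))
  expect_equal(j$link_flags, c(TRUE, FALSE, TRUE))
})
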