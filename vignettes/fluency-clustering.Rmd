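---
title: "Topic-model clustering of semantic verbal fluency tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model clustering of semantic verbal fluency tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semfluency)
```

## The scoring problem

In a semantic verbal fluency test a participant names as many members
of a category (typically *animals*) as possible within one minute.
Beyond the count of correct responses, the informative structure is
temporal-semantic: responses come in *clusters* of related words
(reflecting retrieval within a semantic subcategory) separated by
*switches* (reflecting executive search for a new subcategory).
Manual cluster coding is subjective — trained coders agree only
moderately with each other — which motivates an automatic rule whose
only inputs are the response words, their onset times, and a fixed
semantic representation.

## The representation: a topic-probability lexicon

The representation is a *topic lexicon*: for each category word $w$, a
vector of $K$ probabilities $P(k \mid w)$ that latent topic $k$
underlies the use of $w$, with $\sum_k P(k \mid w) = 1$. Topics play
the role of semantic subcategories, but softly: a word can be strongly
associated with several topics at once, which is exactly what lets the
clustering rule below capture gradual semantic drift.

Such a lexicon is built from a large corpus in three steps
(`run_build_lexicon_command()` composes them):

1. **Corpus filtering** (`filter_corpus()`). Target words are retained
   when their document count in the full corpus is *strictly greater*
   than `min_docs` (default 10); documents are retained when they
   contain at least one retained target. The strict inequality is a
   deliberate reading of "more than *n* documents"; the boundary case
   is tested.
2. **LDA estimation** (`fit_lda()`). A collapsed Gibbs sampler
   (implemented in C++ for throughput) integrates out the multinomial
   parameters and resamples token-topic assignments from
   $p(z_i = k) \propto (n_{dk} + \alpha)\,
   \frac{n_{kw} + \beta}{n_k + V\beta}$.
   Defaults: $K = 10$, $\alpha = 0.4$ (the settings of the published
   animal-category model this package accompanies), $\beta = 0.01$ (a
   common symmetric topic–word prior; the published analysis does not
   state one, so it is exposed and recorded in the fit), 2,000 sweeps
   with 500 burn-in and thinning 10, posterior means averaged over
   retained samples. Model selection over $K$ is *not* automated:
   interpretability of topics is a human judgment, and the per-sweep
   log-likelihood trace is returned to support it.
3. **Bayes inversion** (`topic_probabilities()`). LDA estimates
   $\phi_{kw} = P(w \mid k)$; the lexicon needs $P(k \mid w)$. With
   corpus-level topic proportions $\pi_k$ (estimated from the expected
   token-topic counts) as prior,
   $P(k \mid w) = \pi_k \phi_{kw} / \sum_j \pi_j \phi_{jw}$.
   The row-normalisation makes the result invariant to any common
   rescaling of $\phi$ and guarantees the sum-to-one lexicon
   invariant by construction. Whether the published pipeline used
   uniform or corpus-estimated topic proportions is unstated; this
   package estimates them from the fit and records the choice here.

The sampler is deterministic given `seed` (it draws exclusively from
R's RNG), so two runs with identical inputs are bitwise identical —
for a stochastic estimator, reproducibility and full recording of the
settings are the properties worth guaranteeing, not any particular
chain realisation. Exact numeric reproduction of an externally
published lexicon is therefore not attempted: iteration counts,
chains, and $\beta$ of that fit are unknown.

## The clustering rule

Given a criterion $\theta$, adjacent responses $w_i, w_{i+1}$ are
*linked* iff some topic $k$ has $P(k \mid w_i) > \theta$ **and**
$P(k \mid w_{i+1}) > \theta$; maximal chains of linked pairs are the
clusters (`detect_clusters()`). Two conventions deserve emphasis:

* **Strict inequality.** "Exceeds the criterion" is read as $>$. The
  published criterion $\theta = 0.13$ was chosen just below the
  lexicon-wide minimum of per-word maximum topic probability (0.136),
  so that *every* word can link on at least one topic — strictness
  preserves that intent while keeping the boundary case testable. An
  inclusive mode (`criterion(strict = FALSE)`) exists for sensitivity
  analyses.
* **Fixed vs derived threshold.** `criterion()` defaults to the fixed
  published 0.13 because that value was set by judgment, not by
  formula; `criterion(lex = ...)` instead derives
  $\min_w \max_k P(k \mid w)$ exactly from a lexicon
  (`derive_threshold()`). Both modes record their provenance.

Linking depends only on adjacency in response order — never on elapsed
time — and all responses participate, including repetitions and
intrusions, since errors can be semantically bound to their
neighbours. A response absent from the lexicon is assigned the zero
vector: it can never link, which is the only assumption-free choice
for an out-of-category word (the published analysis encountered one
such intrusion; how it was handled there is unstated, so this rule is
documented as the package's own). A user-supplied alias table can
instead map variant spellings onto lexicon entries before scoring.

Internally a segmentation is a per-response run-id vector plus the
$n-1$ adjacent-pair link flags; the serialized form
(`write_segmentation()`) uses 0-based, half-open `[start, end)` spans,
which make sizes and boundaries unambiguous across languages. The two
forms are bijective and both are round-trip tested.

Word matching everywhere is exact surface-form equality after Unicode
NFKC normalization and whitespace trimming — full-width/half-width
variants unify, but kana/kanji or synonym variation is deliberately
not resolved: silent fuzzy matching would corrupt the measures.

## The measure battery

For each participant and coding source (`compute_measures()`,
`score_cohort()`):

* **MCS** — mean cluster size. Singleton runs count as clusters of
  size 1 by default; this is the convention under which a manual
  coder's MCS can fall below 2, and the automatic MCS is computed
  identically for comparability. The runs-of-size-≥2 convention is an
  option.
* **WCI / OCI** — mean onset-to-onset interval between consecutive
  responses inside the same cluster vs across a switch. Each is a
  flat mean over that participant's intervals of the kind (whether
  the published analysis averaged per cluster first is unstated; the
  flat mean is documented as this package's convention). If a side is
  empty — e.g. the whole sequence forms one cluster, so there are no
  switches — the value is `NA`, and cohort summaries exclude it
  listwise with the count reported, never silently substituting 0.
* **Frequency effect** — the OLS slope of $\log$ word frequency on
  onset, default base 10. The magnitude depends on the log base and
  on which frequency norms the user supplies; both are recorded with
  the result rather than fixed by the package.
* **Error counts** — a response equal (after normalization) to an
  earlier one is a *repetition* (the later occurrence is flagged);
  a non-repetition absent from the category word list is an
  *intrusion*. Lexicon membership is a proxy for category membership;
  a dedicated category list can replace it.

Agreement between two clusterings of the same sequence
(`cohen_kappa()`) is computed on **adjacent-pair same-cluster
labels**: for each of the $n-1$ consecutive pairs, whether the pair
is within one cluster. This unit is a convention choice — it is the
only representation on which two segmentations of one sequence yield
a 2×2 contingency table, and it reconstructs each segmentation
losslessly. $\kappa = (p_o - p_e)/(1 - p_e)$ with marginal-frequency
chance agreement; when both coders are constant and identical,
$p_e = 1$ and $\kappa$ is reported as missing, not 0.

## What the synthetic generators emulate

`simulate_lexicon()` draws word vectors from a symmetric
Dirichlet(concentration): concentration 0.1 (default) gives the
peaked, subcategory-dominated vectors a category lexicon shows;
large values approach uniform.

`simulate_sequence()` plants ground truth: a hidden topic state that
persists with probability 0.7 per response (mean planted run ≈ 3.3
responses, matching mean cluster sizes around 3 reported for young
adults), words drawn from the lexicon entries whose *argmax* topic is
the current state (argmax assignment makes the planted structure
unambiguous while off-argmax mass still exercises Markovian chaining
at detection time), and onsets accumulating intervals from two
truncated-normal regimes — within-run 1.5 ± 0.5 s, switch 4.0 ± 1.0 s,
floored at 0.05 s — encoding the core behavioural assumption that
semantically closer retrievals are faster. Word frequencies decay
log-linearly at −0.006 log₁₀ units/s (residual sd 0.2 around a
10⁵-count baseline), the magnitude reported for healthy young adults.
Defaults of 20 responses per trial and 49 participants per cohort
match the study scale the package targets. `simulate_corpus()` is the
standard LDA generative process with the planted topic–word
distributions returned for recovery tests.

What the generators deliberately do **not** model: retrieval
exhaustion over the minute, perseveration dynamics, real lexical
statistics, or human coders' idiosyncrasies. Passing recovery tests
on these generators therefore shows the estimators are correct under
the model's own assumptions — not that the model is an adequate
account of any particular clinical population.

One consequence visible in the synthetic cohort summaries: the
frequency table is shared across participants (as real frequency
norms are), so a word generated late for one participant may have
been generated early — with a higher frequency — for another. The
cohort-level slope on the shared table is therefore attenuated
relative to the generating −0.006; the estimator's own calibration is
checked separately on per-sequence frequencies.

## Numerical choices and degenerate inputs

* Sum-to-one tolerance: `1e-6` for internally generated lexicons,
  default `1e-3` when reading files, since published tables are
  rounded; lexicon CSVs round-trip at 6 decimals.
* Zero-length documents are dropped from LDA with a notice; `K`
  larger than the vocabulary warns.
* Single-response sequences have no intervals; `wci_oci()` then
  returns `NA` on both sides. Fewer than two frequency-known
  responses, or zero onset variance, give an `NA` slope.
* Dirichlet draws at very small concentration can underflow to an
  all-zero gamma row; the generator then assigns the mass to one
  uniformly chosen topic, preserving validity.
* Undefined measures propagate as `NA` end to end and are excluded
  listwise, with counts, from cohort summaries.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script work at deliberately modest
scales chosen to make every stochastic check stable under its fixed
seed: 1,000 random instances for the union-find equivalence of the
cluster detector, 200 instances for threshold monotonicity, a
300-document × 100-token corpus (vocabulary 200, $K = 5$) for LDA
parameter recovery, 200 replicate sequences for the WCI < OCI
contract, and 500 replicates for frequency-slope calibration. These
sizes are the package's own choices and are recorded here so that
users scaling them up know what the shipped numbers mean.

## Known limitations

* Cluster quality is bounded by the lexicon: out-of-vocabulary
  responses never cluster, and the package does not attempt semantic
  inference beyond the supplied topic probabilities.
* The kappa unit (adjacent-pair labels) is one defensible convention;
  published kappa values computed under a different unit are not
  directly comparable.
* Tokenization, audio onset detection, and inferential statistics
  (ANOVAs, multiple comparisons) are upstream/downstream of this
  package and intentionally out of scope.
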