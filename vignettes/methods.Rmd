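---
title: "Text-driven GO annotation by retrieval and reranking: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Text-driven GO annotation by retrieval and reranking: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gorank)
```

## The annotation model

`gorank` treats automated function prediction as ranked document retrieval.
The target protein is the query, represented by its textual features
`x = (p, L)`: the UniProt-style description `p` (recommended name, species,
entry name) and the curated literature `L` (PubMed titles and abstracts).
GO terms are the documents, represented by their definitions. Two
assumptions drive the two stages:

1. *Proteins with similar descriptions have similar functions.* Stage 1
   therefore retrieves the `k` training proteins whose name + species text
   is most BM25-similar to the target's, pools their ancestor-propagated
   annotations into a candidate set, and scores each candidate by the
   weighted fraction of neighbours carrying it. This reduces the label
   space from tens of thousands of terms to a per-protein candidate list,
   making pairwise semantic scoring affordable.
2. *Evidence for a function is written down in sentences that resemble the
   term's definition.* Stage 2 selects the sentences most relevant to a
   branch-conditioned question, concatenates them with the protein name
   into a query, and rescores every (query, definition) pair.

Both stages are deterministic given their inputs, a property the test suite
relies on throughout.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` (per branch) | MFO 3, BPO 3, CCO 2 | retrieval depth; CCO has fewer distinct annotated terms, so a shallower pool is less noisy |
| `fraction` | 0.5 | share of pooled sentences kept as informative (`ceiling(fraction * n)`, never less than 1) |
| `cap` | 100 | per-protein cap applied to *externally* generated candidate lists before reranking; BM25 candidates are not capped |
| `k1`, `b` | 1.5, 0.75 | Okapi BM25 term-frequency saturation and length normalization |
| `tau_grid` | 0.01 … 1.00 by 0.01 | threshold sweep for weighted Fmax |
| `propagate` | off | ancestor max-propagation of final scores (on = CAFA-style ancestor-consistent output) |
| epsilon | 1e-7 | log-clipping in the training loss |

Tokenization for BM25 and all lexical scorers is lowercasing plus splitting
on non-alphanumeric characters — no stemming, no stop list — so every score
is exactly reproducible.

## Ontology handling

Ancestry uses `is_a` plus `part_of` edges (configurable), matching GO
annotation-propagation practice. Obsolete terms and cross-namespace edges
are dropped at parse time with logged counts; a cyclic graph is a hard
error. Information content is estimated from an ancestor-propagated corpus
as `IC(v) = -log2 Pr(v | Pa(v))`, with the conditional probability the
count of proteins carrying `v` over the count carrying *all* direct parents
of `v` (the literal conditional on the parent conjunction). Branch roots
have IC 0. The probability is clamped to `[1/(N+1), 1]` with `N` the corpus
size, so terms never observed in the corpus receive a large finite IC
rather than an infinite weight — an undefined ratio otherwise.

## Scorer backends and their design

The rerank stage is a contract: `pair_score(scorer, query, doc)` must
return values in `[0, 1]`, deterministically for fixed parameters;
trainable backends add `pair_fit()`. Two backends ship:

- **Lexical fallback** — the fraction of the definition's distinct tokens
  present in the query (*definition coverage*). The asymmetry is
  deliberate: the query pools many sentences and is long, while
  definitions are short, so coverage of the definition is the informative
  direction. A symmetric token-bag cosine was considered and rejected: with
  a long query the cosine compresses all pairs into a narrow band near
  zero, which ranks adequately but leaves the threshold sweep little room
  to separate calls from non-calls.
- **Bag-of-words logistic** — a compact trainable stand-in for transformer
  cross-encoders: hashed counts of tokens shared by query and definition
  (64 buckets) plus two overlap statistics and an intercept, through a
  logistic layer fitted by full-batch gradient descent on the summed
  binary cross-entropy. Training pairs use positives from the protein's
  true set intersected with its candidates and 1:1 uniformly sampled
  negatives from the remaining candidates; 10% of pairs are held out as a
  validation split. All sampling is seed-derived, so two runs with one
  seed produce bit-identical parameters.

Transformer backends (e.g. a biomedical BERT cross-encoder, or a seq2seq
sentence ranker scoring the "true" continuation of a
`Query: … Sentence: … Relevance:` prompt) satisfy the same contracts and
can be attached without touching the pipeline; nothing in the package
depends on which scorer produced the numbers.

## Numerical and degenerate-case choices

- Ranking ties are always broken deterministically: lexicographic accession
  at the k-th retrieval rank, term id among equal rerank scores, stable
  input order among equal sentence relevances.
- Neighbours with BM25 score 0 are kept in the ranked list (a pool smaller
  than `k` still yields that many neighbours), but a target whose
  neighbours *all* score 0 produces no candidates: the vote kernel refuses
  all-zero weights rather than inventing a uniform prior.
- Proteins without literature are still reranked with a name-only query —
  the template keeps an empty description clause rather than crashing.
- Externally supplied candidates beyond the cap keep their stage-1 order,
  rescaled strictly below the smallest reranked score, so the output
  remains a total order.
- Final scores are optionally made ancestor-consistent by max-propagation
  (a parent receives at least the maximum score of its predicted
  descendants). It is off by default to preserve scorer fidelity, and on
  for CAFA-style output; stage-1 vote scores are ancestor-consistent by
  construction, so propagation never changes them.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a three-branch DAG (40 terms per branch,
depth 4), 200 proteins, and at most 3 documents per protein, in seconds.
Functional structure is planted through per-branch *prototypes* — shared
term combinations that play the role of functional families, so proteins
drawing the same prototype have identical branch truth sets. Signal
strength is controlled by two probabilities: `rho`, that a protein's name
carries a term's name token (at `rho = 1`, proteins sharing a term share
name tokens, and BM25 retrieval is maximally informative), and `q`, that
the literature embeds a term's definition keywords in a sentence. Evidence
sentences carry branch-indicative phrasing ("has a molecular function …",
"acts in a biological process …", "localizes to a cellular component …"),
emulating how real evidence sentences signal the GO aspect and giving the
branch-conditioned query something to rank; noise sentences draw from a
vocabulary disjoint from every definition. Defaults (`rho = 0.8`,
`q = 0.8`, one noise sentence per document in expectation) were fixed once
as a moderately noisy regime.

What passing tests on these fixtures shows: the plumbing and the ranking
mathematics are correct, signal present in names and literature is
recovered, and reranking helps exactly when definitions share vocabulary
with the literature. What they cannot show: performance on real SwissProt
text, where sentence relevance is semantic rather than lexical, definitions
are long and stylized, and annotation noise is structured — claims at that
scale require trained transformer backends and real corpora.

## Problem sizes

The test suite runs fixtures of 40–100 proteins with 20–40 terms per
branch; the acceptance script uses the generator defaults (200 proteins,
3×40 terms, 75/25 train/test split) plus a full-signal bundle for candidate
recall. Everything completes in well under a minute on one CPU.

## Known limitations

- The lexical fallback cannot distinguish paraphrases from unrelated text;
  it is a floor, not a ceiling, for rerank quality.
- IC estimated from a small corpus saturates at the clamping floor for
  rare terms, compressing differences among very specific terms.
- The case-study confusion-count table bundled for the F1 arithmetic
  (`worked_example_o82234()`) has F1 values mutually consistent with a
  14-term ground truth; the table's own footnote mentions 16 terms, so the
  package's tests solve the ground-truth size from the counts instead of
  assuming either number.
- BM25 retrieval needs names with shared tokens; identifier-style names
  with no shared vocabulary degrade stage 1 to species-level matching.
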