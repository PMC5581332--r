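---
title: "Mining annotated transcriptional modules from literature tensors"
author: "tensorATM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining annotated transcriptional modules from literature tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorATM)
```

## The problem

Transcription factors (TFs) regulate sets of target genes, and much of
what is known about these regulatory relationships lives in unstructured
biomedical abstracts rather than in curated databases. `tensorATM`
mines such relationships directly from a citation corpus. Whenever a
gene and a TF are both annotated to the same citation (a gene2pubmed
style curation), the titles and abstracts of their shared citations form
a *pair document* describing their functional relationship. Counting
vocabulary terms over all pair documents yields a 3-mode **term x gene x
TF tensor**: cell (i, j, k) holds how often term i occurs in the
documents shared by gene j and TF k.

Factorizing this tensor with a *non-negative* CP (PARAFAC) model
expresses it as a sum of k rank-1 components
$\lambda_i\, (a_i \circ b_i \circ c_i)$. Because every factor entry is
non-negative, the high-magnitude entries of each component triplet can
be read directly as a functional unit: a set of genes, the TFs that
regulate them, and the terms that describe why they belong together. We
call the thresholded triplet an **annotated transcriptional module
(ATM)**.

## Building the corpus and tensor

1. **Citation filtering.** Citations referencing more than
   `maxGenesPerPmid` (default 10) entities are discarded: they are
   typically high-throughput screens with little per-gene information.
   The filter is idempotent.
2. **Pair documents.** One document per (non-TF gene, TF) pair sharing
   at least one citation, concatenated in ascending numeric PMID order
   so every downstream count is deterministic. TF–TF pairs are not
   formed: the gene mode contains only non-TF genes, keeping the two
   entity classes of the tensor disjoint. Genes that share no citation
   with any TF drop out of the universe.
3. **Tokenization.** Lower-case; every character that is not
   alphanumeric, hyphen, or underscore becomes whitespace; tokens
   shorter than three characters and stop-listed tokens are removed.
   Leading/trailing hyphens are stripped, internal hyphens kept
   (`bhlh-domain` stays one token). Purely numeric tokens of length >= 3
   are kept by default (`dropNumeric = TRUE` removes them). A compact
   English stop list ships with the package and can be replaced by any
   one-word-per-line file.
4. **Weighting.** Raw frequencies f are stored as log2(1 + f), damping
   very common terms in favour of specific ones. Counts of 0, 1, 3 map
   to 0, 1, 2.

The tensor is kept in coordinate (COO) form with sorted, duplicate-free
coordinates. `densityReport()` performs the exact bookkeeping
nnz / (m n p) in double precision (exact for any corpus up to ~4·10^15
cells).

## The solver

`ntf()` fits the non-negative CP model by alternating multiplicative
updates over the three mode unfoldings. Conventions and numerical
choices:

* **Unfoldings.** Mode 1 is m x (n p) with the gene index fastest and
  the TF index slowest; modes 2 and 3 use the term-fastest orderings
  consistent with the Khatri–Rao factors C (x) A and B (x) A. The
  matricize/fold pair is exercised as an exact round trip in the tests,
  and tensors built from known factors satisfy
  $X_{(1)} = A\,\mathrm{diag}(\lambda)\,(C \odot B)'$ to 1e-10.
* **Initialization.** Factors start from the absolute values of the k
  leading left singular vectors of each unfolding, computed from the
  eigenvectors of the small mode Gram matrix rather than the wide
  unfolding itself. This makes runs deterministic; a sign convention
  (largest-magnitude entry positive before taking absolute values)
  pins down near-ties. Entries below 1e-12 are raised to 1e-12 so
  multiplicative updates are not permanently zero-locked by round-off.
  When k exceeds the numerical rank of an unfolding — routine when k is
  larger than a mode extent — the remaining columns are seeded
  uniform(0, 1) draws; this is the only randomness in the solver and is
  governed by a single integer seed.
* **Updates.** Each factor is updated by the epsilon-stabilized
  multiplicative rule `F <- F * (X_(mode) Z) / (F Z'Z + eps)` with
  `eps = 1e-9` and Z the Khatri–Rao product of the other two factors.
  The numerator is evaluated by a sparse MTTKRP kernel (cost
  nnz(X) · k), and Z'Z via the Gram identity (U'U) * (V'V), so the
  Khatri–Rao product is never materialized against the tensor. A single
  multiplicative step makes very small progress, so each mode's
  non-negative least-squares sub-problem is advanced `innerIter = 3`
  steps per sweep before moving on; the fit remains monotone and the
  planted-model fixtures converge to fit >= 0.99 well inside 100
  sweeps.
* **Convergence.** fit = 1 − ||X − X̂||_F / ||X||_F is computed
  sparsely after every sweep (||X||² − 2⟨X, X̂⟩ + ||X̂||², the last term
  via factor Grams) and recorded in `fitHistory`. Iteration stops when
  the absolute change in fit drops below `tol` (default 1e-4) or after
  `maxIter = 100` sweeps — a hard cap guarding pathological inputs.
* **Normalization.** Columns are normalized to unit 2-norm once at
  convergence, not every sweep; the removed norms accumulate into
  lambda and components are sorted by lambda descending with ties kept
  in original component order. Normalizing at the end matches the view
  of lambda as a description of the output scale, and the tests verify
  the reconstruction is unchanged by the rescaling.

## From components to modules

For each component and mode, the scores are truncated to the top
`bounds` entities — defaults 300 terms, 184 genes, 21 TFs, reflecting
the largest curated pathway sizes and typical abstract lengths; all
three are configurable. On the truncated list the *normalized entropy*

$$E = -\sum_i p_i \log p_i \,/\, \log n, \qquad p_i = g_i / \textstyle\sum_j g_j$$

measures how concentrated the scores are (1 = uniform, 0 = point mass;
base-independent). The number of significant entities is
$s = \max(1, |\{p_i > E/n\}|)$: the uniform proportion 1/n scaled by the
list's information content. Under this reading a uniform list keeps
exactly one entity (the strict inequality fails), which is the
behaviour one wants from a filter whose purpose is isolating dominant
entries. The threshold is typeset ambiguously in parts of the
literature; the alternative reading 1/(n·E) is implemented behind
`rule = "inverse"` but `E/n` is the default. Ties at the truncation
boundary are broken lexicographically on the entity label, so
extraction is deterministic. An all-zero factor column yields a
single zero-score placeholder with the mode flagged `degenerate`.

## Evaluation statistics

* **Enrichment** — upper-tail hypergeometric probability of the overlap
  between the module's pooled genes+TFs and each category, over the
  tensor's gene+TF universe (pooling matches the precision statistic;
  a gene-only universe is a constructor option). Raw p <= 0.05 flags
  enrichment; no multiple-testing correction is applied by default so
  the statistic matches the exploratory use of the method, and
  `p.adjust` can be applied to the returned column when desired.
* **Term AUC** — Mann–Whitney AUC of the module's ranked terms against
  the tokenized names and descriptions of its enriched categories
  (tokenized with the same corpus tokenizer, so both sides share one
  vocabulary): 1 for a perfect ranking, 0.5 in expectation for a
  random one, 0 for the worst. Tied scores count 0.5 per pair
  (midranks). If every module term is in the gold vocabulary there are
  no negatives and the AUC is reported NA.
* **Precision** — |module ∩ gold| / |module| over pooled genes+TFs,
  with significance from a right-tailed Welch t-test against the
  precisions of 200 size-matched random gene–TF sets per module
  (sampling without replacement, seeded). The corpus-level control is
  1,000 random sets of 8 genes + 2 TFs, the median module size.
* **Redundancy and diversity** — pairwise Jaccard coefficients between
  module memberships, and per-run diversity: the unique entities in
  the union of a k-run's modules divided by the tensor totals, per
  entity type. Diversity is undefined for k < 2 (NA); it is computed
  per run because it is a function of k, with cross-run unions
  available by pooling the inputs.
* **Category prediction** — guilt-by-association (module members not
  yet annotated to an enriched category become candidates) and term
  mapping (categories ranked by the overlap between module terms and
  category description tokens, excluding categories already enriched
  for the module).

## The synthetic generator

`plantedModel()` + `synthTensor()`/`synthCorpus()` provide the study
conditions for every offline test: planted term–gene–TF blocks of
given intensity, optional multiplicative noise on planted entries
(uniform, amplitude `noiseRate`), background cells at rate
`noiseRate`, and — for the corpus generator — bag-of-words abstracts
drawn from per-block synthetic vocabularies (`termXXXX`, avoiding
stop-list collisions), shared citations for within-block gene–TF
pairs, contaminating words and cross-block citations at the noise
rate, and a gold-standard GMT whose categories are the planted blocks.
All randomness flows from one seed through per-component offsets, so
tensors and corpora can be regenerated independently and byte-identically.

What the generator does *not* emulate: natural language (word order,
syntax, entity mentions), realistic vocabulary size or Zipfian term
frequencies, citation-count skew across genes, or overlapping blocks.
Passing recovery tests therefore demonstrate the pipeline's
correctness — parsing, counting, factorization, thresholding, and the
statistics behave as specified on data with known structure — not that
real-corpus modules will be as clean; on real abstracts the blocks
overlap and the noise is far from uniform.

Problem sizes used by the test suite, chosen to exercise every code
path at desk scale: a 50 x 40 x 10 planted rank-3 tensor for solver
quality; a 60 x 20 x 4 two-block corpus (seed 7, noise 0.1) for
end-to-end recovery; a 200 x 100 x 20 four-block tensor for the
16-rank ladder (1, 2, 3, 5, 10, 15, 20, 25, 30, 50, 100, 200, 300,
500, 700, 900 — 2,861 components in total), with sweep counts capped
at the largest ranks where only the component count is under test.

## Known limitations

* The solver is plain multiplicative-update ALS; it inherits the slow
  tail convergence of that family and makes no attempt at line search,
  HALS, or exact non-negative least squares.
* The true tensor rank is not estimated — factorization is exploratory
  across a rank ladder, and components at k far above the modes' ranks
  lean on the seeded random initializer padding.
* Tokenization is deliberately simple (no stemming, no entity
  recognition, no sentence structure); gene symbols in free text are
  just tokens.
* Acquiring real citation corpora, pathway collections, or
  experimental gold standards is out of scope: the package consumes
  the documented file formats and ships a generator for synthetic
  inputs.
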