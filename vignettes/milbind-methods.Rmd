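---
title: "Predicting TF-DNA binding from DNA structure with multiple-instance learning"
author: "milbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF-DNA binding from DNA structure with multiple-instance learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milbind)
```

## The problem

Protein-binding microarrays (PBMs) measure, in vitro, the relative binding
affinity of a transcription factor (TF) to tens of thousands of designed DNA
probes, typically 35-mers. A TF binding site (TFBS) is a short subsequence,
around 6-12 bp, somewhere inside a bound probe — but *where* is unknown.
Conventional classifiers need one feature vector with one label per example,
which forces either a positional encoding (wrong, because binding is largely
position-independent) or a bag-of-words encoding (k-mer counts, which
discard the biophysics of the site).

`milbind` treats the problem as multiple-instance learning (MIL): each probe
is a **bag**, each of its `L - k + 1` overlapping k-mer windows is an
**instance**, and labels attach only to bags. A positive bag (high binding
signal) is assumed to contain at least one true binding-site instance; a
negative bag contains none. Each instance is described not by its letters
but by the 3-D structure of its DNA: every trinucleotide has six base-step
parameters (shear, buckle, stretch, propeller, stagger, opening) tabulated
from molecular-dynamics studies, and an instance's feature vector is the
concatenation of its `k - 2` triplet rows, length `(k - 2) * 6` (30 for the
default `k = 7`).

## The learning procedure

Training uses the *wrapper* MIL reduction:

1. **Flatten.** Every instance becomes a single-instance training row
   carrying its bag's label and weight `1 / (L - k + 1)`, so each probe
   contributes total weight 1 regardless of length (`flatten_bags()`). With
   no prior on the site's position, all windows are equally plausible.
2. **Fit.** A weighted-instance decision tree is fitted once on the
   flattened rows (`mil_train()`).
3. **Predict.** A new probe's bag probability is the unweighted arithmetic
   mean of its instances' positive-class probabilities (`predict_bag()`).
   The same per-instance probabilities, ranked, localize putative binding
   sites within positive probes (`instance_scores()`).

The averaging step encodes the assumption that instances contribute
additively to recruitment; it also means training weights play no role at
prediction time. Flattening gives background windows from positive bags a
wrong (positive) label — this is the price of the reduction. The tree copes
because background windows appear with both labels at similar rates, driving
their leaves toward indifferent probabilities, while true site windows occur
only in positive bags and get extreme probabilities.

Two baselines share the identical base classifier so that comparisons
isolate the representation, not the learner: positional structural
concatenation of the whole probe (`sil3d_features()`, `(L - 2) * 6 = 198`
features for 35-mers, single-instance), and k-mer occurrence counting
(`kmer_count_features()`, `4^k` features; plus the combined 3+4+5-mer
variant with `64 + 256 + 1024 = 1344` features).

## The base classifier

The base learner (`tree_config()`) is a CART decision tree (`rpart`) with
case weights and Laplace (add-one) smoothing of leaf class probabilities.
Historically this role was played by C4.5; we deliberately do not replicate
C4.5's gain-ratio splits or error-based pruning — the scientific comparison
is MIL-vs-SIL and structure-vs-counting, which the wrapper keeps classifier-
agnostic — but we keep its spirit in the defaults:

* `cp = 0`, `minsplit = 4`, `minbucket = 2`: grow a deep, lightly
  constrained tree. Pruned trees give marginally better bag ranking on easy
  data but collapse instance-level localization: site instances end up
  pooled with background in coarse leaves, and small spurious pure leaves
  outscore them. A deep tree isolates the recurring site cluster into its
  own large pure leaf, whose Laplace-smoothed probability
  `(n + 1) / (n + 2)` then dominates every small background leaf. Bag-level
  averaging over `L - k + 1` instances absorbs the extra variance that an
  unpruned tree brings.
* Laplace smoothing keeps probabilities off exactly 0/1, stabilizing both
  the averaging and AUC tie-handling.
* Instance weights are rescaled to mean 1 before fitting so the smoothing
  counts keep their natural scale; split selection is unaffected by this
  rescaling.
* `seed` is part of the configuration and is set before fitting; the whole
  pipeline is deterministic given data, configuration and seeds.

Training is single-pass. An iterative variant (`mil_train_iterative()`)
that re-fits with weights proportional to the previous round's instance
probabilities is included as an explicitly experimental mode, off by
default everywhere: the wrapper reduction itself is single-pass, and we did
not find the iteration necessary for any property this package tests.

## The structural table

The package ships a **synthetic placeholder** table
(`placeholder_structural_table()`): 64 rows of fixed-seed pseudo-random
values within ranges plausible for each base-step parameter. The real
MD-derived table is not redistributed; any user table in the documented TSV
dialect (`kmer shear buckle stretch propeller stagger opening`, 64 rows)
loads via `read_structural_table()` and is a mandatory, swappable input to
every structural feature model. All tests are value-agnostic: they verify
bookkeeping, invariances and learnability, never particular parameter
values. Lookups are case-insensitive and strand-naive — a triplet is not
averaged with its reverse complement, since the mapping convention for that
is not settled; `build_bag(add_revcomp = TRUE)` optionally instances the
reverse-complement windows instead (bag doubles, weights halve).

## The synthetic-data generator

`generate_pbm()` builds PBM-like datasets so the full pipeline is testable
with no downloads: i.i.d. background bases at a chosen GC fraction
(default 0.5, matching near-uniform array designs), 35-base probes, 3000
probes per class by default (the top/bottom-3000 labeling rule of
`label_by_signal()` applied to ~40,000-probe arrays), a consensus site
planted at a uniform offset into each positive with configurable insertion
probability and per-base mutation rate, and signals
`effect * present + N(0, sd)` so ranking by signal approximately recovers
the planted classes. One global seed drives a named substream per purpose
(background, offsets, variant choice, mutations, noise), so adding a
feature never perturbs existing draws, and generation is byte-reproducible.
Benchmarks in this package use 400 labeled probes per class drawn from
420 generated per class — large enough for stable AUCs and site
localization, small enough that the whole suite runs in minutes on one CPU;
these sizes are stated here as the package's chosen study scale.

What the generator does *not* emulate: the de Bruijn 10-mer coverage of
real array designs, replicate probe structure, spatial intensity artifacts,
or realistic intensity distributions (only the ranking enters the
pipeline). Passing tests therefore demonstrate correctness and the claimed
qualitative behaviors under controlled conditions, not performance on real
PBM arrays.

## The weak-consensus benchmark and why it needs a degenerate table

The scientific selling point of structure-based MIL is robustness when a TF
has **no strong sequence consensus** but its sites share structure. Two
subtleties surfaced while designing a synthetic regression test for this
claim, and they are worth recording:

* With a *generic* (injective) 64-row table, the trinucleotide-to-parameters
  map is a bijective re-encoding of sequence: structure carries exactly the
  same information as letters, and a counting model with a tree learner is
  extremely hard to beat. In particular, the pairwise structural twin of a
  motif (`structural_twin_motif()`, the different equal-length sequence with
  the nearest structural vector) is typically a single-base variant sharing
  most of its k-mers, and even a zero-distance complement twin merely gives
  the counting tree a two-word disjunction it learns in two splits.
* Real parameter tables are **degenerate**: conformationally similar
  triplets have near-identical rows even when their sequences are
  unrelated. That degeneracy — many sequences, one structure — is the
  mechanism behind the claim.

`degenerate_structural_table(n_classes = 3)` makes the degeneracy exact and
controllable: the 64 triplets share `n_classes` prototype rows. Under it,
`generate_structural_pbm(spec, table, radius = 0)` plants sites drawn from
the motif's full set of exact structural synonyms (about 110 distinct
7-mers at three classes): the planted population has a weak sequence
consensus but a single structural profile. On such data the structural MIL
model holds its accuracy while 5-mer counting, facing a hundred rare words,
degrades — the package's core scientific regression test
(`tests/testthat/test-acceptance.R`). The pairwise twin generator
(`generate_twin_pbm()`) is retained for its own contract and for building
two-variant datasets.

## Evaluation choices

* **AUC** (`auc_score()`) uses the Mann-Whitney midrank formulation, ties
  counting one half; tests verify it against an exhaustive pairwise oracle.
* **Top k-mer tables** (`top_kmers()`) count every qualifying instance
  (predicted probability at or above the threshold, default 0.85) in
  positive probes — no per-probe deduplication — and break count ties by
  lexicographic order. The threshold is inclusive (`>=`), configurable;
  descriptions of this statistic vary between strict and inclusive, and we
  chose inclusive.
* **Gain analyses** (`gain_analysis()`) correlate the per-TF AUC gain of
  one model over another with (a) the total occurrence of the top
  high-probability k-mers and (b) mean GC content of the positive test
  probes (`gc_content()` averaged over each TF's positive test probes — the
  aggregation is a package choice), and report a two-sided paired t-test on
  the per-TF AUCs. Pearson correlations and the t-test are delegated to
  `stats::cor.test()` / `stats::t.test()` and verified against direct
  formulas in tests.
* **Localization** is measured as argmax-*set* membership: a planted site
  is recovered when its window attains the bag's maximum instance
  probability. Because leaf probabilities are discrete, a site window and
  its one-base overlaps — which are themselves partial sites — frequently
  tie at exactly the same probability; a strict single-argmax rule would
  then be decided by index order rather than by the model. In diagnostics
  the planted window is essentially never *strictly* beaten by a
  non-overlapping background window.
* **Tie-breaking** is deterministic everywhere: probe labeling sorts by
  `(-signal, probe_id)`, instance rankings by `(probability, probe_id,
  offset)`, k-mer count ties lexicographically. Benchmarks are reproducible
  byte for byte given data, configuration and seeds.

## Degenerate inputs and numerical notes

Bags require `3 <= k <= L`; `k = L` yields a single full-weight instance.
Sequences containing non-ACGT characters are rejected at feature time and
filtered (with a warning) at probe-reading time. Single-class training
data, mismatched feature lengths, oversized label requests and malformed
structural tables all fail fast with specific messages. Bag weights sum to
1 within 1e-12; bag probabilities equal instance-loop means within 1e-12.
AUC is undefined (error) when a class is absent; correlations require
nonzero variance.

## Known limitations

* The shipped structural table is a placeholder; scientific conclusions
  require a real MD-derived table supplied by the user.
* Desk-scale synthetic benchmarks say nothing about per-TF accuracy on real
  PBM compendia such as the DREAM5 arrays; they test mechanism, not field
  performance.
* The base tree is CART, not C4.5; models trained elsewhere with J48 are
  not bit-comparable.
* Counting and bag decomposition are forward-strand by convention
  (`add_revcomp` exists for bags); no gapped or variable-length instances.

## A minimal session

```{r example, eval = FALSE}
table <- placeholder_structural_table()
spec <- synthetic_spec(motif = "TGACGTA", n_pos = 420, n_neg = 420,
                       signal_noise_sd = 0.2, seed = 1)
train <- generate_pbm(spec)
spec$seed <- 1001L
test <- generate_pbm(spec)

lab_tr <- label_by_signal(train$probes, 400, 400, tf_name = "demoTF")
lab_te <- label_by_signal(test$probes, 400, 400, tf_name = "demoTF")

report <- benchmark_tf(lab_tr, lab_te, table = table)
report$auc

model <- mil_train(build_bags(lab_tr, 7, table))
head(instance_scores(model, build_bags(lab_te, 7, table)[1:5]))
```
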