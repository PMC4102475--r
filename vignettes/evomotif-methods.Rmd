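---
title: "Methods: evolutionary motif-feature construction and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary motif-feature construction and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evomotif)
```

## Problem and model

`evomotif` classifies fixed-length DNA windows into two classes (site
vs. non-site) by first *constructing* interpretable boolean features and
then *selecting* a non-redundant subset of them. The working assumption is
the one underlying consensus-sequence biology: class membership is driven
by short, possibly degenerate sequence elements that occur at preferred
positions (splice donors), within loose regions (transcription-factor
boxes), or as ordered co-occurring pairs (bipartite signals) — and that a
classifier built from a handful of such elements is worth more to a
biologist than a marginally better black box.

### The feature language

A feature is a typed parse tree. Leaves are motif-matching predicates over
the 15-symbol IUPAC alphabet (each symbol denotes a base set; `R` = G/A,
`Y` = T/C, ..., `N` = any). Internal nodes combine sub-features:

| node | semantics on a window |
|---|---|
| `matches m` | motif `m` occurs anywhere |
| `matches-at m p` | an occurrence starts exactly at 0-based `p` |
| `matches-shift m p s` | an occurrence starts in `p ± s` |
| `matches-region m a l` | an occurrence starts in `[a, a+l)` |
| `and`/`or`/`not` | boolean combination |
| `corr f g s` | ordered co-occurrence of `f` then `g` |

All coordinates are 0-based and half-open internally; anchor-relative
positions (e.g. "−3 nt from the splice junction") exist only in reporting,
as `position − anchor_offset`.

Two semantic choices were genuinely open and are worth recording:

* **Correlational nodes.** When both children are motif-rooted, `corr`
  requires an occurrence of the left child's motif followed 5'→3' by one of
  the right child's, with an inter-motif gap between 0 and `shift` nt,
  where each occurrence must also satisfy its child's own positional
  constraint. This makes the operator directional — reading biological
  signals the way bipartite elements are written — and gives `shift` a
  concrete meaning (maximum gap). With non-motif children the node degrades
  to a conjunction, keeping the operator total over the type system.
  Unordered or center-to-center readings were considered and rejected as
  harder to interpret on output.
* **Shift windows are symmetric** around the expected position; nothing in
  the domain argues for sidedness, and a symmetric window keeps the
  parameter count at one.

Matching treats a degenerate *input* base (allowed only with
`allow_ambiguous = TRUE`) as matched by a motif symbol only when the
symbol's base set covers the input's set — an input `N` is matched by motif
`N` alone, never silently by a concrete base. Clean benchmark data is the
default assumption; silent coercion hides upstream errors.

### Stage 1: feature construction by GP

A population of feature trees evolves for `generations` generations. Each
tree is scored by the filter fitness

$$\mathrm{fitness}(f) = \max\!\left(0, \frac{P_f - N_f}{P}\right)$$

with $P_f$, $N_f$ the positive/negative training sequences containing $f$
and $P$ the positive count. The formula tracks occurrence in positives
(negatives need not share any signal), zeroes out features equally present
in both classes, and — because $N_f$ is not normalized by the negative
count — is deliberately precision-oriented on unbalanced data. No
classifier is trained during construction; filter scoring keeps each
generation linear in the dataset.

Mechanisms, and why they are there:

* **Implosion.** The population shrinks by `implosion_rate` per generation
  (never below `pop_size_floor`): early generations explore broadly, later
  ones concentrate evaluation budget on refinement.
* **Hall of fame.** The `hof_top_k` fittest individuals per generation
  enter a deduplicated, fitness-ranked archive (capacity `hof_capacity`),
  which re-seeds each new generation with `hof_seed_m` random members.
  The archive prevents the purely generational population from losing its
  best discoveries to drift, and it *is* the search space handed to
  stage 2.
* **Typed variation.** Mutation picks one node uniformly and applies one of
  four applicable variants with equal probability: motif edit
  (substitute/insert/delete one symbol within `motif_len_range`), integer
  jitter (±1..5, clamped into the window — clamping rather than discarding
  keeps the operators closed), operator swap (same arity), or subtree
  replacement. Crossover exchanges type-compatible material: boolean
  subtrees, whole motifs, or same-role integers.
* **Bloat control.** Hard caps (`depth_cap`, `size_cap`) enforced at birth
  (offspring re-drawn a bounded number of times, then the parent survives
  unchanged), plus parsimony tie-breaking — equal fitness is resolved
  toward the smaller tree in tournaments and in archive ranking. Both
  mechanisms are standard and, importantly, testable.
* **Parent selection** inside stage 1 is tournament selection (size
  `tournament_size`), the GP default; only stage 2 prescribes
  fitness-proportional selection.

Random motif generation draws concrete bases with probability 0.75 and
degenerate symbols with 0.25, so random features start informative;
evolution is free to degenerate individual positions afterwards. With
`alphabet_mode = "acgt"` degenerate symbols are excluded outright — useful
where ambiguity is known to add nothing, as in splice-site recognition.

### Stage 2: subset selection by GA

Bitstrings of length |hall of fame| evolve generationally: uniform
crossover (per-bit swap probability `p_swap`), bit-flip mutation (default
rate 1/L), fitness-proportional selection with a uniform fallback when all
merits are zero, no elitism in the population — the global best genome is
tracked externally and returned. The fitness is the correlation-based
(CFS) merit

$$\mathrm{merit}(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}$$

computed on the 0/1 occurrence matrix (the features are boolean by
construction, so occurrence — not counts — is the natural scale).
$\bar r_{cf}$ is the mean absolute feature–class Pearson correlation (the
phi coefficient), $\bar r_{ff}$ the mean *absolute* pairwise
feature–feature correlation — redundancy is symmetric, so sign is
discarded. Zero-variance columns contribute 0 by convention; the empty
subset has merit 0.

### Classification and evaluation

Bernoulli naive Bayes with add-one smoothing is the default: with boolean
features the class-conditional model is exactly a smoothed Bernoulli, and
smoothing keeps every conditional in (0,1). A Gaussian-KDE conditional
(Silverman rule-of-thumb bandwidth, with a fixed fallback bandwidth of 0.5
for zero-spread features) is provided for count-mode vectors. Scoring
accumulates log-likelihoods and normalizes per example, so posteriors sum
to 1.

auROC is computed by the rank (Mann–Whitney) identity, ties counting one
half. auPRC uses step-wise integration over distinct-score threshold
groups; linear interpolation in PR space is a known bias and is not
offered. Cross-validation is stratified — the benchmark tasks are heavily
unbalanced and unstratified folds can lose the positive class; within each
fold both evolutionary stages and the classifier see only the training
split. The paired t-test wrapper handles the zero-variance difference
explicitly (identical vectors: t = 0, p = 1; constant non-zero difference:
p = 0), a degenerate case the textbook formula leaves undefined.

Variable-length inputs are handled by keeping the modal length and
discarding both shorter *and* longer outliers — positional operators and
the feature matrix need rectangular data, and a symmetric rule is the
smallest one that guarantees it. Discard counts are logged and a warning
fires above 10%.

## The synthetic generator

`plant_spec()`/`generate_dataset()` emulate the benchmark structure the
framework targets: equal-length windows, i.i.d. background composition,
and class-conditional planted signals — an IUPAC motif written at
`locus + U(−jitter, +jitter)` with each degenerate symbol resolved
uniformly, or an ordered motif pair with a bounded gap. Plants overwrite
the window (never insert), keeping lengths fixed; collisions are resolved
left-to-right with later plants skipped and counted. A ground-truth record
of every realized insertion is returned.

What the generator deliberately does **not** emulate: positional
background biases, repeats and isochores, composition differences between
classes, or correlated background — in real regulatory data all of these
exist. Passing tests on planted data therefore demonstrate that the search
and selection machinery recovers signals that are *present by
construction*; they do not certify performance on any real genomic task.

One consequence worth spelling out: with plant probabilities $p$ in
positives and $q$ in negatives and identical backgrounds, the only class
signal is plant presence, so the Bayes-optimal auROC is
$p(1-q) + \tfrac12\big(pq + (1-p)(1-q)\big)$ — for $p = 0.9, q = 0.05$
that is 0.925, and no classifier can exceed it. Held-out results on such
benchmarks must be read against this ceiling, not against 1.0.

## Problem sizes and defaults

Function defaults (`efc_config()`: population 500, 30 generations, caps
8/40, motif lengths 2–8; `efs_config()`: population 200, 100 generations)
are sized for overnight-scale runs on real window sets. The test suite and
`scripts/acceptance.R` use a desk-scale configuration — population 300, 30
generations, floor 100, size cap 25, archive 100; GA population 100, 40
generations — on benchmarks of 500+500 training and 200+200 held-out
windows of 60 nt, which recovers a planted 6-mer reliably in ~20 s per run
on one CPU. The subset-GA optimality check uses 12 features so the
exhaustive optimum over all 4,096 subsets is computable exactly.

## Known limitations

* Deduplication is syntactic (by canonical serialization); semantically
  equivalent trees (`(and a b)` vs `(and b a)`) can coexist in the archive.
* The surrogate fitness counts raw negatives, so with very large negative
  classes most features floor at 0 and selection pressure comes mostly
  from positives; this is intentional (precision-orientation) but means
  the absolute fitness scale is not comparable across class ratios.
* Count-mode vectorization is defined only for motif-rooted features;
  boolean combinations have no occurrence count.
* Protein alphabets, mismatch-tolerant matching, and semantic boolean
  simplification are out of scope.
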