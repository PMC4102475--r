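# evomotif

Evolutionary construction and selection of interpretable motif features for
binary classification of DNA sequence windows — recognizing sequence
elements such as DNase-hypersensitive sites, splice junctions, or ALU
elements from fixed-length windows, while producing features a biologist
can read.

Most high-accuracy sequence classifiers (PSSM/HMM scoring, string-kernel
SVMs) bury their decision rule in thousands of weights. `evomotif` takes
the opposite route: it *constructs* a small set of boolean features of the
form

```
(and (matches-shift GT 31 2) (not (matches CCTGG)))
```

— IUPAC degenerate motifs combined by boolean (`and`, `or`, `not`),
positional (`matches-at`), shift (`matches-shift`, an occurrence within
*p* ± *s* nt), regional (`matches-region`, an occurrence starting in a
half-open interval) and correlational (`corr`, ordered co-occurrence of two
sub-features within a bounded gap) operators — and then *selects* a small
non-redundant subset of them to feed a naive Bayes classifier.

## The method

**Stage 1 — feature construction (GP).** A population of typed feature
trees evolves under a filter fitness that needs no classifier: with *P_f*
and *N_f* the numbers of positive and negative training sequences
containing feature *f*, and *P* the number of positives,

```
fitness(f) = max(0, (P_f − N_f) / P)
```

which tracks occurrence in positives and penalizes features equally common
in both classes. The population *implodes* (shrinks by a fixed fraction per
generation), each generation's best features enter a deduplicated **hall of
fame**, and the archive seeds part of each new generation. Bloat is
controlled by hard depth/size caps and parsimony tie-breaking.

**Stage 2 — feature selection (GA).** Fixed-length bitstrings over the hall
of fame evolve generationally (fitness-proportional selection, uniform
crossover, bit-flip mutation) to maximize the correlation-based subset
merit

```
merit(S) = k · r̄_cf / sqrt(k + k(k−1) · r̄_ff)
```

where *k* = |S|, *r̄_cf* is the mean feature–class correlation (phi) and
*r̄_ff* the mean absolute pairwise feature–feature correlation: high class
relevance, low redundancy.

**Classification & evaluation.** Bernoulli naive Bayes with Laplace
smoothing (a Gaussian-KDE variant for count features), auROC and
step-integrated auPRC, stratified k-fold cross-validation with strict
train/test isolation of both evolutionary stages, paired t-tests,
per-feature information gain, and a k-mer spectrum baseline featurizer.

A synthetic generator (`plant_spec()` / `generate_dataset()`) plants known
IUPAC motifs — positionally jittered, degenerate, or co-occurring pairs —
into background sequence at class-conditional rates, with a ground-truth
record, so every stage is testable without external data.

## Worked example

Recover a splice-donor-like signal (`GGTAAG` planted at position 30 ± 2 in
90% of positives, 5% of negatives):

```r
library(evomotif)

spec <- plant_spec(60, 200, 200,
                   plants = list(plant("GGTAAG", 30, jitter = 2,
                                       prob_in_positive = 0.9,
                                       prob_in_negative = 0.05)),
                   seed = 7)
sim <- generate_dataset(spec)
sim$dataset
#> <dna_dataset> 200 positive + 200 negative windows of 60 nt

cfg <- efc_config(pop_size_initial = 200, generations = 15,
                  pop_size_floor = 80, size_cap = 25, hof_top_k = 10,
                  hof_seed_m = 20, hof_capacity = 60, seed = 1)
hof <- efc_evolve(sim$dataset, cfg)
hof
#> <hall_of_fame> 60 features (capacity 60)
#>   0.625  (matches-shift GT 31 2)
#>   0.595  (or (and (matches-shift NDAGST 27 5) (matches VNWA)) ...)
#>   ...

sel <- efs_select(hof, sim$dataset,
                  efs_config(pop_size = 80, generations = 30, seed = 1))
length(sel$features)   #> 24
round(sel$merit, 3)    #> 0.667

model <- nb_train(vectorize(sim$dataset, sel$features))
scores <- nb_score(model, vectorize(sim$dataset, sel$features))
round(auroc(scores, sim$dataset$labels), 3)  #> 0.889
```

The top archived feature, `(matches-shift GT 31 2)` with fitness 0.625, is
the invariant `GT` core of the planted donor-like motif at its planted
offset — the kind of directly interpretable output the framework is built
for. Held-out evaluation uses `cross_validate()`, or train/test splits as
in `scripts/acceptance.R`.

A command-line wrapper with `simulate`, `evolve`, `select`, `evaluate` and
`run` subcommands is installed at `inst/cli/evomotif.R`
(`system.file("cli", "evomotif.R", package = "evomotif")`).

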