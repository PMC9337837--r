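---
title: "Classifying interneuron progenitors from single-cell expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying interneuron progenitors from single-cell expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cortical interneurons originate in three embryonic subpallial regions —
the caudal ganglionic eminence (CGE) and the dorsal and ventral parts of
the medial ganglionic eminence (dMGE, vMGE). If cells dissected from
these regions can be told apart from their transcriptomes alone, the
regional identity is already encoded before migration. `cinrules`
implements the machine-learning side of that question as a reusable,
tested pipeline: given a cells × genes matrix of nonnegative RPKM-like
values and a three-class label per cell, it ranks genes, scans nested
feature subsets with two classifier families, scores everything with the
multiclass Matthews correlation coefficient (MCC), and distills the
signal into an ordered list of human-readable threshold rules.

The public dataset this workflow is modeled on has 2,669 cells
(856 CGE / 957 dMGE / 856 vMGE) and 37,310 transcripts, 6,037 of which
are zero in every cell; `cin_dataset_manifest()` records those
structural facts, and the synthetic generator below emulates them at a
desk scale so that every stage is testable without downloads.

## Pipeline at a glance

```{r}
library(cinrules)

ds  <- generate_dataset(generator_config())        # 300 cells x 2000 genes
fz  <- remove_all_zero_features(ds$matrix)
disc <- discretize_three_state(fz$filtered, alpha = 1)
ranked <- mrmr_rank(disc, ds$labels, k = 100)

rf  <- make_learner("tree_ensemble", n_trees = 100, seed = 1)
ifs <- run_ifs(ranked, fz$filtered, ds$labels, rf,
               grid = build_subset_grid(100, step = 10),
               folds = 10, seed = 1)
select_optimal(ifs)
select_compact(ifs, delta = 0.015)

rules <- fit_ripper(ds$matrix, ds$labels, seed = 1)
```

## Feature representation and discretization

Transcripts that are zero in every cell carry no information and are
dropped first (`remove_all_zero_features()`), mirroring the
37,310 − 6,037 = 31,273 arithmetic of the reference dataset.

Mutual-information estimation needs discrete states.
`discretize_three_state()` maps each gene to {−1, 0, +1} by comparing
each value against the gene's mean ± `alpha`·SD. Two conventions are
fixed deliberately:

* **Population SD** (divide by *n*), matching the classical mRMR
  program's discretization; the choice only shifts thresholds by a
  factor `sqrt(n/(n-1))` but is documented so results are reproducible.
* **`alpha = 1`** by default — the mean ± 1 SD three-state scheme is the
  reference convention. A gene with zero variance maps entirely to
  state 0 and therefore has zero relevance.

No transformation is applied to the RPKM values before discretization by
default; raw values are the literal reading of the source protocol. A
`log1p` flag is exposed as a sensitivity option because zero-inflated
expression is strongly right-skewed and the mean ± SD cuts land very
differently on the log scale.

## mRMR ranking

`mrmr_rank()` is the greedy minimum-redundancy maximum-relevance
recurrence: the first gene maximizes plug-in mutual information (bits)
with the labels; each later pick maximizes relevance minus (MID,
default) or divided by (MIQ) the mean MI with the already-selected set.
Numeric choices:

* plug-in (maximum-likelihood) MI without bias correction, as in the
  reference mRMR implementation;
* MI terms are accumulated in ascending sorted order, so the estimate is
  an order-invariant function of the contingency table — ties between
  permuted tables are then *exact* ties;
* every argmax breaks ties toward the lowest original gene index, making
  rankings deterministic and prefix-stable in `k`;
* the MIQ denominator is floored at 0.001 bits to avoid division
  blow-up.

The test suite checks the implementation against an independently coded
brute-force oracle on hundreds of small random datasets, for both
schemes, demanding exact agreement.

## IFS, selection, and the MCC

`build_subset_grid()` produces sizes 10, 20, 30, … (the grid's 24th
point is 240), and `run_ifs()` cross-validates a learner on each ranked
prefix. Folds are stratified by class — with class compositions like
856/957/856 this keeps every training fold balanced — and assembled by
seeded within-class shuffling plus round-robin dealing. Per-size CV
seeds are derived from the base seed and the subset size, never from
execution order, so evaluations could run in any order (or
concurrently) with identical results.

The score is the covariance-form multiclass MCC: one-hot matrices *X*
(truth) and *Y* (prediction), `cov(X,Y)/sqrt(cov(X,X) cov(Y,Y))` with
`cov` summed over per-column sample covariances. The 1/(n−1)
normalization cancels in the ratio; the statistic equals the classical
multiclass R_K computed from the confusion matrix, an equivalence the
tests assert numerically to 1e−12 rather than assume. A constant
predictor has zero variance; the value is then *defined* as 0 (not NaN)
so weak subsets still produce a well-defined IFS curve.

`select_optimal()` takes the grid point with maximal MCC (ties → the
smaller size). `select_compact()` formalizes the usual visual "knee"
reading of an IFS curve as the smallest size within `delta` of the
maximum. The default `delta = 0.015` reproduces the published
compaction of the reference analysis, where a 240-feature optimum
(MCC 0.725) was traded for a 120-feature classifier (MCC 0.711,
difference 0.014) — the packaged check replays exactly that curve shape
and recovers 120.

## Rule induction

`fit_ripper()` is a RIPPER-style sequential-covering inducer for
continuous features. Classes are handled in increasing frequency order
(ties by first appearance); for each non-final class the remaining pool
is split 2/3 : 1/3 into growing and pruning sets, a rule is grown by
greedily adding the single condition with maximal FOIL gain (threshold
candidates are midpoints between consecutive distinct observed values),
pruned by deleting trailing conditions to maximize (p − n)/(p + n) on
the pruning set, and accepted unless its pruning-set error exceeds 50%,
which closes the class. Covered samples are removed and the loop repeats
until no positives remain; the most frequent class becomes the default
of the resulting first-match decision list.

Deliberate simplifications, stated prominently: canonical RIPPER's
MDL-based stopping and its k = 2 post-optimization passes are **not**
implemented — the source protocol specifies only the grow/prune loop, so
the simplified stop rule above is the documented default, and exact
replication of any particular third-party tool's rule count is not a
goal. Tie-breaks are fixed (lowest feature index, then `<=` before
`>=`, then smallest threshold; pruning prefers the shorter rule), making
fits deterministic given the seed.

The same rule engine executes learned lists and the shipped reference
list (`cin_reference_ruleset()`): 22 threshold rules (12 CGE, 10 vMGE)
over a dMGE default. Gene matching is case-insensitive because the
source material mixes capitalizations ("Lhx8"/"LHX8"); in lenient mode a
condition on a gene absent from the sample simply fails, which lets the
fixture score partial expression vectors, while strict mode raises an
error naming the gene and rule. One quirk worth knowing: the 20th
reference rule is a pure conjunction of upper bounds, so an all-zero
expression vector matches it and is labeled vMGE — the default class is
*not* reached by the zero vector.

## The synthetic generator

`generate_dataset()` draws each entry as `exp(N(mu, sd))` with
multiplicative dropout: `mu` is `baseline_log_mean` everywhere except
that each class's marker block gains `effect_size` in its own class.
The log-normal/dropout pair matches the two salient features of the
real data — nonnegative heavy-tailed values and heavy zero-inflation —
and has closed-form moments, which keeps the tests' expectations
checkable. Markers occupy the first `3 * markers_per_class` columns in
class blocks, so ground truth is positional and deterministic.

Defaults are the package's study conditions: 100 cells per class, 2,000
genes, 20 markers per class, effect size 2.0 on the log scale, noise SD
0.5, dropout 0.3, seed 7. `baseline_log_mean = 1` puts background
expression near e ≈ 2.7 and markers near e³ ≈ 20 RPKM, a realistic
separation for strong regional markers. What the generator does *not*
emulate: UMI counting, library-size effects, batch structure, gene–gene
correlation beyond the planted blocks, or multiple developmental time
points. Passing tests therefore demonstrate algorithmic correctness and
recoverability of planted signal — not performance claims about any
real tissue.

## What the checks do and do not show

The recovery checks plant strong, threshold-separable markers; the
ranking recovers essentially all of them into the top of the list and
the tree ensemble reaches near-perfect cross-validated MCC with well
under 100 features, while the rule inducer reconstructs marker-based
rules with high training accuracy. These confirm the machinery, not the
difficulty of real data, where the reference analysis plateaus around
MCC 0.71–0.73.

One negative control deserves emphasis. With `effect_size = 0` the
generator's labels are pure noise, yet the best cross-validated MCC
over the IFS grid stays well above zero (≈ 0.3 under the default
conditions). This is not a defect of the classifier but the classic
selection bias of ranking features on the *full* dataset before
cross-validating prefixes: choosing the best of 2,000 noise genes at
n = 300 leaks label information into every fold. The pipeline keeps the
full-data ranking because that is the protocol it reproduces; the
lesson for users is that IFS curves built this way are honest for
*comparing* subset sizes but optimistic in absolute terms, and an
external validation set (or fold-internal re-ranking) is needed for
unbiased error estimates.

## Problem sizes and reproducibility

The packaged checks run the full stack at 300 cells × 2,000 genes
(ranking to depth 100, IFS to 100 features, 10×10-fold repeated CV) and
the rule inducer at 450 cells × 60 genes — sizes chosen so the whole
suite completes in a few minutes on a single CPU while still exercising
every code path at realistic shapes. Every stochastic step (generation,
fold assignment, ensemble fitting, grow/prune splits) is governed by
explicit seeds; ensemble vote ties are broken with the learner's own
seed rather than the session RNG, so identical inputs give identical
outputs in any calling context. `scripts/acceptance.R` re-runs the main
computations from scratch and writes the resulting quantities as JSON.

## Limitations

* The mutual-information estimator is the plug-in estimate on three
  states; continuous (kernel/k-NN) estimators are out of scope.
* The rule inducer omits MDL stopping and optimization passes (above),
  so it typically emits more, shorter rules than heavily optimized
  implementations on hard data.
* No normalization, batch correction, or highly-variable-gene selection
  is provided; inputs are taken as published.
* Full-data ranking induces the selection bias discussed above.
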