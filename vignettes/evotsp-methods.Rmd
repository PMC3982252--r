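---
title: "Evolving weighted top-scoring gene-pair classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving weighted top-scoring gene-pair classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotsp)
```

## The classification model

Relative expression analysis classifies a sample from the *ordering* of a
few genes' expression values within that sample, never from the values
themselves. Because any monotone per-sample normalisation preserves
orderings, every decision made by this package is invariant to such
transforms — a property the test suite asserts end to end.

For a P × M expression matrix with two classes C1 and C2, a gene pair
(i, j) is scored by the difference between the class-conditional
probabilities of the event $x_i < x_j$:

$$\Delta_{ij} = \left| p_{ij}(C_1) - p_{ij}(C_2) \right|,
\qquad p_{ij}(C) = \frac{1}{|C|} \sum_{m \in C} I(x_{im} < x_{jm}),$$

where the indicator is 1 only for a strict inequality: equality counts as
"not below". The classical family built on this score is implemented as
baselines:

* **TSP** (`fit_tsp`): the single arg-max pair; the relation $x_i < x_j$
  votes for whichever class makes it more probable.
* **k-TSP** (`fit_ktsp`): up to `k_max` gene-disjoint pairs chosen greedily
  best-first, combined by unweighted majority vote; k is selected by
  internal stratified cross-validation over the odd grid 1, 3, …, ≤ `k_max`
  (odd to avoid vote ties), with accuracy ties resolved towards smaller k.
* **TST** (`fit_tst`): for gene triplets, the six within-sample orderings of
  the three values form one distribution per class; the triplet score is
  the total-variation distance between them. This form was chosen because
  it reduces exactly to $\Delta$ when only two genes (two orderings) are
  involved, keeping the pair and triplet scores on one scale. The O(P³)
  scan is intended for small gene panels (a few dozen genes).

Δ ties are broken by a secondary score: convert each sample to within-sample
ranks (average ranks on ties) and take the absolute difference between the
two class means of $R_i - R_j$. We use the unnormalised form (no division by
P); since the score only ever compares pairs within one matrix, a constant
factor cannot change any decision. Remaining double ties fall to
lexicographic gene-id order, so every fit is deterministic.

## The evolved model

`fit_evotsp` searches a strictly larger model space: an *individual* is an
ordered list of k weighted, signed pair rules. Each rule holds two genes, a
sign saying whether $x_i < x_j$ or $x_i > x_j$ votes for C1, and a positive
weight r. A sample is classified by summing the weights of satisfied rules
for C1 against the weights of unsatisfied rules for C2; the heavier side
wins. Gene-disjointness is *not* required, so two rules sharing a gene can
express triplet-like relations, and weights let single strong rules dominate
several weak ones — the two restrictions (disjoint pairs, unweighted votes)
that the classical family imposes for computational reasons.

Decision ties at exactly equal weighted sums go to the majority training
class, then to C1. Weights start at 1 and are only ever multiplied or
divided by 2, so they remain exact powers of two and tie detection is exact
in floating point.

### Fitness

$$\mathrm{fitness} = Q_{\mathrm{reclass}} - \alpha\,(2k + u)$$

with $Q_{\mathrm{reclass}}$ the training-set accuracy, k the number of
rules, u the number of unique genes, and α (default 0.005) the
cost-complexity weight. Unique genes are counted on top of the per-rule
term, so an ensemble that reuses genes is cheaper than a gene-disjoint one
of equal size — a deliberate nudge towards compact multi-gene relations.
With α = 0 the fitness is plain training accuracy. There is no universally
good α; tuning it per dataset can help.

### Initialisation: mixed dipoles

Random pair rules are very likely to vote one class on almost every sample.
Each initial rule is therefore seeded from a *mixed dipole*: one sample
from each class is drawn, then two distinct genes are redrawn (up to
`dipole_retry_limit` times) until their ordering differs between the two
samples; the relation observed in the C1 sample, which we require to be
strict, fixes the rule's sign. A rule built this way is guaranteed to
classify the two dipole samples differently. Requiring strictness on the
C1 side is our choice for tie handling: a strict-relation sign cannot
separate a dipole whose C1 sample holds the two genes at exactly equal
values, so such gene draws are rejected and redrawn. On continuous data
ties have probability zero and the condition is exactly "ordering differs
between the two samples". Each initial individual receives
k ~ uniform{1..`init_k_max`} (default 1..5) dipole rules, all with weight 1.
The 1..5 bound applies at initialisation only; mutation may grow ensembles
beyond it, with the fitness penalty as the only size control.

### Variation operators

Crossover (per-individual probability 0.5; affected individuals are paired
uniformly at random, an odd leftover skips the generation):

* with probability 0.9, one uniformly chosen rule of each parent is
  swapped (both offspring keep their sizes and the rule multiset is
  conserved);
* with probability 0.1, a uniformly chosen rule of the *best individual
  found so far* overwrites a uniformly chosen rule of the first parent —
  only that parent changes.

The two printed probabilities sum to one, so they are read as variant
selection probabilities.

Mutation (independent probability 0.5 per individual, one of six variants
uniformly): add a dipole rule; remove a random rule (redrawn as another
variant when k = 1, so individuals never empty); replace a random rule by a
fresh dipole rule; exchange one gene of a random rule for a uniform random
gene different from its partner; multiply or divide a random rule's weight
by 2; flip a random rule's sign. Crossover and mutation coins are
independent, so both can hit one individual in one generation.

### Selection and termination

Linear-ranking selection: individuals sorted worst (t = 1) to best (t = n)
are drawn with probability $t / \binom{n+1}{2}$, filling n − 1 slots with
replacement; the best individual of the generation is copied unchanged into
the remaining slot and is exempt from the operators in that generation
(elitism). Fitness ties rank by fewer rules, then by a lexicographic key
over the rule list, making ranking deterministic. Each generation runs
evaluate → select → crossover → mutate; this order is conventional and
fixed here. Evolution stops when the best-ever fitness has not improved for
`stall_generations` (default 1000) generations, or at `max_generations`
(default 10000). The best-ever individual — not merely the last elite — is
returned, so the reported best-fitness history is non-decreasing by
construction.

Population size defaults to 100. All randomness flows from `evo_config`'s
single seed; identical seeds give bit-identical models, histories and
serialized JSON.

## The synthetic generator

`simulate_rxa_data` emulates the shape of two-class microarray studies:
continuous positive expression (i.i.d. log-normal background, default
meanlog 5, sdlog 1 — intensity-scale values around e⁵ ≈ 150), M ≈ 100–200
samples split 50/50 by default, and a handful of informative gene pairs
among hundreds to tens of thousands of uninformative ones. A planted pair
is imposed per sample by *swapping* the two background draws into the
class-specific order ($x_i < x_j$ in C1, the reverse in C2), flipped with
probability ε; a planted triplet analogously carries one full ordering per
class, replaced by a uniformly random ordering with probability ε. Because
planting only permutes values within a sample, every gene's marginal
distribution is exactly that of the background — planted genes are
invisible to univariate differential-expression statistics, which is
precisely the regime that motivates rank-pair methods. The population pair
score of a planted pair has the closed form $1 - 2\varepsilon$
(`expected_pair_delta`), which the tests use as a consistency oracle.

What the generator does **not** emulate: correlated gene–gene background,
batch effects, probe-level noise, heavy-tailed outliers, class imbalance
beyond a single fraction parameter, or missing values. Passing tests on
this generator therefore demonstrate correctness of the algorithms and
recoverability of rank-inversion signal under i.i.d. noise — not
performance on any real cohort.

## Numerical and design details

* Pair probabilities are accumulated as integer counts; Δ equality for
  tie-breaking is decided on the exact integer key
  $|n_1 M_2 - n_2 M_1|$, never on floats.
* Equality of two expression values never satisfies a strict relation — in
  scoring, voting and dipole construction alike. No jitter is ever added.
* The k-TSP internal CV takes a seed (default 0) so that fits are
  reproducible; its fold count defaults to 5.
* Degenerate inputs fail loudly: matrices below 2×2, non-finite cells,
  duplicate identifiers, more or fewer than two classes, a class smaller
  than the fold count, and dipole exhaustion (e.g. a matrix constant
  within every sample) are all errors, not warnings.
* The cross-validation harness aggregates accuracy per repeat (pooling
  folds), reports mean ± SD across repeats in percent, and measures model
  size as the number of *unique genes* — the interpretability currency of
  this model family.

## Problem sizes in the shipped tests

The test suite validates the scoring kernels against brute-force double
loops on matrices up to P = 15, M = 30, where exhaustive enumeration is
exact and fast; evolution behaviour (elitism, stalling, recovery of a
planted pair at ε = 0.05) is checked at P = 100–200, M = 60–100 with the
stall limit scaled to 200 and the generation cap to 2000. These sizes were
chosen so that a planted signal is neither trivial (the noise ceiling of
the best of ~20 000 background pairs at M = 100 sits well below the planted
Δ ≈ 0.9) nor out of reach for a few hundred generations of a population of
100.

## Known limitations

* Binary classification only; multiclass and cost-sensitive fitness are
  out of scope.
* The TST scan is exhaustive and cubic in P; it is a small-panel tool and
  deliberately not used by the evolutionary search.
* The evolutionary search is stochastic: different seeds may return
  different, equally fit models; only the seed makes a run reproducible.
* No feature pre-selection is performed by design — the search space is the
  full gene set — so very large P increases the generations needed to
  visit a specific informative pair.
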