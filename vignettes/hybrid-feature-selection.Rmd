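---
title: "Hybrid COVIDOA-SA wrapper feature selection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid COVIDOA-SA wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covidsa)
```

## The problem

Engineered feature tables for smartphone-sensor human activity recognition
(HAR) are wide: the standard six-activity benchmark describes every 2.56 s
sensor window with 561 derived features, many of which are redundant or
uninformative. Wrapper feature selection searches the space of feature
subsets directly, scoring each candidate subset by the error of a classifier
trained on it. With $D$ features there are $2^D - 1$ non-empty subsets, so
the search needs a metaheuristic.

`covidsa` implements one such metaheuristic hybrid: a population stage
modelled on coronavirus replication (COVIDOA), followed by a
simulated-annealing (SA) refinement stage that starts from the population
optimum instead of a random solution. The intuition behind the hybrid is
complementary search behaviour: the population stage explores broadly but
its replication operator is disruptive, while SA performs an intensive local
walk that can still escape local optima through Metropolis acceptance.

## The objective

A candidate subset is a bit mask $V \in \{0,1\}^D$. Its cost is

$$\mathrm{fitness}(V) = a\,\varepsilon(V) + (1-a)\,\frac{|V|}{D},$$

where $\varepsilon(V)$ is the misclassification rate of a classifier trained
on the selected columns, $|V|$ the number of selected features, and
$a \in [0,1]$ trades error against subset size. The classifier behind
$\varepsilon$ is a native $k$-nearest-neighbour classifier ($k = 5$,
Euclidean distance) with fully deterministic tie handling: neighbour-distance
ties resolve by training-row order, vote ties by smallest mean neighbour
distance, then by smallest label index. Determinism here is not cosmetic —
the optimizer ranks millions of candidate masks, and a classifier that broke
ties randomly would make fitness values irreproducible.

The weight defaults to a fixed $a = 0.99$, the conventional wrapper weight.
A strictly faithful variant in which $a$ is redrawn uniformly per evaluation
is available (`fitness_spec(a_mode = "random")`), but it makes the objective
non-stationary — the same mask scores differently on every call — so
candidate ranking degenerates; we default to the stationary form and regard
the random-$a$ reading as a quirk of the original description.

### Error-estimation protocols

`fitness_spec(protocol = ...)` controls which partition estimates
$\varepsilon$:

* `"holdout-test"` (default): train on the training partition, err on the
  test partition. This mirrors the original description, which feeds the
  published train/test split straight into the optimizer — note that this
  lets the search adapt to the test set (selection leakage).
* `"validation-split"`: a stratified 80/20 carve-out of the training
  partition; the test partition stays untouched until final evaluation.
* `"k-fold"`: stratified 5-fold cross-validation within the training
  partition. The error is averaged over every training sample, which makes
  it markedly harder for the search to overfit the estimate; this is the
  protocol we use for ground-truth recovery experiments (see below).

The validation carve-out and fold assignment are deterministic functions of
the dataset, so fitness values are stable across calls and cacheable. The
cache memoizes $\varepsilon$ by mask bits; the fitness value is recomputed
from the cached error on every call, so caching never changes a result, only
the number of classifier fits.

## The population stage (COVIDOA)

Solutions are bit masks throughout. The initial population is seeded by
drawing real vectors uniformly in $[lb, ub]$ (defaults $[-1, 1]$) and
binarizing them through the logistic transfer function
$S(x) = 1/(1+e^{-x})$. Two notes on this step:

* The source description's transfer function has a sign typo in the
  denominator (it would be undefined at 0 and unbounded); we implement the
  standard logistic, which is what "S-shaped transfer function" denotes in
  the binary-metaheuristic literature.
* The printed binarization rule sets a bit when a uniform draw is **at
  least** $S(x)$, i.e. $P(\mathrm{bit}=1) = 1 - S(x)$ — the inverse of the
  conventional rule. We implement the printed rule as the default and expose
  the conventional direction as `binarize(..., direction = "conventional")`.
  For symmetric seeding bounds the two directions are statistically
  indistinguishable at initialization, which is the only place the transfer
  function is used: after initialization the algorithm operates purely in
  bit space, and the random elements of replication and mutation are random
  bits.

Each generation then builds `n_pop` offspring:

1. **Selection.** A parent is drawn by roulette wheel. Because the objective
   is minimized, weights are $w_i = (f_{\max} - f_i) + \delta$ with
   $\delta = 10^{-9}$; the offset keeps a uniform wheel when all fitness
   values coincide.
2. **Frameshift replication.** Each of `nop` protein copies is the parent
   shifted one position right with a fresh random bit in front — the
   binary analogue of ribosomal frameshifting.
3. **Crossover.** The copies are folded left-to-right by uniform crossover
   into one new virion.
4. **Mutation.** Every position is replaced by a fresh random bit with
   probability `mr` (so the probability an individual position actually
   changes is `mr/2`).
5. **Repair.** A mask that ends up empty gets one uniformly chosen bit set;
   classifier error is undefined on zero features.

The population update is $(\mu+\lambda)$ elitism: the best `n_pop` of
parents and offspring survive. The original description says only "update
the population"; we chose elitism because it guarantees the monotone
best-so-far trace that both stages' correctness tests rely on, and it is the
standard reading for this family of algorithms.

Defaults follow the published experimental setup where stated
(`n_pop = 20`, `max_iter = 50`) and otherwise use values conventional for
binary metaheuristics (`nop = 2`, `mr = 0.1`, seeding bounds $[-1, 1]$);
the mutation rate is constrained to the stated admissible range
$[0.005, 0.5]$.

## The refinement stage (SA)

SA starts from the population optimum. Each step proposes a single uniform
bit flip (with empty-mask repair), accepts it by the Metropolis rule for
minimization — improvements always, a worsening $\Delta > 0$ with
probability $e^{-\Delta/t}$ — and cools geometrically, $t \leftarrow l\,t$,
until $t \le T_{end}$. The printed acceptance inequality is ambiguous about
sign and direction; standard Metropolis is the only reading that cools into
hill-climbing, so that is what we implement. The current solution may wander
uphill; the best-so-far solution is tracked separately and returned, so
refinement can never lose the population optimum. Defaults
$T_0 = 1$, $T_{end} = 10^{-4}$, $l = 0.99$ give
$\lceil \log(T_{end}/T_0)/\log l \rceil = 917$ steps. A schedule with
$T_0 \le T_{end}$ runs zero steps, which turns the hybrid into the
population stage alone — useful for paired comparisons, and because the two
stages share one seeded random stream with the population stage first, such
a pair shares its population stage bit for bit.

## The synthetic generator

`generate_synthetic()` builds a class-labelled feature table with known
ground truth in three blocks: *informative* columns (class-conditional unit
variance Gaussians whose class means are drawn at random and rescaled so the
minimum pairwise distance between class means equals `class_sep`),
*redundant* columns (random unit-norm linear combinations of the informative
block plus noise of sd `noise_sd` — class signal, but nothing beyond the
informative block), and *noise* columns (standard Gaussians independent of
the class). Columns and rows are shuffled, and rows are split stratified at
`train_fraction = 0.7139`, the published benchmark's training share.

Default scale: 6 classes, 40 features (8 informative / 8 redundant / 24
noise), 120 samples per class. The sample count keeps the benchmark's
samples-per-feature ratio (10,299 samples for 561 features is roughly 18
per feature; $40 \times 18 \approx 730 = 6 \times 120$). `class_sep`
defaults to 3, chosen against two *a-priori* requirements that pull in
opposite directions: a classifier on the ground-truth informative columns
should approach the high-accuracy regime of engineered HAR tables (ruling
out small separations, which make the task unrealistically hard), and no
small sub-subset of columns should separate the classes outright (ruling
out large separations, which make the ground truth unidentifiable — many
masks that discard informative features are then genuinely optimal).

What the generator deliberately does **not** emulate: temporal correlation
between windows cut from one recording, subject-level grouping, the heavy
redundancy structure of real engineered features (hundreds of highly
correlated statistics), and bounded/normalized feature ranges. Passing
recovery tests on this generator therefore shows that the optimizer can
separate signal from noise columns under clean conditions; it does not show
that the selected subsets would transfer across subjects on real recordings.

### What recovery experiments can and cannot show

A methodological point worth stating plainly: with the `"holdout-test"`
protocol the search evaluates thousands of masks against one fixed, small
evaluation partition, and masks that include noise columns can *genuinely*
score better on it than the ground-truth mask — selection overfitting. When
that happens, retaining noise columns is a property of the objective, not a
search failure; recovery experiments in this package therefore use the
`"k-fold"` protocol, under which the error is averaged over all training
samples and such spurious optima are rarer (the recovery experiment's
noise-retention figure, reported by the acceptance script, quantifies what
remains). At
desk scale the subset-size penalty $(1-a)/D \approx 0.00025$ per feature is
far below the granularity of any error estimate, so pruning pressure on
exactly-neutral columns comes almost entirely from the error term; expect
recovered masks to keep a few noise columns whenever the evaluation
partition is small.

## Numerical and degenerate-input choices

* Distance ties, vote ties and equal-fitness selection are all resolved
  deterministically (documented above and in `?knn_predict`); with a seeded
  run the entire result record is reproducible bit for bit.
* Elitist survival ranks by fitness with a stable order, so parents win
  ties against offspring.
* Empty masks are repaired to a random single bit wherever they can arise
  (initialization, mutation, SA moves).
* `max_iter = 0` returns the best of the initial population with an empty
  trace; `t0 <= t_end` returns the initial solution untouched.
* Stratified splitting allocates training slots by largest remainder, so
  every class's share deviates from the target fraction by less than one
  sample.
* Percentages in printed reports are truncated (not rounded) to one decimal,
  matching the display convention of the published tables; machine-readable
  outputs keep full precision.

## Problem sizes used by the test-suite experiments

The correctness experiments run on deliberately small instances: an
8-feature, 3-class dataset on which exhaustive enumeration of all 255
non-empty masks is feasible (the hybrid must attain the exhaustive optimum
in at least 18 of 20 seeded runs), and the 40-feature default instance for
ground-truth recovery over 10 seeds. These sizes make the exhaustive oracle
exact and keep the full suite comfortably reproducible on a laptop; they are
the package's chosen study conditions, not estimates of real-data behaviour.

## Known limitations

* The frameshift operator is position-disruptive by construction (an
  offspring is its parent shifted by one), so the population stage behaves
  closer to a randomized restart search than to a recombining genetic
  algorithm; most fine improvement comes from the SA stage.
* The wrapper objective inherits the variance of its error estimate;
  on small evaluation partitions the selected subset size has little
  meaning beyond "roughly half the columns", and reduction ratios should be
  read accordingly.
* The native KNN classifier is quadratic in sample count per evaluation;
  for the full 561-feature benchmark with 10,299 samples a single 20-run
  experiment is an overnight job, which is why the package's experiments
  are synthetic-first.
* Only the KNN classifier ships natively; discriminant, naive-Bayes or tree
  classifiers plug in through the `classifier_spec(kind = "adapter")` seam
  but are not provided.
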