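---
title: "Methods: swarm-intelligence feature selection for screening recommenders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-intelligence feature selection for screening recommenders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmrec)
```

## What the package models

`swarmrec` implements a hybrid pipeline for behaviour-pattern screening in
digital mental health: frequent behaviour patterns are mined from
transaction-shaped interaction logs, text posts are featurised with TF-IDF,
a wrapper feature selector driven by two swarm metaheuristics — River
Formation Dynamics (RFD) and Particle Swarm Optimization (PSO) — picks the
feature subset that best supports a downstream model, and a user-based
collaborative-filtering (CF) recommender is evaluated on a top-N
precision/recall grid.  Every stage is backed by a synthetic-data generator
with planted, recoverable structure, so the whole pipeline is testable
without any clinical or social-media data.

## Frequent-pattern mining: the systolic tree emulation

The miner emulates a systolic tree: a tree of pipelined processing elements
(PEs) in which a control PE at level 0 holds no item and each general PE
stores one item with a support accumulator, linked through
leftmost-child/right-sibling references.  Hardware realisations stream
transactions through the PEs in a WRITE mode (tree construction) and count
candidate itemsets in SCAN/COUNT modes.  The emulation is functional, not
cycle-accurate: no timing contract is published for the dataflow, so the
modes become traversal procedures over an explicit node store
(`build_tree()`, `count_support()`).

Two decisions follow FP-tree convention because the tree is required to
mirror FP-tree relative positions without a stated ordering: items are
inserted in descending support order with lexicographic tie-breaks, and
`min_support` is an absolute count (a fractional convenience flag converts
by ceiling).  `mine_frequent()` does level-wise candidate generation with
anti-monotone pruning but takes *every* support from the tree; the
independent `apriori_oracle()` recounts supports directly from the raw
transactions, which is what the equivalence tests lean on.

## TF-IDF text features

The preprocessing pipeline applies the four classic operators in order:
tokenise (maximal alphabetic runs — numerals dropped, the simplest
reproducible rule), lowercase, stopword filtering (a fixed English list
shipped as a package fixture so results never depend on the runtime
environment), and Porter stemming.  The stemmer is implemented in-package
from the original five-step algorithm because no stemming library is
available in the target runtime.  Stemming can map an inflected word onto a
stopword (e.g. "ate" stems to "at"); the pipeline filters stopwords once
more after stemming, which is what makes it idempotent on its own output.

Term weighting is exactly `w[t, d] = tf[t, d] * log10(N / df[t])` — raw
counts, log base 10, no normalisation.  A term present in every document
gets weight zero; unseen terms are absent from the vocabulary, so `df >= 1`
always holds.

## River Formation Dynamics

Drops walk a weighted directed graph toward a goal node whose altitude is
pinned at 0; all other nodes start flat at `init_altitude` (default 100).
At node *i* the neighbours are split by the gradient
`(altitude(i) - altitude(j)) / distance(i, j)` into downhill, uphill and
flat sets; the transition weight is the gradient itself downhill,
`omega / |gradient|` uphill and `delta` on flat edges, normalised by their
sum.  The published probability rule prints the uphill term as
`omega / gradient`, which is negative on the uphill set; the absolute value
is the only reading that yields valid probabilities, and that is what the
package implements.

After all drops move, each traversed pair (i, j) erodes
`E / ((N - 1) * D) * gradient(i, j)` from `altitude(i)` — only the source
node of the pair, exactly as the rule is printed; whether the destination
should also change is unstated and we do not invent it.  The signed form
means climbing deposits rather than erodes.  Each iteration then returns
the total eroded soil uniformly to all non-goal nodes
(`erosion_produced / (N - 1)`), which conserves soil exactly and keeps the
landscape from flattening to zero gradients.

Remaining free choices, all config-exposed with defaults fixed once:
`omega = 0.2`, `delta = 0.1`, `E = 1`, `n_drops = 10`,
`sediment_fraction = 0.5` (the share of carried soil a stuck drop dumps on
its dead-end node before evaporating — the mechanism is described but never
quantified), altitudes floored at `1e-6` to keep gradients finite, and
immediate backtracking forbidden during walks (the drop may not return to
the node it just left), following the routing description.  Walks are
capped at N visited nodes, N the graph order.  The run stops at `max_iter`
iterations or after `patience` iterations without improving the best
goal-reaching path.

## Particle swarm optimisation

Global-best PSO under the minimisation convention, with the inertia-weight
velocity rule `v' = w v + R1 c1 (pbest - x) + R2 c2 (gbest - x)`; `R1`,
`R2` are drawn per dimension (the per-dimension subscripts in the printed
update imply independent draws).  At `w = 1` the update degenerates to the
original inertia-free rule, which the tests assert algebraically.  The
inertia schedule is linear from 0.9 to 0.4 over the run — the standard
"dynamic adjustment" the description alludes to without numbers — with a
constant-`w` mode available.  `c1 = c2 = 2` (never stated; the classic
default), `v_max = 0.2 * (upper - lower)` per dimension, and positions are
clipped to the box with velocity zeroed on clipped dimensions.

## The hybrid RFD-PSO selector

Published descriptions of this hybrid name a full algorithm listing and a
flowchart without printing either, so the schedule here is a documented
reconstruction; every piece
is a `hybrid_params()` knob.

Feature subsets are paths: drops walk a layered graph
`source -> (strictly increasing feature subsequence) -> sink` with unit
distances, so paths and binary masks are in bijection
(`path_to_mask()` / `mask_to_path()`).  Fitness of a mask is
`1 - quality + lambda * |mask|`, where quality is a deterministic held-out
evaluation — 3-NN accuracy on the masked columns, or precision@10 of a CF
recommender whose user similarities are computed on rating-weighted,
mask-restricted item-feature profiles.  `lambda` defaults to 0: an explicit
feature-count objective appears only in the related work being summarised,
so the penalty is optional rather than default behaviour.

Each of `n_phases` (default 3) rounds runs:

1. **RFD exploration** (`rfd_iters = 10` drop iterations): every
   goal-reaching path is scored; paths better than the running mean quality
   receive extra erosion on their feature nodes (scale `reinforce = 30`
   spread over the path), paths worse than the mean silt up by the same
   signed rule.  This concentrates future walks on promising features while
   the standard erode/deposit cycle keeps the landscape alive.
2. **PSO refinement** (`pso_iters = 15`, `swarm_size = 12`): the top-k
   distinct masks seen so far become particles in the `[0,1]^D` relaxation,
   placed at 0.8/0.2 with a small jitter so they sit decisively off the
   binarisation threshold of 0.5; every evaluation re-binarises at that
   threshold.  The velocity clamp is loosened to 0.5 so a bit can flip
   within a few iterations.
3. **Global-best reinforcement**: the refined best mask's path receives a
   small constant erosion bonus (`gbest_bonus = 0.1` times E) — our reading
   of the "small constant updating strategy" the account names but never
   defines.

Fitness values are memoised on the mask string, so the exploration and
refinement phases share one evaluation budget.  The best subset ever
evaluated is returned; a zero-iteration budget degenerates to the best of
the initial random draw.  Pure-RFD and pure-PSO selectors are exported for
the paired comparisons the tests run.

## Collaborative filtering and top-N evaluation

User-user similarities (Pearson or cosine) are computed over co-rated items
only, with two stated conventions: fewer than two co-rated items, or a
constant co-rated vector, give similarity 0.  For prediction and ranking
the similarities are additionally deflated by the Herlocker significance
weight `min(n_co, 20) / 20`, and the weighted-deviation predictor carries a
`+1` shrinkage in its denominator.  Both are standard user-CF components;
without them, predictions backed by one or two lucky co-ratings pin the top
of every ranked list and the top-2 precision of the evaluation grid is
visibly *worse* than top-4 — an artifact, not a property of the method.
`predict_rating(..., shrinkage = 0, significance = NULL)` recovers the
plain textbook formula.

Evaluation follows the conventional hold-out protocol: a per-user 80/20
split (random or temporal), relevance = held-out rating at or above 4 on
the 1–5 scale (the scale and threshold are package choices — no standard
fixes them), candidates = all items unrated by the user in training,
macro-averaged precision@N and recall@N over N = 2, 4, ..., 18.

## The synthetic worlds and what a green test establishes

* **Ratings** come from a rank-`n_factors` Gaussian latent model mapped
  onto the 1–5 scale, observed at `density` random cells with Gaussian
  noise.  The evaluation-shape tests use 800 users x 100 items at density
  0.3, rank 3, noise 0.3.  At this desk scale the regime being emulated is
  *neighbourhood abundance*: about 240 raters per item and about 9 co-rated
  items per user pair, matching the corpus the original evaluation claims
  (thousands of users) better than its literal density would.  Cells are
  missing completely at random — real rating data are not — so a green
  shape test says the method behaves correctly in a well-posed world, not
  that it reproduces any published table.
* **Per-replicate noise**: one replicate's precision curve moves by a few
  thousandths per grid step, the same order as the true slope, so the
  monotone-shape criterion is asserted on the mean curve over eight seeded
  replicates (recall monotonicity, which holds deterministically given
  nested lists, is asserted per replicate).
* **Transactions** plant itemsets as subsets of a stated number of
  transactions plus independent noise items, so planted supports are exact
  lower bounds recoverable by counting.
* **Corpus** is a balanced multinomial bag-of-words with a boosted
  signal-word set; at `signal_strength = 0` the class conditionals are
  identical by construction.  No grammar is modelled: the source's remark
  about adjective/negation grammar rules gives no rules to implement.
* **Actigraphy** uses a daytime half-sinusoid (08:00–20:00, peak 14:00)
  plus truncated Gaussian noise at one-minute epochs; condition subjects
  have daytime signal attenuated by a planted factor recoverable from
  group daytime means.  The scores table mirrors the clinical-metadata
  schema (patient number, days, gender, age group, affective type,
  melancholia, inpatient, marriage, work, MADRS at start/stop); the
  published schema truncates mid-sentence, so the two MADRS columns follow
  the public dataset family it paraphrases.
* **Feature tables** draw standard-normal columns with a logistic label on
  a random informative subset (coefficient magnitude 2 by default — a
  strong, clearly recoverable signal).

## Numerical choices and degenerate inputs

Probability normalisation is exact by construction; tests assert it to
1e-9.  Soil conservation is asserted in absolute terms (1e-9) because an
iteration's net erosion can be arbitrarily close to zero.  Empty masks are
never evaluated: they score worst with a warning at the API surface and
silently worst inside optimisation loops.  Ties in top-N ranking break by
item index; ties in drop transitions are resolved by the sampling weights
themselves.  Duplicate (user, item) ratings keep the last occurrence with a
warning; blank transaction lines are retained as empty itemsets.

## Known limitations

The hybridisation schedule is a reconstruction, not a reproduction of an
unpublished listing.  Previously reported headline precision/recall numbers
for this pipeline are not reproduction targets: they derive from a corpus
that is unavailable and internally inconsistent, and the summary averages
quoted alongside them cannot be derived from the accompanying tables by any
standard averaging we checked.  Off-the-shelf SVM / Naive Bayes
classification workflows are out of scope, as are ACO variants, DSM-IV
symptom sub-categorisation, and any VLSI realisation of the systolic
tree.
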