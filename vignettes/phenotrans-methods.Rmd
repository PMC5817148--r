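---
title: "Models and methods in phenotrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenotrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Endosymbiotic bacteria such as *Wolbachia* manipulate the reproduction of
their arthropod hosts in a handful of characteristic ways: cytoplasmic
incompatibility (CI), feminization (FI), male killing (MK), parthenogenesis
induction (PI), and a residual "other" category (O). Treating the induced
phenotype as a five-state discrete trait of the symbiont, three questions
arise: does the trait track the symbiont phylogeny at all (is it a heritable
trait of the bacterium), which state is ancestral for the major clades, and
are some transitions between states systematically faster than others?

`phenotrans` implements the full comparative toolkit for these questions —
maximum-likelihood Mk-model fitting with a bespoke eight-model family,
two phylogenetic-signal tests, a reversible-jump MCMC over rate-class
models with Bayes factors, marginal ancestral states at tagged clades, and
a cross-method rate synthesis — together with a synthetic-data generator,
so that every stage is testable end to end without any external data.

# The model

The trait evolves along a rooted tree with branch lengths (expected
substitutions) under a continuous-time Markov chain with instantaneous
rate matrix $Q$: off-diagonal $q_{ij} \ge 0$ is the rate of switching from
state $i$ to state $j$; rows sum to zero. With five states there are 20
ordered transition rates. Branch transition probabilities are
$P(t) = e^{Qt}$, and the likelihood of the tip data is computed by
Felsenstein's pruning algorithm with per-node rescaling (C++ kernel; no
underflow up to at least 500 tips, verified by test). The root is weighted
by a prior $\pi$ — uniform by default, optionally the stationary
distribution of $Q$; the original analyses do not record which weighting
their software used, so both are offered and uniform (the common default
in the packages of this field) is the package default.

A *rate model* assigns each of the 20 ordered pairs either to a ZERO class
(rate fixed at exactly 0) or to one of $k$ shared free-rate classes. Three
canonical schemes — `single` ($k=1$), `symmetric` ($k=10$, $q_{ij}=q_{ji}$),
`unconstrained` ($k=20$, "all rates different") — are complemented by five
*reduced* models: starting from the unconstrained maximum-likelihood fit,
rates below a threshold (default 0.1, in the tree's branch-length units)
are fixed at zero, and the surviving range $[lo, hi]$ is cut into
$k \in 1..5$ equal-width intervals, half-open except the last; all rates in
one interval share a class. A value exactly on an interior boundary joins
the upper interval, empty intervals are dropped (so the reported $k$ is
the number of occupied classes), and a zero-width range collapses to one
class with a message. Reduced models re-estimate their class rates from
scratch rather than freezing the binned values: the source procedure says
the models "were fitted", which we read as re-optimization; this is a
declared choice.

Model selection uses AIC $= 2k - 2\ln L$, lowest wins, ties broken toward
fewer parameters.

## Optimization

Each fit maximizes $\ln L$ over the $k$ class rates with L-BFGS-B on the
log scale, bounded to $[10^{-8}, 10^{3}]$. Twenty-parameter surfaces in
this family are multimodal, so every fit uses a battery of starts:

* a parsimony-informed start (observed minimum number of transitions
  divided by total tree length) — good when the trait is clustered;
* a near-saturation start (5 changes per mean root-to-leaf depth) — good
  when the trait carries little signal and the optimum is a saturated
  matrix. Without this start, no-signal datasets left real-tree fits
  stuck in low-rate local optima (discovered during calibration of the
  star-tree test, see "Known limitations");
* `n_starts` random starts, log-uniform on $[10^{-3}, 10]$;
* warm starts chained from simpler schemes inside `select_best()`
  (single → symmetric → unconstrained; reduced models start at the
  binned class means of the unconstrained fit). The chaining both speeds
  the family up and enforces the nesting property
  $\ln L_{ARD} \ge \ln L_{SYM} \ge \ln L_{ER}$ up to optimizer tolerance.

The whole multi-start procedure is deterministic given `fit_opts(seed=)`.

# Phylogenetic signal

Two tests, matching the two used in the source analysis:

1. **Star-tree AIC comparison.** The eight-model selection is run on the
   real tree and on a star tree (all tips attached to the root).
   $\Delta AIC = AIC^{star}_{best} - AIC^{tree}_{best} > 0$ indicates
   signal. The star's pendant branch length is not specified by the
   source; we use the mean root-to-leaf path length of the real tree
   (configurable), which keeps the expected number of changes per lineage
   comparable between the two topologies.
2. **Minimum-transitions permutation test.** The Sankoff parsimony
   minimum (unordered states, unit costs, branch lengths ignored,
   polytomies handled natively) is compared with its distribution under
   uniform permutation of the tip phenotypes. The p-value uses the
   add-one estimator $p = (1 + \#\{null \le obs\}) / (1 + n_{perm})$,
   one-sided (fewer transitions = clustering), ties counting toward
   significance. The source does not report its permutation count; the
   default is 10,000, which comfortably resolves p-values of the order
   reported there (3 × 10⁻⁴).

Because the statistic is a small integer, ties between the observed value
and the null make the add-one p-value *conservative* (never
anti-conservative; verified by test). Exact uniformity holds for the
standard randomized tie-broken transform, which is what the calibration
test checks.

# Reversible-jump MCMC

The sampler explores rate-class models directly: the state is a labeled
assignment of the 20 pairs to label 0 (ZERO) or one of 20 class labels,
one rate per nonempty class, plus a tree index when a sample of trees is
supplied (integrating over phylogenetic uncertainty). The target is

* uniform over labeled assignments and over tree indices,
* i.i.d. exponential(mean $\mu$) rates on nonempty classes
  ($\mu \in \{1, 10, 100, 500\}$ in the source design), and
* the trait likelihood.

Moves per iteration (probabilities configurable): rate update 0.6
(log-normal multiplicative proposal, sd 0.3, on one random class;
accepted with the exact prior and Hastings factors), reassign one pair to
a uniformly chosen other label 0.15, split a class 0.1, merge two classes
0.1, tree switch 0.05.

**Design choice (deviation from the sketched kernel):** when a move
creates a class, its rate is drawn *from the exponential prior* rather
than jittered from the parent class. Prior draws cancel exactly against
the target's prior factor, so every trans-dimensional acceptance ratio is
free of Jacobian terms, and a likelihood-off chain provably samples the
exponential prior — which the acceptance suite verifies to 5% on the
pooled rate mean at 10⁵ samples, together with a total-variation check
between independently seeded chains. A jittered-rate split needs a
hand-derived Jacobian with nothing to validate it against (the source's
appendix defining its computation is unavailable).

Model signatures are canonical strings (classes relabeled by first
appearance, ZERO printed as 0), so label permutations collapse to one
model. A model's parameter count $k$ is its number of nonempty free
classes; a model with some rates zero and all others equal has $k = 1$.

**Bayes factors.** The exact model prior induced by the jump kernel is
characterized empirically by a mandatory matched prior-only run, and
$BF = \frac{post/(1-post)}{prior/(1-prior)}$ on add-one-smoothed visit
fractions, per model and per $k$-class. Natural-log BF is reported (with
log10 alongside, since the source's base is unstated) with Kass–Raftery
verbal labels ($\ln BF > 5$ "decisive"). Items never visited by the prior
chain are flagged: their BF rests entirely on smoothing.

**Diagnostics and ancestral states.** Geweke's z compares the first 10%
and last 50% of a trace with batch-means (20 batches) variance estimates;
zero-variance windows with equal means are flagged undefined rather than
converged, and zero-variance windows with different means are reported as
divergent. Ancestral states at a tagged clade average the marginal
posterior state probabilities at the clade's MRCA over all retained
samples (model, rates, and tree resampled per iteration), skipping and
counting zero-probability samples; Monte-Carlo standard errors accompany
the means. Burn-in discards the first 10% of samples (configurable).

# Cross-method synthesis

Per method-by-dataset combination, the 20 per-pair rate estimates are
min-max standardized to $[0,1]$ (an all-equal vector maps to all zeros,
keeping structural zeros at zero), averaged per pair across combinations
(standard error = sample sd /$\sqrt m$), ranked (descending, lexicographic
tie-break, top four flagged), and cross-correlated with Spearman's rank
correlation (average ranks for ties; two-sided p from the t
approximation). The source is ambiguous about the correlation flavor in
one figure (Spearman in the caption, an r-value in the text); Spearman is
computed and reported as the default statistic.

In the pipeline, the per-pair ML rate vector entering the synthesis comes
from the *unconstrained* fit rather than the AIC-best model: the best
model may constrain many pairs to a single shared value (or zero), which
carries no rank information across the 20 transitions.

# Synthetic data

The generator states a world and stays there:

* **Yule trees**: pure birth from a root bifurcation; with $k$ lineages
  the next split waits Exp($\lambda k$); after reaching $n$ tips one
  final Exp($\lambda n$) stretch is appended, so the expected height is
  $\sum_{k=2}^{n} 1/(\lambda k)$ (verified against 200 simulated trees).
* **Trait simulation**: Gillespie along each branch with the full event
  history recorded, so parsimony lower bounds and true ancestral states
  can be checked against the realization.
* **Preset scenario** (`wolbachia_like_scenario`): 53 ("small") or 71
  ("large") ingroup tips — the two taxon-set sizes of the study system —
  split into clades A and B (Yule subtrees rescaled to height 0.8 under
  0.2 stems), plus one outgroup on a stem twice the ingroup height
  (clean MRCA separation). Traits evolve under a two-class model: a fast
  class (rate 3.0) on PI→MK, MK→O, O→CI, MK→CI (the transitions
  repeatedly flagged as high in comparative work on this system), six
  structural zeros among the rarely observed FI/PI/O interchanges, and a
  slow class (0.3) elsewhere; the root prior is CI-skewed (0.6/0.1/…),
  reflecting CI's dominance among described phenotypes. These are
  generator defaults, not claims about the real system.

Where the acceptance tests need a trait-change budget, the rate is set so
the expected number of changes ($4 r L$ under an equal-rates matrix of
rate $r$ on total tree length $L$) matches the transition-count scale
actually observed in this study system (~15 on ~53 taxa): $r = 0.07$ on
unit-birth-rate 53-leaf Yule trees.

What a green test does *not* establish: the generator produces clocklike
(ultrametric) ingroup trees, a single trait realization per dataset, no
among-branch rate heterogeneity, no phenotype uncertainty at the tips,
and no tree-estimation error (trees are inputs by contract). Real
consensus trees with polytomies, non-clocklike branch lengths, and
database-derived phenotype labels violate all of these in ways the tests
deliberately do not model.

# Numerical choices

* $P(t)$ by one-off eigendecomposition of $Q$; if reconstruction fails
  1e-9 (defective $Q$, common with structural zeros) or produces entries
  below −1e-12, scaling-and-squaring is used instead. Surviving negative
  roundoff above −1e-12 is clamped to zero; worse values error.
* Pruning rescales each message by its maximum, accumulating the log, so
  likelihoods of several hundred tips stay finite.
* Probability-zero data return $-\infty$ from the likelihood (a value,
  not an error) but error from marginals (undefined conditional).
* Missing branch lengths are filled with 1.0 under a warning; zeros are
  kept exact. Trees are used rooted as read, never rerooted.
* All stochastic entry points take a seed and restore the caller's RNG
  state; chains, fits and the pipeline are bit-reproducible given seeds.

# Known limitations

* **Reduction instability without signal.** The threshold-and-bin
  reduction inherits its zero/bin pattern from the unconstrained fit.
  When the trait carries *no* signal (e.g. shuffled tips), the real
  tree's unconstrained fit chases accidental clustering and yields a
  pattern whose reduced models fit poorly, while the star tree's fit
  lands near the clean iid optimum and reduces well. The star therefore
  wins by ~10 AIC units on shuffled 53-leaf data even though the real
  tree can express the same distributions (refitting it under the
  star-derived assignment reproduces the star's log-likelihood to 4e-4).
  The corresponding acceptance expectation (|mean ΔAIC| < 2 after
  shuffling) is deliberately left failing with this analysis attached:
  it documents a real artifact of the eight-model procedure at this data
  scale, not an implementation defect. The signal direction of the test
  (ΔAIC > 0 under simulated signal) is unaffected.
* The empirical-prior Bayes factor is a declared substitute for the
  source's (unavailable) exact definition; it is self-consistent but not
  guaranteed identical.
* The MCMC kernel mixes slowly across very dissimilar assignments on
  strongly informative data; study-scale inference should use long runs
  (the source used 5 × 10⁸ generations) — desk-scale defaults here are
  for calibration and testing.
* `fitDiscrete`-style corrections for unobserved states, hidden-rate
  models, and non-reversible root handling variants are out of scope.
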