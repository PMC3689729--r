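---
title: "Inferring Boolean networks from time-series data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Boolean networks from time-series data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A Boolean network on $n$ species is a set $F = \{f_1, \dots, f_n\}$ of
Boolean update rules: the next state of species $i$ is
$x_i(t+1) = f_i(x(t))$, a function of the current 0/1 state of the whole
system.  Synchronous simulation applies all $f_i$ simultaneously;
asynchronous simulation repeatedly picks one species uniformly at random and
updates it immediately, and averages many such executions — the Boolean
analogue of stochastic (SSA-style) single-molecule simulation.

`boolinfer` reverse-engineers such networks from real-valued concentration
time series in two stages:

1. **Binarization** of each species' trajectory into 0/1, followed by
   removal of false steady-state redundancy.
2. **Learning** one update rule per species from the reduced binary
   trajectories, with candidate networks scored by a trajectory error and
   searched for the minimum-error model.

# Binarization

Three per-species binarizers are provided.

**KM-1** clusters the values (time stamps are ignored) into two groups by
1-D $k$-means; the higher-mean cluster becomes 1.  Cluster centroids are
initialized at random values drawn from the data, as in classical
$k$-means, so repeated runs can differ on ambiguous data.  This randomness
is *intentional*: the outer search iterates over binarizations and keeps
the one whose learned network scores best.  Consequently KM-1/KM-3 results
are functions of R's global RNG state; every top-level entry point accepts
a `seed` argument.  The 2-means partition is invariant under positive
affine transforms of the data, so whether the series was 0–1-normalized
first is immaterial for the k-means binarizers (it matters only for the
step-function scores of BASC A, which is why `normalize_series()` is
exposed separately).

**KM-3** (`binarize_km3()`, depth $d$, default 3) starts from $k = 2^d$
clusters, replaces every value by its cluster's mean, decrements $d$ (so
$k$ halves), re-clusters the smoothed values, and emits bits at the final
$k = 2$ pass.  The coarse-to-fine smoothing lets late, low-amplitude peaks
of a damped oscillation merge with the earlier peaks rather than with the
baseline, preserving the oscillatory pattern that direct 2-means flattens.
Two numerical details are worth stating.  First, when $2^d$ exceeds the
number of distinct values at some level, $k$ is clamped to that number
(replacing values by means can merge them, and clamping avoids empty
clusters).  Second, the peak-preserving behaviour is a property of the
*stochastic* Lloyd iteration, not of the globally WSS-optimal clustering:
on the 8-point damped example in the test suite the exhaustive optimum
merges the late peaks into the baseline, while random initialization
recovers the full alternation in roughly a fifth of draws — and the outer
minimum-error iteration then selects such draws.  Tests therefore assert
the KM1/KM3 contrast as a frequency dominance over seeds rather than a
per-draw certainty.  Assignment ties go to the lower-index centroid, and
degenerate (constant) inputs raise a classed error rather than silently
emitting zeros, because a constant species carries no Boolean signal and
silent coercion would corrupt learning.

**BASC A** (`binarize_basca()`) is deterministic.  The sorted vector is an
ascending step function; for every discontinuity count $j = 1..N-2$ a
dynamic program (verified in the tests against exhaustive enumeration)
finds the $j$-discontinuity ascending step function minimizing quadratic
distance to the sorted data.  Each optimal step function contributes its
strongest discontinuity under the score
$\mathrm{jump}/\max(\mathrm{error}, 10^{-12})$, where the jump is the
difference between the means of the values above and below the break and
the error is the two-sided within-group SSE; ties prefer the larger jump,
then the smaller index.  The candidate threshold at a break is the midpoint
of the two flanking sorted values, and the final threshold is the median of
the candidates (mean of the middle two for an even count).  The upstream
description of this method defers the exact scoring to its original
publication; the ratio above follows the verbal description and is fixed
here as the package's definition.

**Redundancy removal** (`remove_redundancy()`): finely sampled data produce
runs of identical consecutive binary states that falsely suggest steady
states.  Since a synchronous Boolean system can only repeat a state at a
point attractor, every maximal run is collapsed to a single state — except
a run ending at the final time point, which is collapsed to exactly two
states so that a true terminal steady state remains visible as an equal
consecutive pair.  The operation is idempotent.

# Learning

All learners scan regulator subsets by increasing size ($0, 1, \dots,
k_{\max}$; lexicographic within a size) and keep only subsets of the
smallest size meeting their criterion.  The maximum in-degree defaults to 3,
following the original REVEAL recommendation, and is applied uniformly to
all three learners for comparability.  If a size level ever yields more
than 1000 qualifying subsets, the first 1000 in scan order are kept with a
warning.

**REVEAL** consumes a *deterministic transition table*: consecutive state
pairs are tallied and, for each source state, only the most frequent
successor is retained (ties: the successor with the smaller integer
encoding, most significant bit first).  A subset $X$ qualifies for target
$y$ when the mutual information $M(X; y) = H(X) + H(y) - H(X, y)$ over the
table rows equals $H(y)$ (exact functional dependence) *and* all $2^{|X|}$
input patterns occur among the sources (completeness).  Each qualifying
subset has a unique consistent truth table.  An empty candidate list is a
legitimate outcome.

**Best-Fit** builds, per subset, a partially defined Boolean function
(pdBf) directly from the *raw* consecutive pairs — determinization would
hide exactly the inconsistencies its error size measures.  The error size
is $\sum_p \min(\#\text{true}_p, \#\text{false}_p)$ over patterns $p$;
observation counts weight the sum by default (`weighted = FALSE` counts
distinct pairs once; the upstream description is ambiguous on this point).
The minimum error over all subsets up to $k_{\max}$ is located, the subsets
achieving it at the smallest such size are kept, conflicting patterns are
resolved by the majority class (ties to 0), and undefined truth-table
entries are filled by coin flips from the global RNG.

**Full-Fit** is the same scan accepting only zero-error subsets; when every
subset conflicts, no function — and hence no network — exists for that
binarization, which the search reports as an explicit empty result.

**Network sampling**: because the data rarely cover all input patterns,
many functions per species may qualify; `sample_network()` picks one
uniformly per species, and the search samples 100 networks per binarization
and keeps the best.

**Multiple experiments.**  When learning from several trajectories
(cross-validation), pairs are pooled without ever forming a pair that spans
two experiments.  For REVEAL one further choice was forced by
experimentation: determinizing pairs pooled across experiments that
disagree (different initial conditions reach the same binary state in
different phases) yields a table that almost never admits a complete
$M = H$ subset of size $\le 3$ for every species — strict pooling would
leave REVEAL cross-validation without a single network.  Species that the
pooled table cannot resolve therefore fall back to the union of their
single-trajectory REVEAL candidates; the minimum-error criterion over all
pooled training data still selects the final network.

# Error, search, and cross-validation

The **trajectory error** of network $N$ against a reduced binary trajectory
$b_1, \dots, b_T$ simulates $N$ synchronously from $b_1$ for $T-1$ steps
and counts mismatching bits over states $2..T$, normalized by $n(T-1)$ (the
first state is copied by construction and carries no information; the
denominator lives in one place in the C++ kernel should a different
convention ever be preferred).  The error is 0 exactly when the network
reproduces the reduced data.

The **iterated search** (`search_min_error()`) repeats, per search:
binarize, reduce, learn candidates, sample 100 networks, score each.  One
scored network is one *iteration*; a search stops at a zero-error network
or after `max_iterations` (default 10,000) iterations.  Reported metrics
follow the conventions: *min error* is the global minimum over searches;
*convergence* is the mean, over searches, of the iteration at which each
search first reached its own best; *uniqueness* is the number of distinct
synchronous trajectories produced by the winning networks, each simulated
from the first state of its own binarization — distinct networks with
identical dynamics count once.

**Predictive power** is assessed by leave-one-out cross-validation over
datasets differing in initial conditions.  Per repeat, all datasets are
binarized and reduced once (stochastic binarizers re-draw every repeat);
per fold, a minimum-error network is learned from the other datasets by
sampling `samples` (default 100) candidate networks and keeping the best
scorer on the training trajectories; the held-out trajectory is then
predicted one synchronous step at a time, and the fraction of mismatched
bits is averaged over pairs, folds, and repeats.  Prediction error 0 means
a perfect one-step predictor; 1 means always wrong.  The per-fold learning
budget (one binarization round of 100 sampled networks per repeat) is a
pragmatic choice: the search on these data typically reaches its best
network within the first few dozen iterations, and the 100 repeats supply
the binarization diversity.

# The synthetic toy system

`toy_model_spec()` / `generate_toy_series()` provide a fully synthetic
four-gene oscillator so that the entire pipeline is testable without
external data.  The regulatory topology is: gene A is self-regulatory; the
protein products of A and B form a heterodimer that activates C; C
activates D; and D inhibits both A and B.  The kinetic realization is the
package's own: Hill activation/inhibition terms (shared Hill coefficient
4), first-order decay, a basal transcription fraction of 0.2 on A so the
self-loop can escape $A = 0$, and rate constants (in $h^{-1}$)
$v = (1.2, 1.0, 2.0, 1.5)$, $k = (1.0, 1.0, 1.5, 0.8)$ with thresholds
$K = (0.3, 0.25, 0.2, 0.4)$.  These values were chosen once so that the
A/B → C → D ⊣ A/B negative feedback loop, helped by the positive self-loop
on A, produces sustained relaxation oscillations with 4–6 peaks per species
over the 0–24 h window from *every* 0/1 corner initial condition, and were
then frozen.  The default sampling grid is 241 equally spaced points
(0.1 h), which after KM-3 binarization and redundancy removal leaves
roughly 35–40 informative states.  Integration uses an embedded
Dormand–Prince RK45 scheme (rtol $10^{-6}$, atol $10^{-9}$) implemented in
the package because no ODE solver is available among its dependencies;
tolerance-halving convergence is checked in the tests.

What a green test on this generator does and does not establish: the toy
system exercises oscillatory, multi-timescale dynamics, phase diversity
across initial conditions, and near-Boolean switching — but it is
noise-free, stationary, densely and uniformly sampled, and only four
species.  Success here does not imply success on sparse, noisy experimental
series (the subsampling helpers `subsample_timepoints()` exist precisely to
emulate that failure mode), and the package makes no attempt to judge
trajectory similarity visually.

# Degenerate inputs, ties, and other numerical choices

* Constant species raise classed `boolinfer_degenerate_error`s everywhere
  (binarization, normalization), with the species named.
* All stochastic components draw from R's global RNG; top-level functions
  derive independent per-search/per-repeat substreams from one integer seed
  via a fixed linear map, so results are reproducible and independent of
  scheduling order.
* Transition-table ties and pdBf output ties break deterministically
  (smaller successor encoding; majority with ties to 0).
* The asynchronous simulator counts one *step* per single-species update
  (not per sweep); with a single isolated species it is therefore
  deterministic alternation — mixing behaviour requires at least two
  species.  Defaults: 100 runs, $10n$ steps.

# Known limitations

* Learning is restricted to in-degree $\le k_{\max}$ (default 3); systems
  whose determinized tables genuinely require more regulators yield empty
  REVEAL/Full-Fit results.
* The candidate-pool cap (1000 subsets per size level) makes very
  underdetermined problems tractable at the cost of completeness of the
  enumeration.
* Multi-level (non-binary) discretization, probabilistic Boolean networks,
  and automated trajectory-similarity judgments are out of scope.
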