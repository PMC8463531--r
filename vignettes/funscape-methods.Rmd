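---
title: "Methods: attractor landscapes, community simulation and beta-diversity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attractor landscapes, community simulation and beta-diversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funscape)
```

## What the package computes

Microbial communities can be viewed as dynamical systems whose
*functional composition* — the relative abundances of predicted gene
functions such as KEGG orthologs or GO terms — moves on a landscape with
several locally stable configurations ("metastability").  `funscape`
implements the complete analytical pipeline for detecting such
attractors from sample-by-function abundance tables, a stochastic
individual-based community simulator for asking whether pairwise species
interactions alone can generate metastability, and the beta-diversity
statistics used to answer that question.

The pipeline has four stages:

1. **Dissimilarity.** Pairwise Jensen–Shannon divergence (JSD) between
   the renormalised functional compositions of all samples,
   \(\mathrm{JSD}(p, q) = H(m) - \tfrac{1}{2}(H(p) + H(q))\) with
   \(m = (p+q)/2\) and Shannon entropy \(H\) in bits, so the divergence
   lies in \([0, 1]\).  The base of the logarithm is a free choice; we
   use base 2 because the bounded scale makes the Mapper cover
   construction scale-free.  The divergence itself (not its square root)
   is used: no downstream step requires the triangle inequality.
   Compositions are always renormalised first, so count tables and
   relative-abundance tables behave identically.
2. **Ordination.** Principal coordinate analysis (classical metric
   scaling) of the JSD matrix.  Axes with eigenvalue below
   \(10^{-10}\lambda_{\max}\) are dropped; *relative eigenvalues* (each
   eigenvalue over the sum of positive eigenvalues) report the fraction
   of variance each principal coordinate captures, in the usual
   "Table of variance explained" layout via `eigenvalue_table()`.
3. **Mapper.** The first two principal coordinates are the filter.  The
   plane is covered by a 15 × 15 grid of overlapping closed rectangular
   windows (70 % overlap between consecutive windows, window edges
   anchored to the data minimum and maximum).  Each window's preimage is
   clustered by single linkage *in the original JSD metric* (the
   ordination is only a lens; clustering in the metric is the Mapper
   convention) with the histogram gap heuristic: the merge heights plus
   the preimage diameter are binned into 10 equal-width bins over
   \([0, d_{\max}]\) and the cut is placed at the left edge of the first
   empty bin above the smallest merge height.  Bins below the smallest
   merge height are ignored — otherwise any preimage whose merges all
   fall in the upper bins (for instance two samples, or any set of
   equidistant samples) would shatter into singletons, which contradicts
   what the heuristic is for.  Clusters become nodes; nodes sharing at
   least one sample are joined by an edge.  Nodes containing a single
   sample are pruned before attractor detection; their samples become
   "unassigned".
4. **Attractors and basins.** Every sample receives a k-nearest-
   neighbour (kNN) value — the JSD to its \(k\)-th nearest neighbour,
   with \(k = \lceil\sqrt{n}\rceil\) by default — which is inversely
   related to the local density of observed community states.  A node's
   raw potential is the mean kNN value of its members.  Attractors are
   maximal connected sets of equal-potential nodes with no
   lower-potential neighbour; every other node descends along steepest
   potential descent (ties broken deterministically toward the smallest
   node id) until it reaches an attractor, and a sample belongs to the
   basin of the lowest-potential node containing it.

## The potential and why it is smoothed

The raw node potential is a mean of few kNN values, and its sampling
noise is of the same order as the real potential differences inside a
dense region.  Left untreated, that noise manufactures spurious shallow
basins: on synthetic landscapes with two planted archetypes the raw rule
returned three to five attractors in half of the runs, at every noise
level we tried.  The underlying landscape method describes the kNN
values as being "modified" into a potential without fixing the
modification, so the package adopts a deliberately simple one: five
rounds of size-weighted averaging of each node's potential with its
graph neighbours (`find_attractors(smooth = TRUE, smooth_rounds = 5)`).
Weighting by node size lets well-populated nodes dominate their
thinly-populated slivers, and because potential only diffuses along
edges, regions of the graph that are not connected — in particular,
well-separated archetypes — can never be merged by smoothing.  Five
rounds is past the point where recovered attractor counts stop changing
on our synthetic landscapes.  `smooth = FALSE` restores the raw rule,
which the unit tests use to pin down the descent and tie-break
semantics exactly.

Potential equality (for plateau detection) is judged at a relative
tolerance of \(10^{-9}\), since potentials are floating-point means.

## Hyperparameters

| Parameter | Default | Meaning |
|---|---|---|
| `intervals_per_axis` | 15 | Mapper windows per filter axis |
| `overlap_fraction` | 0.70 | fraction of a window shared with its successor |
| `histogram_bins` | 10 | bins of the merge-height histogram |
| `knn_k` | \(\lceil\sqrt{n}\rceil\) | neighbour rank of the density estimate |
| `smooth_rounds` | 5 | potential-smoothing iterations |

The first three are the hyperparameters of the published landscape
analyses and are kept as defaults everywhere, including the
command-line interface.

## The community simulator

Two individual-based models act on `I = 500` sites holding individuals
of up to `S = 50` metacommunity species, run for 600 timesteps with 450
replicates per parameter combination (all defaults of `sim_config()`).

**Self-organized instability (SOI).** Pairwise interactions live in an
\(S \times S\) matrix `A`; `connectivity` is the fraction of
off-diagonal entries that are non-zero, their values are uniform on
\((-1, 1)\), and signs are switched at random until at most 30 % of the
non-zero entries are positive (the positive-edge-percentage cap).  The
diagonal holds a self-limitation constant of −0.5.  Each timestep has
three phases in fixed order: (1) *immigration* — each species enters one
uniformly chosen empty site with its migration probability, drawn once
per parameter combination from U(0, 1); (2) *interaction/growth* — `I`
events, each picking a random occupied site \(a\) (species \(i\)) and a
random other site \(b\); an empty \(b\) is colonised by \(i\) with
probability 0.5 (`growth_prob`), an occupied \(b\) (species \(j\)) is
resolved by the net effect \(\Delta = A_{ij} - A_{ji}\): \(i\) displaces
\(j\) with probability \(\min(1, \Delta)\) if \(\Delta > 0\), and
conversely if \(\Delta < 0\); (3) *extinction* — every occupied site is
vacated independently with probability 0.1 (`extinction_prob`).  The
published description delegates the mechanics to the SOI literature;
this phase structure is the package's concrete reconstruction of the
model's three ingredients, and connectivity 0 degenerates exactly to
neutral dynamics.  The extinction and growth rates and the interaction
value distribution are not published; the defaults above are explicit
package choices and all are configurable.

**Hubbell (neutral).** Connectivity 0 dispatches to a zero-sum neutral
model: per timestep, `round(0.1 * I)` uniformly chosen individuals die
and are immediately replaced, by an immigrant with probability
\(\bar m\) (the mean migration probability; immigrant species drawn
proportional to the migration probabilities) or by the offspring of a
uniformly chosen other local individual.  Occupancy stays at `I`.

Both inner loops are compiled (C++) and consume R's random number
stream, so a single experiment seed makes entire experiments
bit-reproducible; per-replicate seeds are drawn without replacement
from one seeded stream, which also guarantees no two parameter
combinations share a replicate seed.  All replicates of a combination
share the interaction matrix, the fixed initial individuals and the
migration probabilities; the `n_fixed` fixed individuals (0, 100 or 200
of the 500) occupy the same sites in every replicate, and the rest are
drawn uniformly per replicate.

## Beta-diversity statistics

Within each parameter combination the 450 final communities are grouped
into 225 disjoint random pairs ("each community used once"), and each
pair is scored with the classic Morisita overlap
\[
C = \frac{2\sum_i x_i y_i}{(\lambda_x + \lambda_y)XY},\qquad
\lambda_x = \frac{\sum_i x_i(x_i-1)}{X(X-1)},
\]
using the unbiased \(\lambda\) rather than the Morisita–Horn
simplification because only the former allows \(C > 1\) (overlap
exceeding within-community aggregation), the regime reported for these
simulations; the dissimilarity is \(d = 1 - C\), negative in that
regime.

The response is modelled with gamma GLMs with an inverse link
(\(\mu = 1/\eta\)) and numeric covariates: connectivity \(c\), fixed
individuals \(x\), and their product.  Five models — null, `Con`,
`Fix`, `Con + Fix`, `Con + Fix + Con:Fix` — are ranked by the
small-sample Akaike criterion
\(\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)\) with Akaike weights
\(w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}\).  The likelihood
convention is the gamma plug-in used by base R: dispersion
\(\hat\varphi = \mathrm{deviance}/n\), log-likelihood the sum of gamma
log-densities with shape \(1/\hat\varphi\), and \(k\) counting the
dispersion (so the intercept-only model has \(k = 2\) and the complete
model \(k = 5\)).  Nested models are compared by the deviance
difference scaled by the Pearson dispersion of the full model, referred
to a \(\chi^2\) distribution with degrees of freedom equal to the
coefficient difference.

A gamma response must be positive.  When every pair's dissimilarity is
negative (the all-\(C>1\) regime) the reflected dissimilarity
\(y = -d\) is used; otherwise the overlap \(y = C\) is used, and the
choice actually taken is recorded in the analysis object and the run
configuration.  In this package's own reconstruction of the simulation
study the overlaps straddle 1, so the overlap response is selected.

## The synthetic-data generators

The generators produce tables with *known* attractor structure so the
whole chain can be validated without any external dataset:

* `sample_cross_sectional()` — `K` archetypal compositions over `F`
  features built from disjoint dominant-feature blocks blended toward
  uniform by `separation` (at separation 1, pairwise JSD between
  archetypes is exactly 1), each sampled `n_per_group` times with
  Dirichlet noise of a given `concentration`.  Dirichlet noise is a
  modelling choice; any strictly positive compositional noise behaves
  equivalently under JSD.
* `sample_trajectories()` — longitudinal cohorts in which each subject
  starts at a start-mode-specific composition (e.g. two birth modes)
  and contracts toward a shared target archetype at rate
  `convergence_rate`, emulating ecological succession toward a common
  mature state.
* `sample_generational()` — multi-generation lineages that keep their
  archetype or switch to a random other one with probability `drift`
  per generation (drift 0 = perfect functional persistence).

Generators emit proportions; a `depth` parameter draws multinomial
counts for Morisita-style analyses.  What the generators do *not*
emulate: feature correlation structure, sparsity patterns of real
functional annotations, uneven sequencing depth, or subject-level
covariance — so passing the recovery suites demonstrates correctness of
the chain on its own assumptions, not performance on real annotation
pipelines.

## Problem sizes and numerical choices in the validation suites

The test suite validates the chain end to end on planted landscapes
with K ∈ {2, 3, 4} archetypes, 100 samples per archetype, 200 features
and concentration 1000.  Those sizes satisfy the recovery
preconditions by a comfortable margin: the planted separation is then
roughly 28 times the within-archetype JSD spread, and each archetype is
densely sampled relative to the fixed 15-interval cover.  At much
smaller cohorts (about 30 samples per archetype) the cover slices a
cloud into sparsely populated strips whose graph can disconnect, and
every disconnected fragment necessarily contributes an attractor — a
known limitation of Mapper at fixed resolution, documented here rather
than hidden: with few samples, expect spurious extra attractors.

Simulator invariants (occupancy bounds, zero-sum conservation,
symmetric-interaction neutrality, species exchangeability) are swept
over 100 seeds at small scale (3–8 species, 20–60 sites).  The
gamma-GLM machinery is validated against direct numerical maximisation
of the gamma likelihood (IRLS and the optimiser agree to 1e-4 on small
random designs), the deviance test holds its nominal 5 % level within
Monte-Carlo error over 1000 null replications at the study's design
size (n = 2025), and the AICc/weight computations reproduce the worked
example shown in the README to print precision.  One caveat is worth
stating plainly: under a pure connectivity effect the `Con` model
attains the strictly lowest AICc in only about three quarters of
replications, not more — the superset models overfit past it with
probability ≈ P(χ²₁ > 2), an intrinsic property of AIC-type selection
rather than of this implementation.

## Reproducibility

Every stochastic entry point takes an explicit seed; workflows write
their resolved configuration (`config.txt`), logs and all intermediate
tables next to their outputs, so a run directory is self-describing and
reruns are byte-identical.  Determinism of the compiled simulator is
guaranteed by routing all randomness through R's generator.
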