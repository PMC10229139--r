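---
title: "Inferring causal gene networks from single-cell data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring causal gene networks from single-cell data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccausal)
```

## Overview

Correlation networks built from scRNA-seq data cannot distinguish causes
from effects. Constraint-based causal discovery can: it infers a completed
partially directed acyclic graph (CPDAG) over a gene set by testing
conditional independence (CI) between genes, exploiting the fact that a
causal structure leaves a characteristic pattern of conditional
independencies in observational data. `sccausal` implements this workflow
end to end for dense gene-by-cell expression matrices:

1. **Preprocessing** — loading (CSV/TSV/MTX), `log2(x+1)` or per-gene
   z-score transforms, per-gene attributes (mean, detection rate, variance,
   fold change vs an optional control), conjunctive threshold filtering, and
   cell sub-sampling.
2. **Feature selection** — reducing the filtered candidates to a panel of
   ~50 genes most dependent on one or several response genes, by BAHSIC
   (backward elimination on the Hilbert-Schmidt Independence Criterion)
   and/or random-forest impurity importance.
3. **Causal discovery** — the order-independent PC algorithm (PC-stable)
   with a pluggable CI test, v-structure orientation, and Meek-rule
   propagation.
4. **Reliability** — consensus networks across tests or runs, structural
   Hamming distance (SHD) similarity, TPR against the consensus, edge
   stability across repeated runs, and spike-in separation QC.
5. **Benchmarking** — synthetic DAG/structural-equation data with
   scRNA-seq-style dropout and evaluation against the known truth.

## Conditional-independence tests

Each tester maps `(data, i, j, S)` to a statistic and a p-value for the
hypothesis that genes `i` and `j` are independent given the gene set `S`.

* **gauss** — partial correlation via correlation-matrix inversion and the
  Fisher z statistic `sqrt(n - |S| - 3) atanh(r)`. Exact under joint
  Gaussianity and fast, but blind to nonlinear dependence; a singular
  conditioning matrix triggers a regularized inverse and a warning flag.
* **hsic.gamma / hsic.perm** — the HSIC V-statistic
  `trace(KHLH)/n^2` with Gaussian kernels and median-heuristic bandwidths
  (at most 1000 seeded pairs enter the median; a zero median falls back to
  bandwidth 1). With `S` non-empty, each tested variable is first replaced
  by its residual from a kernel ridge regression on the `S` columns
  (Gaussian kernel, median-heuristic bandwidth, ridge `1e-3`): a
  deterministic residualization-based conditional test.
* **dcc.gamma / dcc.perm** — the squared sample distance covariance
  (double-centered Euclidean distance matrices) with the same
  conditioning scheme. Distance covariance is zero iff independence, like
  HSIC with a characteristic kernel.
* **rcit / rcot** — random-Fourier-feature approximations of the kernel
  conditional-independence test: tested variables (and `S`) are mapped to
  seeded random cosine features (defaults `f_xy = 5`, `f_z = 25`, the
  published defaults of the approximated method), `S`-features are partialed
  out by linear regression, and `n * ||cov||_F^2` of the residual features
  is referred to a Hall–Buckley–Eagleson weighted-chi-square null. RCoT
  residualizes both sides on `S`; RCIT builds the second variable's
  features on `(X_j, S)` — the published asymmetric scheme. With empty `S`
  the two coincide.

Both gamma variants fit a two-moment gamma to the permutation null of the
centered-matrix statistic: mean `tr(A)tr(B)/(n^2(n-1))` and the classical
HSIC gamma-test variance. For Gaussian kernels this is exactly the
standard HSIC gamma test; applying the same moments to centered distance
matrices gives the distance-covariance analogue. Negative variance
estimates are floored at `1e-12`; a degenerate fit falls back to the
permutation null with a warning. Permutation variants use `B = 100` by
default (minimum 19) and the add-one estimator
`p = (1 + #{perm >= obs})/(1 + B)`, so p-values are never zero. All
statistics are computed after per-column standardization, and every random
ingredient (permutations, Fourier features) derives deterministically from
the tester seed and the tested indices, making full PC runs reproducible.

Measured behaviour (recomputed by the test suite): under a linear-Gaussian
null with `|S| = 2` at `n = 300`, all seven tests hold their level at
`alpha = 0.05` within the exact binomial 99% band over 500 replicates; on
`y = x^2 + noise` all kernel-based tests reject in at least 90% of
replicates while the partial-correlation test does not.

One power limit worth knowing: with the default five Fourier features and
the median-heuristic bandwidth, rcit/rcot resolve smooth nonlinearities
(quadratics, `sin(2x)`) but lose power against high-frequency signals such
as `sin(4x)`, whose frequency lies several bandwidths outside the sampled
spectrum. Raising `f_xy` helps only marginally; the exact kernel tests
(hsic/dcc) are the robust choice when such dependence is plausible.

## PC-stable and orientation

The skeleton phase starts from the complete graph. At level `l` each
retained pair is tested against all size-`l` subsets of either endpoint's
neighborhood *frozen at the start of the level* (PC-stable), so the result
does not depend on variable order; the first test with `p > alpha` removes
the edge and records the separating set (smallest level, lexicographic
subset order — deterministic). For retained pairs the largest p-value seen
becomes the edge annotation, i.e. the weakest evidence that survived, and
edge thickness is `-log10(p)` (p floored at `1e-300`).

Orientation finds every unshielded triple `a - c - b` and orients
`a -> c <- b` when `c` is absent from the recorded separating set of
`(a, b)`, then applies Meek rules 1–4 to a fixpoint. Two safeguards keep
the output a valid CPDAG on noisy data: a pair demanded in both directions
by different v-structures stays undirected with a conflict flag
(conservative, order-independent), and any orientation that would close a
directed cycle is skipped. With a d-separation oracle as the tester, the
output equals the true CPDAG on random DAGs (verified exhaustively against
brute-force Markov-equivalence enumeration in the tests).

Four user parameters matter, mirroring the platform conventions this
workflow follows: `alpha` (default 0.1; larger keeps more edges), the
number of cells sampled (300 suggested for plate-based, 600 for
droplet-based data at ~50 genes), the sampling mode (seeded random or
first-n), and `max_cond_size` (default 3; deeper conditioning is slower
and, at small n, noisier).

Edge signs are assigned after inference: the Pearson correlation of the two
endpoint columns, `+1` (activation) if positive, `-1` (repression) if
negative, `0` if zero or undefined (constant column, with a warning).

## Consensus, similarity, and stability

Networks inferred with different CI tests (or repeated runs of a
permutation-based test) are compared by SHD: one count per adjacency
present in exactly one graph, one per shared adjacency whose mark differs
(undirected vs directed, or opposite direction) — a direction flip costs 1.
SHD maps to a similarity `exp(-d / (2 sigma^2))` with `sigma = 5`, so
distance 0 gives similarity 1 and distance 50 gives `exp(-1)`. The
consensus network is the intersection: an adjacency survives iff present in
every member, its direction iff unanimous, its sign iff unanimous. A
network's TPR against the consensus is `overlap / (overlap + specific)`
over adjacencies (an empty network is vacuously 1, with a warning).
Adjacency — not direction — is deliberately the unit of consensus
membership, TPR, and stability counting; direction disagreements demote to
undirected rather than discarding the interaction.

Where the member set of the consensus is chosen visually from a cluster
map in interactive use, `select_consensus_members()` provides a
reproducible stand-in: average-linkage hierarchical clustering on
`1 - similarity`, cut at a configurable height (default 0.5), keeping the
largest cluster. Explicit member labels always override it.

`edge_stability()` counts, for each adjacency in the union of `m` runs, how
many runs contain it, summarizing exact-`k` and at-least-`k` fractions of
the union. The exact-`k` fractions sum to 1 and the cumulative fractions
are non-increasing — both are asserted in the tests.

## Spike-in QC

`integrate_spike_in()` equalizes cell counts by seeded subsampling, pairs
spike-in cells to case cells by a seeded random permutation, prefixes
spike-in gene ids with `SPIKE_`, and stacks the blocks. Random pairing is a
deliberate choice: the two blocks come from unrelated sources, and random
pairing guarantees zero true cross-block dependence, so any inferred
cross edge estimates the false-positive behaviour of the chosen CI test on
this data. `spike_separation_report()` classifies edges as within-spike,
within-case, or crossing and flags separation when the crossing fraction is
at most 5% (configurable; no quantitative criterion is standard, so this
default is declared, not derived).

## Synthetic benchmark generator

`random_dag(p, expected_degree)` samples a random topological order and
includes each forward pair with probability `expected_degree/(p-1)` —
acyclic by construction, expected edge count `p * expected_degree / 2`.
Edge coefficients have magnitude uniform in `[0.5, 2]` with random sign,
bounding effects away from zero so that "present" edges are detectable in
principle. `simulate_sem()` generates in topological order: root nodes are
unit-variance Gaussian sources; every other node is the sum of parent
contributions (`w x` linear, or `w g(x)` with `g` drawn per edge from tanh,
square, sine) plus Gaussian noise with `noise_sd` (default 0.5). Columns
are standardized, matching the z-score form the inference stage expects.

Dropout is modeled as uniform Bernoulli zeroing at a configurable rate
(expression-dependent logistic zeroing is available but not the default) —
it emulates the *excess zeros* of scRNA-seq capture, not library-size
variation, batch effects, or counts' mean-variance relation. Passing
benchmarks on this generator therefore demonstrates tolerance to missing
values and nonlinearity, not robustness to everything real data can do.

Problem sizes in the packaged checks were chosen as the smallest that
exercise the claims meaningfully: CI-test calibration at `n = 300`,
`|S| = 2`, 500 replicates; recovery at `p = 10`, expected degree 2,
`n = 600`, 10 seeds (median adjacency F1 ≥ 0.7 without dropout, ≥ 0.5 at
30% dropout); oracle equivalence on 50 random DAGs of 3–5 nodes. The
acceptance script (`scripts/acceptance.R`) re-derives all headline numbers
from scratch at these sizes.

## Numerical and degenerate-input conventions

* z-scoring a constant gene yields all zeros; "expressed" always means
  strictly `> 0`; filter thresholds are strict inequalities; filter ties
  break lexicographically by gene id.
* Fold change is `log2((mean_case + 1)/(mean_ctrl + 1))` on the matrix as
  given — self-contained, monotone, and finite at zero counts. This is a
  declared convention (marker-based tools differ in pseudo-count and
  scale), so fold changes are comparable within a run, not across tools.
* BAHSIC removes `ceiling(0.1 * remaining)` genes per round, scoring each
  gene singly against the (possibly multivariate) response — for additive
  kernels this yields the same ranking as leave-one-out set HSIC at linear
  cost. Kernels and bandwidths are fixed per run, so rankings are
  deterministic; batch ties break by score, then gene id.
* The tree-based selector delegates to `ranger` with a fixed seed and one
  thread; importances of an all-constant candidate set tie at zero and
  fall back to lexicographic order.
* Permutation p-values are never zero (add-one estimator); gamma fits are
  floored and fall back to permutation when degenerate; `atanh(r)` is
  clamped away from `|r| = 1`.

## Known limitations

* Kernel CI tests cost `O(n^2)` memory and `O(n^2)`–`O(n^3)` time per test;
  beyond a few dozen genes or a few thousand cells, use rcit/rcot or
  sub-sample cells.
* Constraint-based discovery assumes causal sufficiency; gene panels from
  feature selection virtually always exclude relevant variables, so edges
  are best read as (possibly indirect) causal relationships.
* Members of a Markov equivalence class are indistinguishable: many edges
  legitimately stay undirected.
* The conservative conflict policy (undirected + flag) trades orientation
  recall for stability under sampling noise.
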