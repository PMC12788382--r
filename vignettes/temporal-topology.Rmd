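---
title: "Topology-assisted temporal clustering of dynamic connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-assisted temporal clustering of dynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempoph)
```

## The problem

Sliding-window dynamic functional connectivity (dFC) analyses describe the
resting brain as moving between a handful of recurring connectivity states.
The number of states recovered by clustering, however, depends strongly on
the acquisition's sampling period (TR): the same subject scanned at
TR = 645, 1400 and 2500 ms yields time series of very different lengths and
noise characters, and conventional pipelines often report different state
counts for each. `tempoph` addresses this by clustering *topological
signatures* of the per-timepoint networks rather than the networks
themselves, on the premise that 0-dimensional persistent homology summarizes
a network's connectivity structure in a way that is stable across sampling
rates.

## The pipeline, stage by stage

### From signals to networks

`sliding_window_pearson()` assigns one FCN to every timepoint `t`: the
pairwise Pearson correlation of the ROI signals over a *trailing* window
ending at `t`. A trailing (rather than centered) window avoids using future
samples and keeps exactly `T` outputs; near the series start the window is
truncated. Pairs that are constant within a window get correlation 0 and a
`degenerate` flag — never `NaN`, so downstream stages need no missing-value
handling.

The window width can be fixed (the default in all tests, for determinism) or
chosen per timepoint by `adf_window_width()`: walking a doubling ladder from
`min_w` (default 20 samples) and accepting the first width at which at least
90% of the (non-degenerate) ROI series reject the augmented Dickey-Fuller
unit-root null at level `alpha = 0.05`. No installed package provides the
ADF test, so the package implements it directly: the regression of
`diff(y)` on an intercept, the lagged level and AIC-selected lagged
differences (lag order 0..Schwert bound, selected on a common trimmed
sample, then refit on the full window), with MacKinnon finite-sample
critical values for the constant/no-trend case. Note that the joint
90%-of-ROIs rule is demanding at 20-sample windows: the per-series power of
any ADF variant at `n = 20` is well below 1, so even pure white noise
selects the smallest width only for a majority — not the near-totality —
of timepoints. If no width qualifies the maximum is returned with a
`flagged` attribute.

### From correlations to filtration distances

`correlation_to_distance()` supports two strictly decreasing maps from
correlation to distance, both sending 1 to 0 and -1 to 1:

* `sqrt_half` (default): `d = sqrt((1 - r) / 2)`. This is the chord
  distance between the standardized signals (`d^2 = ||z_p - z_q||^2 / (2T)`),
  hence a true metric — the natural choice for a Vietoris–Rips filtration.
* `half`: `d = (1 - r) / 2`, the same quantity without the square root.

The two are related by a strictly monotone map (`half = sqrt_half^2`), so
the *order* of H0 merge events — which edges enter the minimum spanning
tree, and in which sequence — is identical under both; only the numeric
scale of deaths and Wasserstein distances changes. The choice is an explicit
argument, never silent.

### H0 persistent homology as a minimum spanning tree

For a finite metric the 0-dimensional persistence barcode of the
Vietoris–Rips filtration has a closed combinatorial form: every vertex is
born at filtration value 0, each merge of two connected components happens
exactly at the weight of a minimum-spanning-tree edge, and one component
survives forever. `compute_h0_diagram()` therefore runs Kruskal's algorithm
with union–find — exact, `O(R^2 log R)`, no general boundary-matrix
reduction — returning `R` intervals with the `R - 1` finite deaths sorted
ascending. Ties between equal edge weights are broken by lexicographic edge
index; the death *multiset* (all the package ever uses downstream) is
tie-invariant. The test suite checks the deaths against an independent
Prim's-algorithm oracle on hundreds of random matrices, exactly.

### Exact Wasserstein distances

`wasserstein_distance()` computes the exact q-Wasserstein distance between
diagrams (default `q = 1`, internal norm L-infinity — the conventions of the
common TDA libraries; both configurable since reasonable analyses may want
`q = 2`/L2). Partial matching is reduced to a square assignment problem:
each point of one diagram may match a point of the other or a "ghost"
standing for its diagonal projection. The ghost blocks are row- or
column-constant, which keeps every cost finite, and the assignment is solved
by an `O(n^3)` Hungarian algorithm in C++. A brute-force enumeration over
all partial matchings serves as the test oracle, and metric axioms
(symmetry, identity of indiscernibles on finite parts, triangle inequality)
are property-tested on random diagrams.

H0 diagrams always carry exactly one infinite bar, which is removed before
matching by default: with equal birth values the pair would contribute 0
anyway, and exclusion keeps all distances finite under every convention.
With `finite_only = FALSE` infinite bars are matched by absolute birth
difference, and diagrams with different infinite-bar counts are at distance
`Inf`.

`pairwise_wd_matrix()` computes only the upper triangle of the `T x T`
temporal distance matrix and mirrors it; the all-pairs loop runs in C++.

### Embedding and cluster-count selection

`mds_embed()` performs metric least-squares MDS by SMACOF stress
majorization, initialized from the classical-MDS (Torgerson) configuration.
The deterministic start matters: with random initializations the chosen
cluster count would vary across runs, confounding exactly the cross-rate
comparison the pipeline exists for. Iterations stop when the relative
stress change falls below `1e-12` or after 300 iterations; the reported
stress is normalized stress-1. Zero distances in the current configuration
contribute 0 to the Guttman transform (the standard convention).

`select_k()` runs k-means (`stats::kmeans`, Hartigan–Wong) for every
`k` in 2..16 with 10 restarts of `iter.max = 300`, initial centers drawn
from the *distinct* rows (so duplicated points — common in noise-free
synthetic data — cannot crash the initialization), each `k` on its own
deterministic seed substream. The mean silhouette
`(b - a) / max(a, b)` selects `k`; ties break toward the smaller `k`
(conservative and reproducible). Conventions fixed by the implementation
and its tests: lone points of singleton clusters contribute 0; an all-zero
`0/0` ratio counts as 0; a single admissible cluster or fully identical
points are signaled as degenerate-input errors rather than silently
clustered. Candidates exceeding `T - 1` (short cohorts) are dropped with a
warning; candidates exceeding the number of distinct points are skipped.
`silhouette_mean()` is cross-checked against `cluster::silhouette` in the
tests.

### Baselines and consistency statistics

The three comparison pipelines reuse the same machinery so only the
representation differs: `direct_cluster()` feeds the raw `T x R^2`
flattened matrices (full matrix, row-major, including the diagonal — for
`R = 113` the familiar 12,769-length vectors) straight to `select_k()`;
`pca_cluster()` inserts a 2-component PCA (column-centered SVD with a
deterministic sign convention); `traditional_cluster()` replaces the
Wasserstein matrix by the entrywise (Frobenius) Euclidean distance between
FCNs — provably identical to the Euclidean distance between flattened rows,
a cross-module identity the tests assert — followed by the same MDS and
selection. Flattened features are not rescaled (column centering only, and
only for PCA).

`cohort_distance()` is the sum of the three absolute pairwise differences
of a subject's cluster counts, identically `2 * (max - min)` and identically
the sum of the three pairwise distances — both identities are asserted
exhaustively over all count triples in `[1, 16]^3`. Study summaries report
percentages within ≤ 1 (cohort-wide) and ≤ 2 (pairwise), rounded half-even
to one decimal, and cluster-count histograms over the fixed axis `k = 1..16`
(selection starts at 2, so the `k = 1` bin stays empty under defaults).

## The synthetic generator

`simulate_fcn_sequence()` emulates the multi-rate study design: one latent
continuous-time Markov trajectory per subject — exponential dwell times
(memoryless, the simplest law consistent with "oscillating between discrete
states"), uniform jumps to a different state — sampled at each TR in
`tr_list`, so all cohorts of a subject are downsampled views of the same
state sequence and ground truth is shared across rates.

State correlation matrices come from a low-rank factor model
`W_k = sqrt(1 - s) W_0 + sqrt(s) Z_k` (shared component `W_0`, rank
`max(2, R/4)`), so between-state Frobenius distances grow with the
separation `s`. Crucially, states also differ in a global coupling gain:
H0 is permutation-invariant, so states that differ only in *which* regions
correlate have nearly exchangeable death multisets and are close to
invisible to a topological summary. Real resting-state states differ in
overall integration vs segregation, and the generator reproduces that
contrast, spacing the state connectivity levels evenly on the filtration
distance scale `d = sqrt((1 - rho) / 2)` (spread proportional to `s`, all
levels collapsing as `s -> 0`) so that neighboring states are equally
distinct. The factor Gram matrix plus a `0.5 r` ridge is rescaled to a
correlation matrix, positive definite by construction.

Per-timepoint FCNs are the active state's matrix plus symmetric Gaussian
noise (`noise_sigma`), repaired to a valid correlation matrix: symmetrize,
unit diagonal, eigenvalue clipping at zero, diagonal renormalization, clip
to `[-1, 1]`. The order matters (renormalizing before clipping eigenvalues
would destroy positive semidefiniteness); on an already-valid matrix the
repair is an identity up to round-off, and with `noise_sigma = 0` the state
matrix is emitted bit-exactly. `simulate_roi_timeseries()` instead draws
per-timepoint multivariate normal observations with the active state's
correlation as covariance, for exercising the windowed-correlation front
end.

Defaults mirror the scaled study design used throughout the tests:
`R = 20` regions, `K = 3` states, cohorts at TR = 645/1400/2500 ms over a
215 s trajectory (333/153/86 timepoints), mean dwell 20 s, noise 0.05,
separation 0.8. One seed drives a study; subjects, cohorts, noise streams
and per-k k-means restarts each use deterministic substreams
(`seed_substream()`, a polynomial string hash modulo `2^31 - 1`), so any
subset of a study reproduces the full run's values.

What the generator does *not* emulate: hemodynamic response convolution,
physiological noise spectra, scanner drift, head motion, and
parcellation/registration error. Passing recovery tests on this generator
therefore demonstrates that the pipeline's stages compose correctly and
that topological summaries transfer the planted state structure across
sampling rates — not that real multi-site fMRI will show the same effect
sizes.

## Problem sizes and determinism

The packaged studies are deliberately scaled down from a full imaging
cohort: 10 subjects at `R = 20` regions keep the complete three-cohort TDA
study (including the ~333x333 pairwise Wasserstein matrix per subject's
fastest cohort) around a minute, which makes the full parameter-recovery
experiment runnable inside the test suite. All writers emit deterministic
bytes (fixed key order, 17 significant digits, `inf` token for infinite
deaths, 0-based indices on disk), and two runs of the same seeded study
produce byte-identical results files — asserted in the tests.

## Known limitations

* The 0-dimensional summary discards which regions merge; states
  distinguished purely by connectivity *pattern* at identical overall level
  are provably hard for this pipeline (the generator's gain contrast exists
  precisely because of this).
* Silhouette selection inherits its known granularity bias: when
  between-state separations are very uneven, merging the two closest states
  can out-score the true partition.
* The MAT-file dialect common in preprocessing environments is not read;
  stacks are exchanged as delimited text (per-timepoint files or a single
  header-prefixed archive).
* The ADF-adaptive window implements a reasonable ladder rule; the exact
  adaptive-window rule used by any particular preprocessing code base may
  differ, so fixed windows are recommended where reproducibility across
  tools matters.
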