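# tempoph

Topology-assisted temporal clustering of dynamic functional connectivity
networks (dFCN).

Resting-state fMRI is acquired at very different sampling periods (TR) across
sites and protocols — e.g. 645, 1400 and 2500 ms — and the apparent number of
temporal "brain states" recovered by sliding-window connectivity analyses is
notoriously sensitive to that choice. `tempoph` implements a pipeline that
summarizes each per-timepoint functional connectivity network (FCN) by a
topological signature that is largely invariant to the sampling rate, so the
number of recurring connectivity states can be compared across cohorts
acquired at different TRs. It is aimed at neuroimaging methodologists working
on dynamic functional connectivity and multi-site/multi-protocol
harmonization.

## Method

For each subject and cohort, a sequence of `T` symmetric `R x R` correlation
matrices (one FCN per timepoint, from sliding-window Pearson correlation with
an optional stationarity-adaptive window driven by the augmented
Dickey-Fuller test) is processed as follows:

1. **Correlation to distance.** Each FCN is mapped to a filtration distance
   matrix, by default `d_ij = sqrt((1 - r_ij) / 2)` — the chord distance of
   standardized signals, a true metric; `d = (1 - r)/2` is available as an
   alternative. Perfect correlation maps to distance 0, perfect
   anticorrelation to 1.
2. **0-dimensional persistent homology.** The Vietoris–Rips filtration of
   each distance matrix yields an H0 persistence diagram: all `R` components
   are born at filtration value 0, and the `R - 1` finite deaths are exactly
   the minimum-spanning-tree edge weights of the weighted complete graph
   (computed by Kruskal with union–find; one bar is infinite).
3. **Wasserstein geometry of time.** The q-Wasserstein distance
   `W_q(A, B) = min over partial matchings (sum of cost^q)^(1/q)` (default
   `q = 1`, L-infinity internal norm, unmatched points paying transport to
   the diagonal) is solved exactly as an assignment problem for every pair
   of timepoints, giving a `T x T` temporal distance matrix per
   subject-cohort.
4. **Embedding and state counting.** The temporal matrix is embedded in 2-D
   by metric MDS (SMACOF stress majorization from a deterministic
   classical-MDS start) and the number of temporal clusters `k` is chosen by
   silhouette-maximizing k-means over `k = 2..16`.
5. **Cross-rate consistency.** For each subject the cohort-wide distance
   `|k_2500 - k_1400| + |k_1400 - k_645| + |k_645 - k_2500|` and the
   pairwise distances `|k_a - k_b|` quantify agreement of the state count
   across sampling rates; study-level summaries report the percentage of
   subjects within thresholds (≤ 1 cohort-wide, ≤ 2 pairwise) and the
   cluster-count distribution per cohort.

Three non-topological baselines (direct k-means on flattened FCNs, PCA-to-2D
clustering, and Frobenius-distance dFCN clustering through MDS) share the
same embedding/selection machinery so only the representation differs.

A built-in synthetic generator produces ground-truthed multi-rate studies:
each subject has one latent continuous-time Markov trajectory over `K`
planted connectivity states (factor-model correlation matrices whose
coupling levels are spaced on the filtration-distance scale), sampled at
each TR, with entrywise noise and PSD repair.

## Worked example

Simulate one subject at three sampling rates from a single latent two-state
trajectory, run the TDA pipeline on each cohort, and compare state counts:

```r
library(tempoph)

cfg <- synthetic_config(n_regions = 12, n_states = 2,
                        tr_list = c(645, 1400, 2500),
                        total_duration = 120, mean_dwell = 15, seed = 42)
sim <- simulate_fcn_sequence(cfg)
sapply(sim$cohorts, function(f) dim(f$matrices)[1])
#>  tr645 tr1400 tr2500
#>    186     85     48

res <- lapply(sim$cohorts, run_tda_subject, seed = 42)
sapply(res, `[[`, "chosen_k")
#>  tr645 tr1400 tr2500
#>      2      2      2

cohort_distance(sapply(res, `[[`, "chosen_k"))
#> [1] 0

round(res$tr2500$silhouette_by_k[1:5], 3)
#>     2     3     4     5     6
#> 0.928 0.591 0.573 0.569 0.353
```

All three cohorts — 186, 85 and 48 timepoints of the same 120-second
trajectory — recover the planted two states (silhouette peaks sharply at
`k = 2`), and the cohort-wide distance of 0 says the state count is
invariant to the sampling rate for this subject.

A command-line front-end wrapping the same functions lives at
`inst/cli/tempoph.R` (`simulate`, `fcn`, `tda`, `baseline`, `stats`, `run`
subcommands).

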