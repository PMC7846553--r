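---
title: "Methods: models, calibration and design choices in coexdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in coexdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

`coexdiff` analyzes a probes × samples matrix of normalized, continuous
expression values split into two groups of samples (reference group
first; in the motivating parity study, 42 nulliparous and 71 parous
women). This vignette documents the statistical models behind each
stage, the parameters a user may want to move, what the synthetic
generator does and does not emulate, and the design decisions taken
where a published description leaves the procedure under-determined.

## Gene-by-gene criteria

### Mean expression (ME)

Per probe, the two group means are compared with a Welch two-sample
t-test (two-sided, unequal variances), and p-values are adjusted across
probes with the Benjamini–Hochberg step-up procedure
(`stats::p.adjust`, exposed as `bh_adjust()`). The direction convention
everywhere in the package is *group 2 relative to group 1*: "up" means
the second group's value is larger. Probes with zero variance in both
groups are untestable; they are flagged `degenerate`, excluded from
testing, and reported.

### CDF area (CD)

The area under a probe's empirical CDF is computed by exact step
summation over a common support. Because `∫ F̂ = upper − mean` for data
inside the bounds, the CD *difference* under a shared support is
exactly the negated mean difference — CD's added value over ME lies in
its accompanying distribution tests, not in the area difference itself
(the test suite asserts this collinearity explicitly). Distributional
change is tested with two-sided Kolmogorov–Smirnov and Wilcoxon
rank-sum tests; ties are handled by midranks with a normal
approximation. Both raw and BH-adjusted p-values are reported because
FDR calibration for these rank/sup-norm tests is less settled than for
the t-test; the significance flag used by downstream displays is the
raw-p flag, with the adjusted flag alongside.

Integration bounds are the probe's pooled min/max across both groups.
A common support is required for comparability and mirrors the entropy
grid; this is a package convention, since any bounded support yields a
valid area.

### Shannon entropy (SE)

Each probe's pooled range is divided into `n_bins` equal-width bins
(default 10, configurable — results depend on it, and with 42–71
observations per group ten bins keeps expected bin counts in a usable
range). Entropy is `−Σ f log₂ f` in bits, bounded by `log₂ n_bins`.
Per group, `n_boot` (default 1000) with-replacement resamples of the
group's samples give a bootstrap distribution of the group's entropy;
the package draws the resampled *bin counts* directly from
`Multinomial(n, f̂)`, which is exactly equivalent to resampling the
series and re-binning, and orders of magnitude faster.

Testing the entropy difference is the one place where a literal
reading of the source procedure fails its own purpose. A Welch t-test
*between the two collections of bootstrap entropies* treats resamples
as independent observations: its standard error shrinks with
`1/√n_boot` while the true uncertainty of each group's entropy does
not, and on two independent same-distribution samples we measure a
null rejection rate near 0.95 at the study's group sizes. (If the two
groups share literally the same data values the collection t-test is
calibrated — but that is not the relevant null.) The package therefore
defaults to an **exact permutation test** of the plug-in entropy
difference under group-label exchange, implemented as multivariate
hypergeometric draws from the pooled bin counts (500 permutations by
default); measured null rejection at α = 0.05 is ≈ 0.05. Two
alternatives are kept behind `method=`: `"boot-z"`, a bootstrap
bias-corrected z-test using the bootstrap variances (measured null
rate ≈ 0.066), and `"collection"`, the literal collection t-test, for
comparability.

### Criterion cross-correlations and profiles

`criteria_correlations()` reports Pearson correlations between the
per-probe *relative* changes (group2/group1) of the three criteria;
probes with a zero reference value are excluded. `relative_profile()`
produces the ordered relative-value curve per criterion (reference
group at the horizontal line 1), carrying the significance mask.
`hierarchical_order()` supports the heatmap views: Euclidean distance,
complete linkage, optional row z-scoring (zero-variance rows are left
raw with a warning). Merge ties are resolved by `stats::hclust`'s
deterministic ordering; the tests exercise tie-free fixtures against a
direct O(n³) agglomeration oracle.

## Power and critical values

`t_test_power()` gives Welch power via the noncentral t with
Welch–Satterthwaite degrees of freedom; `power_coverage()` applies it
probe-wise for a relative detectable difference (e.g. 10% of the
reference mean at 90% power). `wilcoxon_power_sim()` estimates
rank-sum power by Monte Carlo, the standard route for that test.

`correlation_critical_value()` returns the smallest correlation
magnitude detectable by a Fisher-z test of zero correlation:
`ρ* = tanh((z_α + z_power)/√(n−3))`. With α = 0.05 **one-sided** and
power 0.8 this reproduces the motivating study's printed ±0.29 (n = 71)
and ±0.37 (n = 42) critical values to within a unit in the second
decimal; a two-sided reading does not, so one-sided is the default for
this operation and the choice is documented here. The `√n` denominator
variant differs only in the third decimal and is available via
`denom = "n"`.

## Correlation-bin networks and graph summaries

Pearson product-moment correlation is used for all probe pairs (the
motivating text's "Pearson's rank correlations" is read as
product-moment, consistent with its later use of Pearson's ρ and with
the critical-value computation; Spearman is available behind
`method = "spearman"`). Pairs are assigned to nine 0.2-step bins;
positive bins are right-closed, negative bins left-closed, the central
`[-0.2, 0.2]` bin closed on both ends, so ρ = ±1 falls in the extreme
bins and every pair lands in exactly one bin. Networks contain only
nodes with at least one in-bin edge, matching a pair-count (not
node-count) summary table.

`graph_summary()` reports seven parameters. Numerical conventions:

* Path length and diameter use unweighted breadth-first shortest
  paths; on a disconnected network they are computed on the largest
  connected component and flagged (`lcc_used`), since they are
  otherwise infinite.
* The clustering coefficient is the unweighted local coefficient
  averaged over all nodes, with degree < 2 nodes contributing 0.
* Modularity is maximized on absolute edge weights at resolution 1.
  Greedy Louvain optimization is seed-dependent and can miss the
  optimum even on tiny graphs, so the default (`"auto"`) uses exact
  maximization (`igraph::cluster_optimal`) for graphs of at most 15
  nodes and Louvain (best of `n_restarts = 5` restarts) above — exact
  where feasible, heuristic at scale. The partition is returned
  alongside Q.
* Eigenvector centrality uses absolute weights; a single number per
  network is produced by max-normalizing the leading vector and
  averaging over nodes. Whether a published per-network centrality is
  a mean, median or maximum is generally not stated; the mean of the
  max-normalized vector is this package's explicit convention.

`subsample_metric_test()` compares one metric between two networks by
recomputing it on 100 induced subgraphs of 90% of each network's nodes
and applying a two-sample Student t-test. Integration metrics and the
raw link count are not offered for subsampling (path lengths are
systematically biased by node deletion and the link count scales with
the sample), leaving degree, clustering, modularity and eigenvector
centrality; modularity inside the subsampling always uses Louvain so
that the two distributions are produced by one estimator.

`differential_edges()` applies the Fisher r-to-z two-sided test to
every pair and builds one significant-edge network per requested α,
with node degree and Louvain community attributes attached for
size/color-coded export. Pairs with |r| = 1 have an infinite transform
and are excluded with a report.
`changed_corr_stable_mean_pairs()` combines the edge test with
per-probe Welch mean-stability (raw p ≥ α for both members) on a random
probe subsample (default 3,000) and extrapolates the count by the
total-to-sampled pair ratio. `correlation_difference_pdf()` reports
kernel densities, standard deviations and the cross-group covariance;
`Var(Δρ) = Var₁ + Var₂ − 2 Cov` holds exactly and the compactness of
the difference distribution relative to `√(Var₁+Var₂)` measures how
strongly the two correlation structures are coupled.

## The differential regression screen

Seed pairs are classified A–D by the threshold rules
(`ρ₂ > 0.8 & ρ₁ < 0.4` → A, and the sign/group mirrors), with a
conjunctive `|Δρ| > 0.4` filter. The raw inequalities can overlap for
the rare pair that is strongly correlated in both groups with opposite
signs; classes are made mutually exclusive by first-match precedence
A > B > C > D. For each sampled seed pair the first probe is the
regressand, the second the first regressor, a sampled third probe the
second regressor, and the final regressor sweeps all remaining probes;
per-group R² for the sweep is computed in one residualized pass rather
than per-fit `lm` calls. A fit is kept when all four conditions hold:

1. R² in `[0.8, 1)` in one group and `[0, 0.4]` in the other (interval
   ends taken literally from the transition description, boundary
   inclusion as written here);
2. at least one of the four probes mean-stable (Welch raw p ≥ α);
3. the four probes do **not** all lie in one connected component of
   the `|ρ| > 0.8` network of the strong-R² group ("network" here
   means high-correlation network, as elsewhere in the analysis);
4. the six pairwise correlation changes among the four probes do
   **not** all share one sign while all exceeding 0.4 in magnitude —
   this operationalizes "not all homogeneously modify their
   correlations", which has no published formal definition; the 0.4
   threshold reuses the screen's own change threshold and the
   predicate is isolated so it can be replaced.

Rank-deficient designs (collinear regressors) are flagged degenerate
and excluded. `extrapolate_relation_counts()` scales a screened count
by the examined-to-total ratio.

## The synthetic generator as study conditions

`synthetic_config()` defaults encode the study conditions used
throughout the tests: group sizes 42/71; Gaussian background at mean 8,
SD 1 on a log₂-like intensity scale (normalized microarray intensities
are near-Gaussian — in the motivating data 99.9% of series passed a
Shapiro screen, which also motivates Gaussian background for the
normality-screen calibration test); 100 mean-shift probes at 1.0 SD
with 68% shifted up (matching the ~2.17 up/down regulation ratio);
100 shape-shift probes with group-2 variance ×9 (a 3-fold SD change —
the scale at which the KS test has usable power at these group sizes;
a 3-fold *variance* change gives KS power ≈ 0.25 and would be a
mis-specified planted effect); 100 entropy-shift probes with an
equal-mean uniform distribution of 3 SD half-spread in group 2, so
discretized entropy moves while the mean does not; two 10-probe
modules with within-module correlation 0.9 in group 2 and 0 in
group 1, generated by a per-module per-group latent factor with
loading `a = √(ρ/(1−ρ))` (so the expected pairwise correlation equals
the configured ρ exactly); and ten 4-probe relations
`p₁ = p₂ + p₃ + p₄ + ε` with the first regressor on a 4×SD scale and
noise SD 40 (group 1) / 0.8 (group 2), giving population R² ≈ 0.011
vs ≈ 0.966 and a class-A seed pair (ρ₂ ≈ 0.93, ρ₁ ≈ 0.10) with wide
margins to the classification thresholds.

One global seed drives an independent substream per block, so adding
or resizing one block leaves the other blocks' draws untouched.

The generator emulates the statistical structure each stage assumes —
and nothing else. It does not simulate probe-level microarray
artifacts, batch effects, missing values, heavy-tailed intensity
noise, or the diffuse weak correlation background of real
transcriptomes. Passing recovery tests therefore demonstrates that the
pipeline detects the effects it models at the stated sizes, not that
those effect sizes are what a given real dataset contains.

## Problem sizes and runtime

All-pairs stages are quadratic in the probe count; `run_pipeline()`
refuses inputs above `max_probes = 5000` unless the cap is raised
explicitly. A full-array run (≈ 1.7 × 10⁸ pairs) is supported in
principle but memory- and time-heavy; the screen and the
changed-correlation count are designed to run on probe subsamples with
extrapolation for exactly that reason. The test suite exercises the
pipeline at 2,000 probes with the 42/71 group design (the calibration
checks use 2,000 null probes, 10,000 disjoint null pairs for the
Fisher-z size, and 500 replicates for the BH false-discovery
proportion), sizes chosen to make Monte-Carlo bands tight enough to be
meaningful while keeping a full run in minutes on one core.

## Interfaces

The package is driven from R: `run_pipeline()` orchestrates the stages
and returns a classed result with `print`/`summary`/`plot` methods,
every stage is exported individually, and tabular/graph outputs are
written as TSV and GraphML (plus edge-list TSV) when an output
directory is supplied — formats chosen so external tools (e.g. Gephi
for force-directed layout, which this package deliberately does not
implement) can consume them. A coefficient/prediction interface is not
meaningful for this kind of multi-stage analysis object and is
deliberately absent.

## Known limitations

* KS/Wilcoxon FDR behavior is reported both raw and adjusted, but no
  claim is made that BH controls FDR for the sup-norm statistic's
  discreteness at these sample sizes.
* The collection-t variant of the SE test is anticonservative by
  construction and is included only for comparison with analyses that
  used it.
* Louvain modularity above the exact-optimization size cap is a lower
  bound on the true maximum; Q values on large networks inherit the
  optimizer's seed dependence (mitigated by restarts, reported with
  the partition).
* The screen's extrapolations assume the sampled seed pairs and third
  probes are representative; they are point estimates without
  uncertainty intervals.
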