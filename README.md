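# tfcombo

Combinatorial transcription-factor (TF) enrichment analysis for binary
differential-expression profiles overlaid on a regulatory network.

## The problem

Given a universe of measured genes, a subset called differentially
expressed (DE), and a background map from TFs to their direct target
genes, the routine question is which regulators were perturbed. Standard
tools test each TF separately: a one-sided Fisher exact test on the 2x2
table cross-classifying genes by *targeted* and *DE*, Bonferroni-corrected
over the tested TFs. When several regulators act at once this per-TF view
is biased — small regulons fail to reach significance individually while
high-degree regulators and co-targeting TFs over-occur.

tfcombo instead searches over *subsets* of TFs for the combination whose
**union** of target sets best separates DE from unaltered genes. The
objective is the one-sided Fisher tail of the union,

    f(S) = log10 P( X >= a ),   X ~ Hypergeometric(M, a + c, a + b),

evaluated for the union's contingency table and carried in log10 space
end-to-end (optimal combined p-values routinely underflow doubles). The
2^N space over the N TFs that target at least one DE gene is explored by:

* greedy heuristics — `method_a()` (rank-order, O(N)), `method_b()`
  (set-cover style on uncovered genes, O(N^2)), `method_c()` (candidate
  scored by the combined p of solution + candidate, O(N^2); the
  recommended method);
* `exhaustive_search()` — the exact oracle for N <= 20–25;
* `steepest_descent()`, `local_minima_census()`,
  `random_walk_autocorrelation()` — landscape/ruggedness diagnostics;
* `simulated_annealing()` — stochastic search with a calibrated geometric
  cooling schedule, used as an independent estimate of the global minimum.

Significance of the winning combination is calibrated by
`randomized_null()`: the DE label is redistributed uniformly over network
genes, the search re-run, and the observed log10 p standardized as a
z-score against that null (with a K-S normality diagnostic).

A simulation benchmark (`synthetic_network()`, `generate_trial()`,
`run_benchmark()`) measures how much better the combinatorial search
recovers a known perturbed TF set than the per-TF test, via occurrence
RMSE, paired recovery accuracy and Wilcoxon signed-rank comparison.

## Worked example

```r
library(tfcombo)

net   <- synthetic_network(40, 300, degree_exponent = 1.5, min_degree = 2,
                           max_degree = 60, seed = 1)
trial <- generate_trial(net, k_min = 4, k_max = 8, noise_rate = 0.05,
                        seed = 2)

glance(default_enrichment(net, trial$profile))
#> # A tibble: 1 x 5
#>   n_tested     m alpha n_significant min_log10_p
#> 1       33    33  0.05             6       -9.58

method_c(net, trial$profile)
#> <tf_solution> method c: 8 TF(s), log10 p = -47.7626 (N = 33)
#>   tf006, tf035, tf029, tf017, tf039, tf015, tf008, tf032

trial$input_tfs
#> [1] "tf006" "tf008" "tf015" "tf017" "tf029" "tf032" "tf035" "tf039"

glance(randomized_null(net, trial$profile, reps = 100, seed = 3))
#> # A tibble: 1 x 7
#>    reps  mean    sd ks_statistic  ks_p observed_log10_p z_observed
#> 1   100 -4.58  1.33       0.0961 0.314            -47.8      -32.5
```

Eight TFs were perturbed; even at 5% label noise the per-TF test finds
only 6 of them significant, while the combinatorial search returns exactly
the 8 perturbed TFs with a combined log10 p of −47.8 — 32.5 null standard
deviations below what randomly relabelled profiles achieve (null mean
−4.6), so the profile is strongly consistent with the network.

## Command line

A thin wrapper over the same functions ships in `inst/scripts/tfcombo`:

```sh
tfcombo enrich    --network net.tsv --universe universe.txt --de de.txt --outdir out
tfcombo search    --network net.tsv --universe u.txt --de de.txt --method a,b,c,sa --seed 1
tfcombo nullz     --network net.tsv --expression expr.tsv --condition c12 --reps 1000
tfcombo benchmark --synthetic --trials 1000 --noise 0.05 --seed 7
```

Networks are read either as RegulonDB-style `network_tf_gene` TSV or as a
generic two-column edge list; DE profiles come from gene-list files or
from an expression matrix via gene-wise z-scores (`|z| > 2` against each
gene's own mean/sd across all conditions). Exit codes: 0 success, 1 I/O or
parse failure, 2 empty-result conditions.

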