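---
title: "Combinatorial transcription-factor enrichment: model, search and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial transcription-factor enrichment: model, search and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcombo)
```

## The inference problem

A differential-expression experiment reduces, after thresholding, to a
binary profile: a universe of $M$ measured genes of which $n$ are called
differentially expressed (DE). Overlaying this profile on a background
regulatory network (a map from each transcription factor to its direct
target genes) raises the question: *which regulators were perturbed?*

The standard ("default") answer tests each TF separately. For a TF whose
target set overlaps the universe in $a + b$ genes, with $a$ of them DE, the
one-sided Fisher exact test gives the probability that an overlap at least
as large arises when DE labels are distributed at random:

$$
P = \sum_{x \ge a} \frac{\binom{a+c}{x}\binom{b+d}{(a+b)-x}}{\binom{M}{a+b}},
$$

where $c$ counts DE genes not targeted and $d$ the remainder. P-values are
Bonferroni-corrected over the $m$ TFs with non-zero DE overlap.

When several regulators are perturbed at once this per-TF test is biased:
a small regulon can be individually non-significant even though its
targets are jointly explained by the perturbation, while large regulons
and co-targeting TFs can reach significance spuriously. tfcombo therefore
scores *subsets* $S$ of TFs by the same Fisher tail applied to the
**union** of their target sets,

$$
f(S) = \log_{10} P\big(\textstyle\bigcup_{t \in S} \mathrm{targets}(t)\big),
$$

and seeks the subset minimizing $f$. The objective is raw (uncorrected):
the search compares configurations of one expanding hypothesis rather than
testing many separate hypotheses, and significance of the winner is
calibrated afterwards by randomization (below).

Two representation choices matter numerically:

* **Everything stays in log10 space.** Optimal combined p-values on real
  profiles reach $10^{-40}$ and far below, outside linear double range.
  The tail is summed in log space (log-sum-exp over the log pmf), never by
  exponentiating terms first.
* **The universe is the full measured gene set by default.** A DE gene
  absent from the network stays in the universe (it contributes to the
  $c/d$ cells); a `universe_mode = "network"` style restriction is
  available when the analysis should be conditioned on network genes only,
  as in the simulation trials. Identifiers are lower-cased before matching
  (network databases and array annotations disagree on case); this can be
  switched off.

## Searching $2^N$ combinations

Only the $N$ "relevant" TFs — those targeting at least one DE gene — can
affect $f$, so the search space is the $2^N$ subsets of that list. $N$ is
routinely 100–150 on bacterial networks, so exhaustive enumeration
(provided as `exhaustive_search()`, with a Gray-code incremental scan) is
reserved for $N \le 20$–25 and everything else is heuristic:

* **Method A** (`method_a()`, $O(N)$ evaluations): rank TFs once by
  individual p-value; add in rank order while the combined objective
  strictly improves. The stopping rule is read literally — the scan stops
  at the first non-improving TF; `skip = TRUE` gives the lenient variant
  that skips it and continues, for sensitivity analysis.
* **Method B** (`method_b()`, $O(N^2)$): set-cover flavoured; each
  candidate is scored by a Fisher test on the *reduced* problem with the
  already-covered genes removed from the universe, the DE set and the
  candidate's targets. We condition the whole table on the uncovered
  subproblem (the description of the procedure fixes only the DE side),
  and accept a step only if the full-problem objective improves, so that
  the B and C stopping rules are comparable.
* **Method C** (`method_c()`, $O(N^2)$): each candidate is scored by the
  combined objective of (running solution + candidate); the argmin is
  appended while it strictly improves. By construction its final value is
  at least as good as the best single TF.

Ties are always broken lexicographically on TF identifier, so reruns are
deterministic; with a fixed seed every stochastic routine is
bit-reproducible.

### Ruggedness diagnostics and stochastic search

`steepest_descent()` treats configurations as bit-vectors over the
relevant TFs (the empty set, $f = 0$, is a valid state) and moves to the
best strictly-improving single-flip neighbour. Repeated restarts
(`local_minima_census()`) count *distinct* converged values — two minima
are identified when their log10 p differ by less than $10^{-9}$, since
distinct TF sets with the same union are the same statistical hypothesis.
`random_walk_autocorrelation()` reports the Pearson autocorrelation of $f$
along uniform single-flip walks (default length $3N$, long enough to expose
a decay over $O(N)$ steps, pooled over walks and start times).

`simulated_annealing()` escapes local minima by accepting a worsening move
at temperature $T$ with probability $\exp(-\Delta/T)$, where $\Delta$ is
the change in **natural-log** p (log10 differences are scaled by
$\ln 10$; mixing bases silently changes the meaning of $T$). The schedule
is geometric, $T_{n+1} = r\,T_n$, down to $T_f = 0.01$; rather than tuning
$r$ to the landscape, a grid of schedule lengths
$\{5, 10, 15, 20, 25\} \times N$ is run with 10 restarts each. The initial
temperature is set so the mean initial acceptance probability of a
worsening move is 0.8 (`calibrate_initial_temperature()`, probing 100
random states with one random worsening neighbour each). Within each run
the best state *visited* (not the final state) is recorded and polished by
steepest descent before runs are compared.

## Calibrating significance

The search always returns some combination, however meaningless the
profile. `randomized_null()` redistributes the DE label — $n$ genes drawn
uniformly without replacement from the network's gene set, universe held
fixed so $M$ is comparable — re-runs the search (1000 replicates by
default) and standardizes the observed $f$ as a z-score against that
sample. A Kolmogorov–Smirnov test against a normal with the sample's own
mean and sd sanity-checks the z-score's interpretability; because the
parameters are estimated from the same sample this is anti-conservative in
the Lilliefors sense, and is reported as a diagnostic rather than
corrected. Strongly negative z indicates the profile is consistent with
the network's regulon structure; on uniformly random DE sets z is centred
near zero — a property the test suite checks directly.

## The simulation benchmark

`generate_trial()` emulates an idealized perturbation: $k \sim
\mathrm{Uniform}\{5,\dots,20\}$ TFs are "activated", all their direct
targets become DE over a universe of network genes, and with noise rate
$\eta$ a fraction $\lfloor \eta M \rfloor$ of genes have their label
flipped. `run_benchmark()` compares the default test (Bonferroni at
$\alpha$, sweepable down to $10^{-6}$) against Method C by:

* per-TF occurrence frequencies in input and recovered sets, with
  denominator equal to the total trial count for both curves;
* the RMSE of each method's occurrence profile against the input profile,
  averaged over **all** network TFs, including never-selected ones;
* paired recovery accuracies $(TP + TN)/(P + N)$ over the test set of
  relevant TFs, with a two-sided Wilcoxon signed-rank test (zero
  differences dropped), win/tie counts and unit-accuracy counts.

`synthetic_network()` provides the testbed: out-degrees from a truncated
discrete power law, targets uniform without replacement. The acceptance
checks use 197 TFs over a 1934-gene pool with exponent 1.44 and maximum
out-degree 500, chosen so the analytic mean out-degree matches an edge
density of about 4055 interactions over 197 TFs — the scale of a curated
bacterial (E. coli-like) regulatory map with its global-regulator tail.

What the simulator does *not* emulate: operon/transcription-unit
structure, correlated regulon overlap (synthetic regulons overlap only by
chance), signed regulation, and realistic microarray noise (label flips
are uniform, real false calls are expression-dependent). Consequently the
qualitative conclusions — the degree bias of per-TF testing, its
suppression by the combinatorial search, near-perfect noiseless recovery —
transfer to real networks, but exact win rates and RMSE values under noise
depend on the curated network's overlap structure and should be
re-measured on the network of interest. The per-TF deficit of the default
method is concentrated in the lowest out-degree tertile, exactly the
regulators a per-TF test is blind to when perturbations are combined.

### Problem sizes used in the shipped checks

Test-suite and acceptance-script runs use 200–500 trials per noise level,
200 exhaustively solvable instances ($N \le 12$), 200-replicate nulls and
an 80-TF/800-gene network for null calibration — sizes at which every
qualitative assertion above is stable under reseeding while the whole
suite stays fast enough for routine development.

## Worked example

```{r example}
net <- synthetic_network(40, 300, degree_exponent = 1.5, min_degree = 2,
                         max_degree = 60, seed = 1)
trial <- generate_trial(net, k_min = 4, k_max = 8, noise_rate = 0.05,
                        seed = 2)

glance(default_enrichment(net, trial$profile))
sol <- method_c(net, trial$profile)
sol
trial$input_tfs
```

```{r null}
null <- randomized_null(net, trial$profile, reps = 100, seed = 3)
glance(null)
```

## Numerical and degenerate-input conventions

* $a = 0$ gives $P = 1$ ($f = 0$) by the tail definition; empty TF sets
  score 0; a universe entirely DE makes the landscape identically 0.
* Genes with zero expression variance never receive a z-score and are
  never called DE (`zscore_de_call()`, strict `|z| >` threshold;
  population sd by default, sample sd available since the convention is
  not universal).
* Bonferroni's $m$ is the number of TFs with non-zero DE overlap
  (configurable to the total TF count); significance uses strict `<`.
* Random configurations are drawn by independent inclusion with
  probability 1/2 — uniform over the $2^N$ configurations.

## Limitations

Only direct TF-to-gene regulation is modelled: no operon expansion, no
sigma factors or protein-protein layers, no regulation sign, no
parsimony-penalized stopping (the objective is minimized to convergence;
a BIC-like size penalty is a natural extension), and no co-targeting
"module" building blocks. Exhaustive verification is limited to
$N \le 25$ by the $2^N$ enumeration itself.
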