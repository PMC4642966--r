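#' Generate a synthetic regulatory network with broad out-degrees
#'
#' Out-degrees are drawn from a truncated discrete power law
#' `P(d) proportional to d^-exponent` on `[min_degree, max_degree]`, and
#' each TF's targets are drawn uniformly without replacement from the gene
#' pool. Mimics the broad (scale-free-like) out-degree distribution of
#' curated bacterial regulatory networks, where a few global regulators
#' coexist with many small regulons. Only targeted genes enter the
#' network's gene set, so every TF is connected.
#'
#' @param n_tfs Number of transcription factors.
#' @param n_genes Size of the target-gene pool.
#' @param degree_exponent Power-law exponent (larger = narrower); `Inf`
#'   gives every TF exactly `min_degree` targets.
#' @param min_degree Smallest allowed out-degree (>= 1).
#' @param max_degree Largest allowed out-degree (default `n_genes`).
#' @param seed Optional integer seed.
#' @return A [regulatory_network()] with TFs `tf001, tf002, ...` and genes
#'   `g0001, g0002, ...`.
#' @export
synthetic_network <- function(n_tfs, n_genes, degree_exponent = 2,
                              min_degree = 1, max_degree = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_tfs >= 1, n_genes >= 1, min_degree >= 1)
  max_degree <- as.integer(max_degree %||% n_genes)
  max_degree <- min(max_degree, n_genes)
  stopifnot(min_degree <= max_degree)
  support <- min_degree:max_degree
  degrees <- if (is.infinite(degree_exponent) || length(support) == 1L) {
    rep(min_degree, n_tfs)
  } else {
    w <- support^(-degree_exponent)
    sample(support, n_tfs, replace = TRUE, prob = w / sum(w))
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  targets_of <- lapply(degrees, function(d) sort_ids(sample(genes, d)))
  names(targets_of) <- sprintf("tf%03d", seq_len(n_tfs))
  new_regulatory_network(targets_of)
}

# Analytic mean of the truncated discrete power law used above.
truncated_powerlaw_mean <- function(degree_exponent, min_degree, max_degree) {
  d <- min_degree:max_degree
  if (is.infinite(degree_exponent)) return(min_degree)
  w <- d^(-degree_exponent)
  sum(d * w) / sum(w)
}

#' Simulate one perturbation trial
#'
#' Draws `k ~ Uniform{k_min, ..., k_max}` TFs for differential activation;
#' all their direct targets form the DE set over a universe of all network
#' genes (the noiseless limit). With `noise_rate` eta > 0,
#' `floor(eta * |universe|)` uniformly chosen genes then have their label
#' flipped (DE becomes unaltered and vice versa), mimicking
#' misclassification in real profiles.
#'
#' @param net A [regulatory_network()].
#' @param k_min,k_max Input TF set size range (defaults 5 and 20).
#' @param noise_rate Misclassification fraction eta in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return List with `input_tfs` (character) and `profile`
#'   (a [differential_profile()]).
#' @export
generate_trial <- function(net, k_min = 5, k_max = 20, noise_rate = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(net, "regulatory_network"),
            k_min >= 1, k_min <= k_max, k_max <= length(net$tf_ids),
            noise_rate >= 0, noise_rate < 1)
  k <- if (k_min == k_max) k_min else sample(k_min:k_max, 1L)
  input_tfs <- sort_ids(sample(net$tf_ids, k))
  universe <- net$gene_ids
  de <- universe %in%
    unique(unlist(net$targets_of[input_tfs], use.names = FALSE))
  n_flip <- floor(noise_rate * length(universe))
  if (n_flip > 0) {
    flip <- sample.int(length(universe), n_flip)
    de[flip] <- !de[flip]
  }
  list(
    input_tfs = input_tfs,
    profile = differential_profile(universe, universe[de],
                                   case_normalize = FALSE)
  )
}

#' Recovery accuracy of an inferred TF set
#'
#' `(TP + TN) / |test_set|` where the test set is the TFs targeting at
#' least one DE gene, TP counts input TFs correctly recovered, and TN
#' counts test TFs in neither the input nor the recovered set. Equals 1
#' exactly when the recovered set matches the input within the test set.
#'
#' @param input_tfs TFs actually perturbed in the trial.
#' @param recovered TFs returned by an inference method.
#' @param test_set The relevant TFs the classification is judged over.
#' @return Accuracy in `[0, 1]`, or `NA` for an empty test set.
#' @export
recovery_accuracy <- function(input_tfs, recovered, test_set) {
  test_set <- unique(as.character(test_set))
  if (length(test_set) == 0L) return(NA_real_)
  input_tfs <- intersect(unique(as.character(input_tfs)), test_set)
  recovered <- intersect(unique(as.character(recovered)), test_set)
  tp <- length(intersect(recovered, input_tfs))
  tn <- length(setdiff(setdiff(test_set, input_tfs), recovered))
  (tp + tn) / length(test_set)
}

#' Benchmark combinatorial vs per-TF inference on simulated trials
#'
#' Runs [generate_trial()] `n_trials` times; in each trial the perturbed
#' TFs are inferred both by the default per-TF test
#' ([default_enrichment()], Bonferroni-significant TFs at `alpha`) and by
#' the combinatorial search (default [method_c()]). Aggregates per-TF
#' occurrence frequencies (fraction of all trials in which each TF appears
#' in the input / recovered sets), the root-mean-square error of each
#' method's occurrence profile against the input profile (averaged over
#' *all* network TFs), paired recovery accuracies with a two-sided Wilcoxon
#' signed-rank test (zero differences dropped), win/tie/loss counts, and
#' unit-accuracy counts.
#'
#' @inheritParams generate_trial
#' @param n_trials Number of trials.
#' @param alpha Significance threshold for the default method's adjusted
#'   p-values.
#' @param search Combinatorial search function (default [method_c()]).
#' @return Object of class `benchmark_result`: list with `per_tf` (tibble
#'   `tf`, `out_degree`, `freq_input`, `freq_default`, `freq_combo`),
#'   `trials` (tibble of per-trial sizes and accuracies), `summary` (tibble
#'   with `rmse_default`, `rmse_combo`, `wilcoxon_p`, `n_combo_wins`,
#'   `n_default_wins`, `n_ties`, `n_unit_acc_combo`, `n_unit_acc_default`)
#'   and `config`.
#' @export
run_benchmark <- function(net, n_trials = 100, k_min = 5, k_max = 20,
                          noise_rate = 0, alpha = 0.05, seed = NULL,
                          search = method_c) {
  if (!is.null(seed)) set.seed(seed)
  tf_ids <- net$tf_ids
  occ_input <- occ_default <- occ_combo <-
    stats::setNames(numeric(length(tf_ids)), tf_ids)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trial <- generate_trial(net, k_min, k_max, noise_rate)
    test_set <- relevant_tfs(net, trial$profile)
    enr <- default_enrichment(net, trial$profile, alpha = alpha)
    rec_default <- enr$tf[enr$significant]
    rec_combo <- if (length(test_set) > 0L) {
      search(net, trial$profile)$tfs
    } else {
      character()
    }
    occ_input[trial$input_tfs] <- occ_input[trial$input_tfs] + 1
    occ_default[rec_default] <- occ_default[rec_default] + 1
    occ_combo[rec_combo] <- occ_combo[rec_combo] + 1
    acc_default <- recovery_accuracy(trial$input_tfs, rec_default, test_set)
    acc_combo <- recovery_accuracy(trial$input_tfs, rec_combo, test_set)
    k_i <- length(trial$input_tfs)
    n_de_i <- trial$profile$n_de
    trials[[i]] <- tibble::tibble(
      trial = i,
      k = k_i,
      n_de = n_de_i,
      n_test = length(test_set),
      acc_default = acc_default,
      acc_combo = acc_combo
    )
  }
  trials <- dplyr::bind_rows(trials)
  per_tf <- tibble::tibble(
    tf = tf_ids,
    out_degree = unname(net$out_degree),
    freq_input = unname(occ_input) / n_trials,
    freq_default = unname(occ_default) / n_trials,
    freq_combo = unname(occ_combo) / n_trials
  )
  ok <- !is.na(trials$acc_default) & !is.na(trials$acc_combo)
  diff <- trials$acc_combo[ok] - trials$acc_default[ok]
  wilcoxon_p <- if (any(diff != 0)) {
    suppressWarnings(
      wilcox.test(trials$acc_combo[ok], trials$acc_default[ok],
                  paired = TRUE, exact = FALSE)$p.value
    )
  } else {
    NA_real_
  }
  summary <- tibble::tibble(
    n_trials = n_trials,
    noise_rate = noise_rate,
    alpha = alpha,
    rmse_default = sqrt(mean((per_tf$freq_input - per_tf$freq_default)^2)),
    rmse_combo = sqrt(mean((per_tf$freq_input - per_tf$freq_combo)^2)),
    wilcoxon_p = wilcoxon_p,
    n_combo_wins = sum(diff > 0),
    n_default_wins = sum(diff < 0),
    n_ties = sum(diff == 0),
    n_unit_acc_combo = sum(trials$acc_combo[ok] == 1),
    n_unit_acc_default = sum(trials$acc_default[ok] == 1)
  )
  structure(
    list(per_tf = per_tf, trials = trials, summary = summary,
         config = list(n_trials = n_trials, k_min = k_min, k_max = k_max,
                       noise_rate = noise_rate, alpha = alpha, seed = seed)),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat("<benchmark_result>: ", s$n_trials, " trials (eta = ", s$noise_rate,
      ", alpha = ", s$alpha, ")\n",
      "  occurrence RMSE: default = ", format(s$rmse_default, digits = 3),
      ", combinatorial = ", format(s$rmse_combo, digits = 3), "\n",
      "  accuracy wins (combo/tie/default): ", s$n_combo_wins, "/",
      s$n_ties, "/", s$n_default_wins, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) {
  x$per_tf
}

#' @export
glance.benchmark_result <- function(x, ...) {
  x$summary
}

#' Known-causal-regulator evaluation (over-expression style)
#'
#' Generic driver for datasets where the causally perturbed TF is known a
#' priori (e.g. TF over-expression experiments): reports whether the causal
#' TF is individually Bonferroni-enriched at `alpha`, whether it appears in
#' the combinatorial solution, its rank in the individual p-value ordering,
#' and whether it falls among the top k individually ranked TFs (k = size
#' of the combinatorial solution).
#'
#' @inheritParams relevant_tfs
#' @param causal_tf The known perturbed TF identifier.
#' @param alpha Significance threshold for the per-TF test.
#' @param search Combinatorial search function (default [method_c()]).
#' @return One-row tibble: `causal_tf`, `in_network`, `has_overlap`,
#'   `individually_enriched`, `in_combo`, `rank_individual`, `k_combo`,
#'   `in_top_k`.
#' @export
evaluate_known_regulator <- function(net, profile, causal_tf, alpha = 0.05,
                                     search = method_c) {
  causal_tf <- normalize_ids(causal_tf)
  in_network <- causal_tf %in% net$tf_ids
  enr <- default_enrichment(net, profile, alpha = alpha)
  has_overlap <- causal_tf %in% enr$tf
  if (nrow(enr) == 0L) {
    return(tibble::tibble(
      causal_tf = causal_tf, in_network = in_network, has_overlap = FALSE,
      individually_enriched = FALSE, in_combo = FALSE,
      rank_individual = NA_integer_, k_combo = 0L, in_top_k = FALSE
    ))
  }
  combo <- search(net, profile)
  tibble::tibble(
    causal_tf = causal_tf,
    in_network = in_network,
    has_overlap = has_overlap,
    individually_enriched =
      has_overlap && enr$significant[enr$tf == causal_tf],
    in_combo = causal_tf %in% combo$tfs,
    rank_individual = if (has_overlap) match(causal_tf, enr$tf)
                      else NA_integer_,
    k_combo = length(combo$tfs),
    in_top_k = has_overlap &&
      match(causal_tf, enr$tf) <= length(combo$tfs)
  )
}
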