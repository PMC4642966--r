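test_that("synthetic networks honor their degree law and are reproducible", {
  n1 <- synthetic_network(10, 50, degree_exponent = Inf, min_degree = 3,
                          seed = 1)
  expect_true(all(n1$out_degree == 3L))
  n2 <- synthetic_network(10, 50, degree_exponent = Inf, min_degree = 3,
                          seed = 1)
  expect_identical(n1$targets_of, n2$targets_of)
  n3 <- synthetic_network(40, 200, degree_exponent = 1.5, min_degree = 1,
                          max_degree = 50, seed = 2)
  expect_true(all(n3$out_degree >= 1 & n3$out_degree <= 50))
  expect_length(n3$tf_ids, 40L)
})

test_that("the empirical mean out-degree matches the analytic truncated
           power-law mean", {
  lo <- 1; hi <- 30; gamma <- 1.5
  analytic <- tfcombo:::truncated_powerlaw_mean(gamma, lo, hi)
  set.seed(77)
  degs <- unlist(lapply(1:100, function(i) {
    synthetic_network(20, 100, degree_exponent = gamma, min_degree = lo,
                      max_degree = hi)$out_degree
  }))
  expect_equal(mean(degs), analytic, tolerance = 0.1)
})

test_that("trials perturb k TFs and label exactly their targets DE in the
           noiseless limit", {
  net <- disjoint_network(n_tfs = 10, degree = 5)
  trial <- generate_trial(net, k_min = 3, k_max = 3, seed = 9)
  expect_length(trial$input_tfs, 3L)
  expect_equal(trial$profile$n_de, 15L)
  expect_setequal(
    trial$profile$de_genes,
    unlist(net$targets_of[trial$input_tfs], use.names = FALSE)
  )
  # determinism under a fixed seed
  again <- generate_trial(net, k_min = 3, k_max = 3, seed = 9)
  expect_identical(trial, again)
  # eta = 1 is rejected
  expect_error(generate_trial(net, noise_rate = 1, k_min = 2, k_max = 3),
               "noise_rate")
})

test_that("label noise flips exactly floor(eta * M) genes", {
  net <- disjoint_network(n_tfs = 10, degree = 5)
  clean <- generate_trial(net, k_min = 4, k_max = 4, seed = 13)
  set.seed(13)
  noisy <- generate_trial(net, k_min = 4, k_max = 4, noise_rate = 0.1)
  sym_diff <- union(setdiff(clean$profile$de_genes, noisy$profile$de_genes),
                    setdiff(noisy$profile$de_genes, clean$profile$de_genes))
  expect_length(sym_diff, floor(0.1 * length(net$gene_ids)))
})

test_that("recovery accuracy implements (TP + TN) / |test set|", {
  test_set <- paste0("t", 1:5)
  expect_equal(recovery_accuracy(c("t1", "t2"), c("t1", "t2"), test_set), 1)
  # P = 2, TP = 1, TN = 2 => 3/5
  expect_equal(
    recovery_accuracy(c("t1", "t2"), c("t1", "t3"), test_set), 0.6
  )
  # recovered = complement of input: every classification wrong
  expect_equal(
    recovery_accuracy(c("t1", "t2"), c("t3", "t4", "t5"), test_set), 0
  )
  expect_true(is.na(recovery_accuracy("t1", "t1", character())))
})

test_that("a single disjoint-target trial is recovered perfectly by both
           methods", {
  net <- disjoint_network(n_tfs = 10, degree = 5)
  bench <- run_benchmark(net, n_trials = 1, k_min = 3, k_max = 3, seed = 4)
  expect_equal(bench$summary$rmse_default, 0)
  expect_equal(bench$summary$rmse_combo, 0)
  expect_equal(bench$trials$acc_default, 1)
  expect_equal(bench$trials$acc_combo, 1)
})

test_that("input occurrence frequencies match uniform sampling expectation", {
  net <- synthetic_network(30, 150, degree_exponent = 1.5, min_degree = 2,
                           seed = 41)
  bench <- run_benchmark(net, n_trials = 150, k_min = 5, k_max = 10,
                         seed = 42)
  p_expected <- mean(5:10) / 30
  se <- sqrt(p_expected * (1 - p_expected) / 150)
  expect_lt(abs(mean(bench$per_tf$freq_input) - p_expected), 3 * se)
  expect_true(all(bench$per_tf$freq_input >= 0 &
                    bench$per_tf$freq_input <= 1))
})

test_that("benchmarks are reproducible under a seed and expose tidy
           summaries", {
  net <- synthetic_network(15, 80, degree_exponent = 1.5, min_degree = 2,
                           seed = 51)
  b1 <- run_benchmark(net, n_trials = 10, k_min = 3, k_max = 5, seed = 52)
  b2 <- run_benchmark(net, n_trials = 10, k_min = 3, k_max = 5, seed = 52)
  expect_identical(b1$per_tf, b2$per_tf)
  expect_identical(b1$trials, b2$trials)
  expect_s3_class(glance(b1), "tbl_df")
  expect_identical(tidy(b1), b1$per_tf)
  expect_true(all(b1$summary$rmse_default >= 0, b1$summary$rmse_combo >= 0))
})

test_that("an isolated single-TF perturbation is recovered exactly by the
           default test", {
  net <- disjoint_network(n_tfs = 8, degree = 6)
  for (seed in 1:5) {
    trial <- generate_trial(net, k_min = 1, k_max = 1, seed = seed)
    enr <- default_enrichment(net, trial$profile)
    expect_equal(enr$tf[enr$significant], trial$input_tfs)
  }
})

test_that("the known-regulator driver reports recovery of the causal TF", {
  net <- disjoint_network(n_tfs = 8, degree = 6)
  trial <- generate_trial(net, k_min = 1, k_max = 1, seed = 3)
  row <- evaluate_known_regulator(net, trial$profile, trial$input_tfs)
  expect_true(row$in_network && row$has_overlap)
  expect_true(row$individually_enriched)
  expect_true(row$in_combo)
  expect_equal(row$rank_individual, 1L)
  expect_true(row$in_top_k)
  # a TF unrelated to the profile
  other <- setdiff(net$tf_ids, trial$input_tfs)[1]
  row2 <- evaluate_known_regulator(net, trial$profile, other)
  expect_false(row2$has_overlap || row2$in_combo)
})
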