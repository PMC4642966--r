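test_that("steepest descent is a fixed point at the global optimum", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  sol <- steepest_descent(net, prof, initial = c("a", "b"))
  expect_setequal(sol$tfs, c("a", "b"))
  expect_length(sol$trace, 1L)
})

test_that("steepest descent leaves an improvable configuration and lands at
           a state with no strictly improving neighbor", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  sol <- steepest_descent(net, prof, initial = "c")
  expect_false(identical(sol$tfs, "c"))
  expect_true(all(diff(sol$trace) < 0))
  # no neighbor (single-TF flip, empty set allowed) improves the result
  relevant <- relevant_tfs(net, prof)
  for (tf in relevant) {
    flipped <- if (tf %in% sol$tfs) setdiff(sol$tfs, tf) else c(sol$tfs, tf)
    expect_gte(combined_log_p(net, flipped, prof), sol$log_p)
  }
})

test_that("descent local minima have no improving neighbor on random
           instances", {
  for (seed in 1:10) {
    inst <- random_small_instance(seed)
    sol <- steepest_descent(inst$net, inst$profile, seed = seed + 100)
    relevant <- relevant_tfs(inst$net, inst$profile)
    neighbors <- vapply(relevant, function(tf) {
      flipped <- if (tf %in% sol$tfs) setdiff(sol$tfs, tf)
                 else c(sol$tfs, tf)
      combined_log_p(inst$net, flipped, inst$profile)
    }, double(1))
    expect_true(all(neighbors >= sol$log_p - 1e-12))
    expect_equal(sol$log_p,
                 combined_log_p(inst$net, sol$tfs, inst$profile),
                 tolerance = 1e-12)
  }
})

test_that("descent rejects starts outside the relevant set and is
           reproducible under a seed", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  expect_error(steepest_descent(net, prof, initial = "zz"), "relevant")
  s1 <- steepest_descent(net, prof, seed = 7)
  s2 <- steepest_descent(net, prof, seed = 7)
  expect_identical(s1$tfs, s2$tfs)
  expect_identical(s1$trace, s2$trace)
})

test_that("random-walk autocorrelation starts at 1 and decays", {
  net <- synthetic_network(15, 80, degree_exponent = 1.5, min_degree = 2,
                           seed = 3)
  set.seed(4)
  prof <- differential_profile(net$gene_ids, sample(net$gene_ids, 20))
  ac <- random_walk_autocorrelation(net, prof, n_walks = 200, seed = 5)
  expect_equal(ac$autocorrelation[[1]], 1)
  expect_equal(nrow(ac), 3 * length(relevant_tfs(net, prof)) + 1)
  n <- length(relevant_tfs(net, prof))
  expect_lt(ac$autocorrelation[ac$lag == 2 * n], 0.5)
  expect_true(all(diff(ac$n_pairs) < 0))
})

test_that("a constant landscape reports undefined autocorrelation", {
  # when the whole universe is DE, every draw from it succeeds surely:
  # each configuration has p = 1 and the landscape is flat at log10 p = 0
  net <- regulatory_network(tibble::tibble(
    tf = c("a", "b"), gene = c("g1", "g2")
  ))
  prof <- differential_profile(c("g1", "g2"), c("g1", "g2"))
  expect_warning(
    ac <- random_walk_autocorrelation(net, prof, n_walks = 10, seed = 1),
    "constant"
  )
  expect_true(all(is.na(ac$autocorrelation)))
})

test_that("the local-minima census matches brute-force basin enumeration on
           the toy landscape", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  # deterministic descent from every one of the 2^3 states
  starts <- c(list(character()), all_subsets(c("a", "b", "c")))
  finals <- vapply(starts, function(s) {
    steepest_descent(net, prof, initial = s)$log_p
  }, double(1))
  n_distinct_expected <- length(unique(round(finals, 9)))
  census <- local_minima_census(net, prof, n_runs = 200, seed = 8)
  expect_equal(nrow(census$distinct_minima), n_distinct_expected)
  expect_equal(sum(census$distinct_minima$multiplicity), 200L)
  expect_true(all(diff(census$minima_curve$n_distinct) >= 0))
  expect_equal(census$best$log_p, min(finals), tolerance = 1e-12)
})

test_that("a single-minimum landscape flattens the census curve at 1", {
  net <- disjoint_network(n_tfs = 4, degree = 3)
  prof <- differential_profile(net$gene_ids,
                               unlist(net$targets_of[1:2],
                                      use.names = FALSE))
  census <- local_minima_census(net, prof, n_runs = 50, seed = 2)
  expect_equal(unique(census$minima_curve$n_distinct), 1L)
})

test_that("assess_ruggedness bundles both diagnostics reproducibly", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  r1 <- assess_ruggedness(net, prof, n_walks = 30, n_runs = 30, seed = 9)
  r2 <- assess_ruggedness(net, prof, n_walks = 30, n_runs = 30, seed = 9)
  expect_identical(r1$autocorrelation, r2$autocorrelation)
  expect_identical(r1$minima_curve, r2$minima_curve)
  expect_s3_class(glance(r1), "tbl_df")
})
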