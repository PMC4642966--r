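test_that("contingency cells count target/DE overlap over the universe", {
  prof <- differential_profile(paste0("g", 1:10), paste0("g", 1:5))
  tab <- build_contingency(paste0("g", 1:4), prof)
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 4L, b = 0L, c = 1L, d = 5L))
  expect_equal(tab$M, 10L)
  # targets outside the universe are intersected away
  out <- build_contingency(c("x1", "x2"), prof)
  expect_equal(c(out$a, out$b), c(0L, 0L))
  # degenerate full-overlap table
  all_prof <- differential_profile(paste0("g", 1:4), paste0("g", 1:4))
  full <- build_contingency(paste0("g", 1:4), all_prof)
  expect_equal(c(full$a, full$b, full$c, full$d), c(4L, 0L, 0L, 0L))
})

test_that("log-space Fisher tail matches hand-derived values", {
  # M=10, draws=4, successes=5, a=4: p = C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(log_fisher_right(list(a = 4, b = 0, c = 1, d = 5)),
               log10(5 / 210), tolerance = 1e-12)
  # M=4, draws=2, successes=2, a=1: p = 1 - C(2,0)C(2,2)/C(4,2) = 5/6
  expect_equal(log_fisher_right(list(a = 1, b = 1, c = 1, d = 1)),
               log10(5 / 6), tolerance = 1e-12)
  # a = 0 is the whole tail: p = 1
  expect_identical(log_fisher_right(list(a = 0, b = 3, c = 2, d = 5)), 0)
})

test_that("log-space tail agrees with exact enumeration and stays finite
           far below linear-double underflow", {
  set.seed(9)
  for (i in 1:200) {
    M <- sample(4:60, 1)
    K <- sample(0:M, 1)
    k <- sample(0:M, 1)
    a_max <- min(K, k)
    a_min <- max(0, k + K - M)
    a <- if (a_min == a_max) a_min else sample(a_min:a_max, 1)
    b <- k - a
    cc <- K - a
    d <- M - a - b - cc
    mine <- log_fisher_right(list(a = a, b = b, c = cc, d = d))
    ref <- oracle_log10_fisher(a, b, cc, d)
    # absolute agreement in log10 units (both may be -Inf for impossible
    # tails)
    expect_true(identical(mine, ref) || abs(mine - ref) < 1e-10)
  }
  # extreme enrichment: p underflows linearly but not in log space
  lp <- log_fisher_right(list(a = 300, b = 0, c = 0, d = 3000))
  expect_true(is.finite(lp) && lp < -300)
  expect_equal(lp, -lchoose(3300, 300) / log(10), tolerance = 1e-9)
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.03, 1), 0.03)
  expect_equal(bonferroni(0.03, 5), 0.15)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_error(bonferroni(0.05, 0), "m")
})

test_that("per-TF enrichment tests exactly the relevant TFs", {
  net <- toy_abc_network()
  # DE = {g1, g2}: only A and C overlap; B has a = 0 and is not tested
  prof <- differential_profile(paste0("g", 1:8), c("g1", "g2"))
  enr <- default_enrichment(net, prof, alpha = 0.1)
  expect_equal(enr$tf, c("a", "c"))
  expect_equal(attr(enr, "m"), 2L)
  # A covers both DE genes: p = C(2,2)C(6,0)/C(8,2) = 1/28, adj = 2/28
  expect_equal(enr$p_adj[enr$tf == "a"], 2 / 28, tolerance = 1e-12)
  expect_true(enr$significant[enr$tf == "a"]) # 2/28 < 0.1
  expect_false(all(enr$significant)) # C overlaps one DE gene only
  expect_true(all(diff(enr$log10_p) >= 0))
  # m_mode = "all" uses the full TF count
  enr_all <- default_enrichment(net, prof, m_mode = "all")
  expect_equal(attr(enr_all, "m"), 3L)
  expect_equal(enr_all$p_adj[enr_all$tf == "a"], 3 / 28, tolerance = 1e-12)
})

test_that("no relevant TFs yields an empty enrichment table, not an error", {
  net <- toy_abc_network()
  prof <- differential_profile(paste0("g", 1:8), "g8")
  enr <- default_enrichment(net, prof)
  expect_equal(nrow(enr), 0L)
  expect_s3_class(enr, "tf_enrichment")
})

test_that("combined objective scores the union of target sets", {
  net <- regulatory_network(tibble::tibble(
    tf = c("a", "a", "b"), gene = c("g1", "g2", "g3")
  ))
  prof <- differential_profile(paste0("g", 1:8), c("g1", "g2", "g3"))
  # union covers all 3 DE genes: p = C(3,3)C(5,0)/C(8,3) = 1/56
  expect_equal(combined_log_p(net, c("a", "b"), prof), log10(1 / 56),
               tolerance = 1e-12)
  expect_identical(combined_log_p(net, character(), prof), 0)
  expect_equal(combined_log_p(net, c("b", "a"), prof),
               combined_log_p(net, c("a", "b"), prof))
  expect_error(combined_log_p(net, "nope", prof), "nope")
})

test_that("overlapping unions do not double-count and idempotent unions
           match the single-TF value", {
  net <- toy_abc_network()
  prof <- toy_abc_profile()
  # C's targets are inside A+B's union: adding C changes nothing
  expect_equal(combined_log_p(net, c("a", "b", "c"), prof),
               combined_log_p(net, c("a", "b"), prof))
  expect_equal(combined_log_p(net, c("a", "a"), prof),
               combined_log_p(net, "a", prof))
})

test_that("adding a TF fully inside the uncovered DE set strictly improves
           the combined objective", {
  net <- disjoint_network(n_tfs = 8, degree = 4)
  prof <- differential_profile(net$gene_ids,
                               unlist(net$targets_of[1:4],
                                      use.names = FALSE))
  sol <- net$tf_ids[1]
  for (tf in net$tf_ids[2:4]) {
    before <- combined_log_p(net, sol, prof)
    sol <- c(sol, tf)
    expect_lt(combined_log_p(net, sol, prof), before)
  }
})
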