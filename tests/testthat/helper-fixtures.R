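# Fixtures and independent oracles shared across the suite. Everything is
# built in code at test time; no data files.

# Three-TF toy landscape: A -> {g1,g2}, B -> {g3,g4}, C -> {g2,g3} over a
# universe of 8 genes with DE = {g1..g4}. {A,B} is the global optimum
# (a=4, b=0 => p = 1/choose(8,4) = 1/70).
toy_abc_network <- function() {
  regulatory_network(tibble::tibble(
    tf = c("a", "a", "b", "b", "c", "c"),
    gene = c("g1", "g2", "g3", "g4", "g2", "g3")
  ))
}

toy_abc_profile <- function() {
  differential_profile(paste0("g", 1:8), paste0("g", 1:4))
}

# Network whose TF target sets are mutually disjoint: TF i regulates its own
# block of `degree` genes. With DE = union of some TFs' blocks, only those
# TFs are relevant and recovery is provably exact.
disjoint_network <- function(n_tfs = 10, degree = 5) {
  edges <- tibble::tibble(
    tf = rep(sprintf("tf%02d", seq_len(n_tfs)), each = degree),
    gene = sprintf("g%03d", seq_len(n_tfs * degree))
  )
  regulatory_network(edges)
}

# Exact hypergeometric right-tail oracle: plain rational-arithmetic pmf
# enumeration with choose(), independent of the log-space implementation.
oracle_log10_fisher <- function(a, b, cc, d) {
  M <- a + b + cc + d
  K <- a + cc
  k <- a + b
  if (a == 0) return(0)
  x <- a:min(K, k)
  log10(sum(choose(K, x) * choose(M - K, k - x))) - log10(choose(M, k))
}

# Small random instance for oracle-equivalence checks: a narrow synthetic
# network plus a uniformly drawn DE set (not trial-generated, so the
# landscape is rugged rather than trivially recoverable).
random_small_instance <- function(seed, n_tfs = 12, n_genes = 40) {
  set.seed(seed)
  net <- synthetic_network(n_tfs, n_genes, degree_exponent = 1.5,
                           min_degree = 2, max_degree = 8)
  n_de <- sample(4:12, 1)
  profile <- differential_profile(net$gene_ids,
                                  sample(net$gene_ids, n_de))
  list(net = net, profile = profile)
}

# All non-empty subsets of a character vector (for brute-force enumeration
# on tiny landscapes).
all_subsets <- function(ids) {
  n <- length(ids)
  purrr::map(seq_len(2^n - 1), function(mask) {
    ids[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) > 0]
  })
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
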