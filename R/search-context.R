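# Internal search context: the combination landscape restricted to the
# relevant TFs, with genes re-indexed into the universe so that combined
# p-values of neighboring configurations can be updated incrementally in
# O(out-degree) instead of recomputed from the union each time.

search_context <- function(net, profile) {
  tfs <- relevant_tfs(net, profile)
  universe <- profile$universe
  M <- length(universe)
  de <- universe %in% profile$de_genes
  targets <- lapply(net$targets_of[tfs], function(tg) {
    idx <- match(tg, universe)
    idx[!is.na(idx)]
  })
  list(tfs = tfs, N = length(tfs), M = M, n_de = profile$n_de,
       de = de, targets = targets)
}

# Combined log10 p of a subset given as integer TF indices (from scratch).
ctx_eval <- function(ctx, tf_idx) {
  if (length(tf_idx) == 0L) return(0)
  u <- unique(unlist(ctx$targets[tf_idx], use.names = FALSE))
  log10_hyper_tail(ctx$M, ctx$n_de, length(u), sum(ctx$de[u]))
}

# Mutable search state: coverage counts per universe gene plus the running
# union size k, overlap a, and objective lp for the selected subset.
ctx_state <- function(ctx, sel) {
  counts <- tabulate(as.integer(unlist(ctx$targets[sel], use.names = FALSE)),
                     nbins = ctx$M)
  covered <- counts > 0L
  st <- new.env(parent = emptyenv())
  st$sel <- sel
  st$counts <- counts
  st$k <- sum(covered)
  st$a <- sum(ctx$de & covered)
  st$lp <- log10_hyper_tail(ctx$M, ctx$n_de, st$k, st$a)
  st
}

# Objective after flipping TF j (add if absent, drop if present), without
# mutating the state. Only genes whose coverage count crosses 0 change the
# union.
ctx_flip_lp <- function(ctx, st, j) {
  tg <- ctx$targets[[j]]
  if (st$sel[[j]]) {
    changed <- tg[st$counts[tg] == 1L]
    k <- st$k - length(changed)
    a <- st$a - sum(ctx$de[changed])
  } else {
    changed <- tg[st$counts[tg] == 0L]
    k <- st$k + length(changed)
    a <- st$a + sum(ctx$de[changed])
  }
  log10_hyper_tail(ctx$M, ctx$n_de, k, a)
}

ctx_flip_apply <- function(ctx, st, j) {
  tg <- ctx$targets[[j]]
  if (st$sel[[j]]) {
    st$counts[tg] <- st$counts[tg] - 1L
    changed <- tg[st$counts[tg] == 0L]
    st$k <- st$k - length(changed)
    st$a <- st$a - sum(ctx$de[changed])
    st$sel[[j]] <- FALSE
  } else {
    changed <- tg[st$counts[tg] == 0L]
    st$counts[tg] <- st$counts[tg] + 1L
    st$k <- st$k + length(changed)
    st$a <- st$a + sum(ctx$de[changed])
    st$sel[[j]] <- TRUE
  }
  st$lp <- log10_hyper_tail(ctx$M, ctx$n_de, st$k, st$a)
  invisible(st)
}

# Uniform random configuration: each relevant TF included with prob 1/2.
ctx_random_sel <- function(ctx) {
  runif(ctx$N) < 0.5
}
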