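new_tf_solution <- function(tfs, log_p, trace, method, n_dim, ...) {
  structure(
    list(tfs = tfs, log_p = log_p, trace = trace, method = method,
         n_dim = n_dim, ...),
    class = "tf_solution"
  )
}

#' @export
print.tf_solution <- function(x, ...) {
  cat("<tf_solution> method ", x$method, ": ", length(x$tfs), " TF(s), ",
      "log10 p = ", format(x$log_p, digits = 6), " (N = ", x$n_dim, ")\n",
      sep = "")
  if (length(x$tfs)) cat("  ", paste(x$tfs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.tf_solution <- function(x, ...) {
  tibble::tibble(step = seq_along(x$trace), log10_p = x$trace)
}

#' @export
glance.tf_solution <- function(x, ...) {
  tibble::tibble(method = x$method, n_tfs = length(x$tfs),
                 log10_p = x$log_p, n_dim = x$n_dim,
                 n_steps = length(x$trace))
}

# Individual (single-TF) log10 p for every relevant TF, plus the greedy
# starting index: the argmin with lexicographic tie-break (ctx$tfs is
# already in lexicographic order, so the first minimum wins).
ctx_individual_lp <- function(ctx) {
  vapply(seq_len(ctx$N), function(j) ctx_eval(ctx, j), double(1))
}

ctx_require_relevant <- function(ctx) {
  if (ctx$N == 0L) {
    stop("nothing to search: no TF targets a differentially expressed gene",
         call. = FALSE)
  }
}

#' Greedy search, Method A: fixed individual-p ranking
#'
#' TFs are ranked once by their individual enrichment p-value (ascending,
#' lexicographic tie-break). The solution starts with the top-ranked TF;
#' each subsequent TF in rank order is tentatively added and kept only if
#' the combined log10 p strictly decreases. By default the scan stops at the
#' first non-improving TF; `skip = TRUE` instead skips it and continues down
#' the list (sensitivity variant). Costs at most N combined-p evaluations.
#'
#' @inheritParams relevant_tfs
#' @param skip Continue scanning past a non-improving TF instead of
#'   stopping.
#' @return A `tf_solution`: fields `tfs` (insertion order), `log_p`, `trace`
#'   (combined log10 p after each accepted update), `method`, `n_dim`.
#' @export
method_a <- function(net, profile, skip = FALSE) {
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  lp_ind <- ctx_individual_lp(ctx)
  ord <- order(lp_ind, method = "radix")
  sol <- ord[[1]]
  cur <- lp_ind[[sol]]
  trace <- cur
  for (j in ord[-1]) {
    cand <- ctx_eval(ctx, c(sol, j))
    if (cand < cur) {
      sol <- c(sol, j)
      cur <- cand
      trace <- c(trace, cur)
    } else if (!skip) {
      break
    }
  }
  new_tf_solution(ctx$tfs[sol], cur, trace, "a", ctx$N)
}

#' Greedy search, Method B: set-cover-style scoring on uncovered genes
#'
#' Starts with the best single TF. At each step every remaining candidate is
#' scored by a Fisher p-value on the *reduced* problem in which the genes
#' already covered by the running solution are removed from the universe,
#' the DE set, and the candidate's target set (conditioning on the uncovered
#' subproblem). The best-scoring candidate is appended only if the
#' full-problem combined log10 p strictly decreases; otherwise the search
#' halts. O(N) candidate scores per step, O(N^2) total.
#'
#' @inheritParams relevant_tfs
#' @return A `tf_solution` (see [method_a()]).
#' @export
method_b <- function(net, profile) {
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  lp_ind <- ctx_individual_lp(ctx)
  start <- which.min(lp_ind)
  st <- ctx_state(ctx, seq_len(ctx$N) == start)
  trace <- st$lp
  sol <- start
  repeat {
    remaining <- which(!st$sel)
    if (length(remaining) == 0L) break
    covered <- st$counts > 0L
    M_red <- ctx$M - st$k
    K_red <- ctx$n_de - st$a
    red <- vapply(remaining, function(j) {
      tg <- ctx$targets[[j]]
      tg <- tg[!covered[tg]]
      log10_hyper_tail(M_red, K_red, length(tg), sum(ctx$de[tg]))
    }, double(1))
    best_j <- remaining[[which.min(red)]]
    cand <- ctx_flip_lp(ctx, st, best_j)
    if (cand < st$lp) {
      ctx_flip_apply(ctx, st, best_j)
      sol <- c(sol, best_j)
      trace <- c(trace, st$lp)
    } else {
      break
    }
  }
  new_tf_solution(ctx$tfs[sol], st$lp, trace, "b", ctx$N)
}

#' Greedy search, Method C: combined-p scoring of each candidate
#'
#' Starts with the best single TF. At each step every remaining candidate is
#' scored by the combined log10 p of (running solution + candidate) on the
#' full problem; the argmin is appended if it strictly improves the
#' objective, otherwise the search halts. O(N^2) combined-p evaluations. By
#' construction the final log10 p is at most the best individual TF's.
#'
#' @inheritParams relevant_tfs
#' @return A `tf_solution` (see [method_a()]).
#' @examples
#' net <- regulatory_network(tibble::tibble(
#'   tf = c("a", "a", "b", "b", "c", "c"),
#'   gene = c("g1", "g2", "g3", "g4", "g2", "g3")
#' ))
#' prof <- differential_profile(paste0("g", 1:8), paste0("g", 1:4))
#' method_c(net, prof)$tfs # "a" "b"
#' @export
method_c <- function(net, profile) {
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  lp_ind <- ctx_individual_lp(ctx)
  start <- which.min(lp_ind)
  st <- ctx_state(ctx, seq_len(ctx$N) == start)
  trace <- st$lp
  sol <- start
  repeat {
    remaining <- which(!st$sel)
    if (length(remaining) == 0L) break
    cand_lp <- vapply(remaining, function(j) ctx_flip_lp(ctx, st, j),
                      double(1))
    best_i <- which.min(cand_lp)
    if (cand_lp[[best_i]] < st$lp) {
      best_j <- remaining[[best_i]]
      ctx_flip_apply(ctx, st, best_j)
      sol <- c(sol, best_j)
      trace <- c(trace, st$lp)
    } else {
      break
    }
  }
  new_tf_solution(ctx$tfs[sol], st$lp, trace, "c", ctx$N)
}

# TRUE if sorted index vector x precedes y under the exhaustive-search
# tie-break: smaller subset first, then lexicographic.
subset_precedes <- function(x, y) {
  if (length(x) != length(y)) return(length(x) < length(y))
  d <- which(x != y)
  if (length(d) == 0L) return(FALSE)
  x[[d[[1]]]] < y[[d[[1]]]]
}

#' Exhaustive search over all non-empty TF combinations
#'
#' Enumerates all `2^N - 1` non-empty subsets of the relevant TFs in Gray
#' code order (one TF flipped per step, so each subset is scored
#' incrementally) and returns the global minimum of the combined log10 p.
#' Ties are broken toward the smallest subset, then lexicographically.
#' Intended as the exact oracle for small instances; refuses to run above
#' 25 dimensions.
#'
#' @inheritParams relevant_tfs
#' @param max_n Largest N the search will attempt (default 20, hard cap 25).
#' @param return_all Also return the full vector of subset log10 p-values
#'   (length `2^N - 1`, enumeration order) as field `all_log_p`, for rank
#'   statistics.
#' @return A `tf_solution` with method `"exhaustive"`.
#' @export
exhaustive_search <- function(net, profile, max_n = 20, return_all = FALSE) {
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  max_n <- min(max_n, 25L)
  if (ctx$N > max_n) {
    stop("N = ", ctx$N, " relevant TFs exceeds max_n = ", max_n,
         "; use a heuristic (method_c, simulated_annealing) instead",
         call. = FALSE)
  }
  st <- ctx_state(ctx, rep(FALSE, ctx$N))
  n_subsets <- bitwShiftL(1L, ctx$N) - 1L
  all_lp <- if (return_all) numeric(n_subsets) else NULL
  best_lp <- Inf
  best_set <- integer()
  for (i in seq_len(n_subsets)) {
    j <- 1L
    while (bitwAnd(i, bitwShiftL(1L, j - 1L)) == 0L) j <- j + 1L
    ctx_flip_apply(ctx, st, j)
    if (return_all) all_lp[[i]] <- st$lp
    if (st$lp < best_lp ||
        (st$lp == best_lp && subset_precedes(which(st$sel), best_set))) {
      best_lp <- st$lp
      best_set <- which(st$sel)
    }
  }
  new_tf_solution(ctx$tfs[best_set], best_lp, best_lp, "exhaustive", ctx$N,
                  all_log_p = all_lp)
}

#' Compare search methods on one profile
#'
#' Runs the requested heuristics (and, when N permits, the exhaustive
#' oracle) on a single profile and tabulates solution size and objective,
#' plus each solution's rank among all subset p-values when the oracle ran.
#'
#' @inheritParams relevant_tfs
#' @param methods Subset of `c("a", "b", "c")`.
#' @param exhaustive Also run [exhaustive_search()] if N does not exceed
#'   `max_n`.
#' @param max_n Passed to [exhaustive_search()].
#' @return Tibble with columns `method`, `n_tfs`, `log10_p`, and (when the
#'   oracle ran) `rank` (1 = global minimum) and `global_min`.
#' @export
compare_methods <- function(net, profile, methods = c("a", "b", "c"),
                            exhaustive = TRUE, max_n = 20) {
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(a = method_a, b = method_b, c = method_c)
  sols <- purrr::map(methods, function(m) runners[[m]](net, profile))
  out <- purrr::map2(methods, sols, function(m, s) {
    tibble::tibble(method = m, n_tfs = length(s$tfs), log10_p = s$log_p)
  }) |> dplyr::bind_rows()
  n_rel <- length(relevant_tfs(net, profile))
  if (exhaustive && n_rel <= min(max_n, 25)) {
    ex <- exhaustive_search(net, profile, max_n = max_n, return_all = TRUE)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(method = "exhaustive", n_tfs = length(ex$tfs),
                     log10_p = ex$log_p)
    )
    sorted <- sort(ex$all_log_p)
    out$rank <- vapply(out$log10_p, function(lp) {
      sum(sorted < lp - 1e-9) + 1L
    }, integer(1))
    out$global_min <- abs(out$log10_p - ex$log_p) < 1e-9
  }
  out
}
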