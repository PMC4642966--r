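#' Steepest-descent local search over TF configurations
#'
#' States are subsets of the relevant TFs (the empty configuration, with
#' log10 p = 0, is a valid state); neighbors differ by adding or removing a
#' single TF. From the starting configuration the search repeatedly moves to
#' the best strictly-improving neighbor (ties broken toward the
#' lexicographically smallest flipped TF) and stops at a local minimum.
#'
#' @inheritParams relevant_tfs
#' @param initial Character vector of TFs for the starting configuration
#'   (must be relevant TFs), or `NULL` to draw a uniform random
#'   configuration (each relevant TF included with probability 1/2).
#' @param seed Optional integer seed for the random start.
#' @return A `tf_solution` with method `"descent"`; `trace` starts at the
#'   initial configuration's log10 p and strictly decreases.
#' @export
steepest_descent <- function(net, profile, initial = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- search_context(net, profile)
  sel <- descent_initial_sel(ctx, initial)
  st <- ctx_state(ctx, sel)
  descent_from_state(ctx, st)
}

descent_initial_sel <- function(ctx, initial) {
  if (is.null(initial)) return(ctx_random_sel(ctx))
  initial <- unique(as.character(initial))
  bad <- setdiff(initial, ctx$tfs)
  if (length(bad) > 0L) {
    stop("initial configuration contains TF(s) outside the relevant set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ctx$tfs %in% initial
}

# Core descent loop on a mutable state; shared with simulated annealing's
# polishing step.
descent_from_state <- function(ctx, st) {
  trace <- st$lp
  repeat {
    best_lp <- st$lp
    best_j <- 0L
    for (j in seq_len(ctx$N)) {
      lp_j <- ctx_flip_lp(ctx, st, j)
      if (lp_j < best_lp) {
        best_lp <- lp_j
        best_j <- j
      }
    }
    if (best_j == 0L) break
    ctx_flip_apply(ctx, st, best_j)
    trace <- c(trace, st$lp)
  }
  new_tf_solution(ctx$tfs[st$sel], st$lp, trace, "descent", ctx$N)
}

#' Random-walk autocorrelation of the combined p-value landscape
#'
#' Each walk starts at a uniform random configuration and flips one
#' uniformly chosen TF per step. For each lag k, the Pearson correlation
#' between the log10 p at times t and t + k is pooled across walks and
#' start times. A fast decay (over O(N) steps) indicates a rugged
#' landscape. The lag-0 correlation is 1 by definition; if the landscape is
#' constant along the walks the correlation is undefined and reported as
#' `NA` with a warning.
#'
#' @inheritParams relevant_tfs
#' @param n_walks Number of independent walks (default 5000).
#' @param walk_length Steps per walk; default `3 * N`.
#' @param seed Optional integer seed.
#' @return Tibble with columns `lag`, `autocorrelation`, `n_pairs`.
#' @export
random_walk_autocorrelation <- function(net, profile, n_walks = 5000,
                                        walk_length = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- search_context(net, profile)
  if (ctx$N < 2L) {
    stop("random walks need at least 2 relevant TFs", call. = FALSE)
  }
  L <- as.integer(walk_length %||% (3L * ctx$N))
  lp_mat <- matrix(NA_real_, nrow = n_walks, ncol = L + 1L)
  for (w in seq_len(n_walks)) {
    st <- ctx_state(ctx, ctx_random_sel(ctx))
    lp_mat[w, 1L] <- st$lp
    flips <- sample.int(ctx$N, L, replace = TRUE)
    for (t in seq_len(L)) {
      ctx_flip_apply(ctx, st, flips[[t]])
      lp_mat[w, t + 1L] <- st$lp
    }
  }
  if (stats::var(as.vector(lp_mat)) == 0) {
    warning("log p is constant along all walks; autocorrelation undefined",
            call. = FALSE)
    return(tibble::tibble(lag = 0:L, autocorrelation = NA_real_,
                          n_pairs = NA_integer_))
  }
  ac <- vapply(0:L, function(k) {
    if (k == 0L) return(1)
    x <- as.vector(lp_mat[, seq_len(L + 1L - k)])
    y <- as.vector(lp_mat[, seq_len(L + 1L - k) + k])
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, double(1))
  tibble::tibble(
    lag = 0:L,
    autocorrelation = ac,
    n_pairs = n_walks * (L + 1L - 0:L)
  )
}

#' Census of local minima by repeated steepest descent
#'
#' Runs [steepest_descent()] from uniformly sampled random configurations
#' and tracks the number of *distinct* converged log10 p-values as a
#' function of the number of runs. Two minima count as identical when their
#' log10 p differ by less than `tol`. The growth of the cumulative curve
#' summarizes the landscape's ruggedness.
#'
#' @inheritParams relevant_tfs
#' @param n_runs Number of restarts (default 2000).
#' @param seed Optional integer seed.
#' @param tol Absolute log10 tolerance for identifying two minima
#'   (default 1e-9).
#' @return Object of class `ruggedness_report`: list with `minima_curve`
#'   (tibble `run`, `n_distinct`), `distinct_minima` (tibble `log10_p`,
#'   `multiplicity`), `best` (the lowest minimum's `tf_solution`), `n_runs`
#'   and `tol`.
#' @export
local_minima_census <- function(net, profile, n_runs = 2000, seed = NULL,
                                tol = 1e-9) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- search_context(net, profile)
  finals <- numeric(n_runs)
  best <- NULL
  for (r in seq_len(n_runs)) {
    st <- ctx_state(ctx, ctx_random_sel(ctx))
    sol <- descent_from_state(ctx, st)
    finals[[r]] <- sol$log_p
    if (is.null(best) || sol$log_p < best$log_p) best <- sol
  }
  groups <- group_within_tol(finals, tol)
  first_seen <- !duplicated(groups$id)
  structure(
    list(
      minima_curve = tibble::tibble(run = seq_len(n_runs),
                                    n_distinct = cumsum(first_seen)),
      distinct_minima = tibble::tibble(
        log10_p = groups$levels,
        multiplicity = tabulate(groups$id, nbins = length(groups$levels))
      ),
      best = best,
      n_runs = n_runs,
      tol = tol
    ),
    class = "ruggedness_report"
  )
}

# Cluster scalar values whose sorted gaps are < tol into shared levels.
group_within_tol <- function(x, tol) {
  ord <- order(x)
  xs <- x[ord]
  new_level <- c(TRUE, diff(xs) >= tol)
  level_of_sorted <- cumsum(new_level)
  levels <- xs[new_level]
  id <- integer(length(x))
  id[ord] <- level_of_sorted
  list(id = id, levels = levels)
}

#' @export
print.ruggedness_report <- function(x, ...) {
  cat("<ruggedness_report>: ", nrow(x$distinct_minima),
      " distinct local minima over ", x$n_runs, " descent runs; best log10 p = ",
      format(x$best$log_p, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ruggedness_report <- function(x, ...) {
  x$minima_curve
}

#' @export
glance.ruggedness_report <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    n_distinct_minima = nrow(x$distinct_minima),
    best_log10_p = x$best$log_p,
    best_fraction = x$distinct_minima$multiplicity[[1]] / x$n_runs
  )
}

#' Joint ruggedness assessment
#'
#' Convenience wrapper running both [random_walk_autocorrelation()] and
#' [local_minima_census()] under one seed.
#'
#' @inheritParams local_minima_census
#' @inheritParams random_walk_autocorrelation
#' @return A `ruggedness_report` whose `autocorrelation` field holds the
#'   random-walk curve.
#' @export
assess_ruggedness <- function(net, profile, n_walks = 5000,
                              walk_length = NULL, n_runs = 2000,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ac <- random_walk_autocorrelation(net, profile, n_walks = n_walks,
                                    walk_length = walk_length)
  rep <- local_minima_census(net, profile, n_runs = n_runs)
  rep$autocorrelation <- ac
  rep
}
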