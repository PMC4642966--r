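#' Build the 2x2 enrichment contingency table
#'
#' Cross-classifies the gene universe by membership in a target set and in
#' the DE set: `a` targeted and DE, `b` targeted not DE, `c` DE not
#' targeted, `d` neither. Target genes outside the universe are intersected
#' away first.
#'
#' @param target_set Character vector of target genes.
#' @param profile A [differential_profile()].
#' @return Named list with integer cells `a`, `b`, `c`, `d` and total `M`,
#'   of class `contingency_table`.
#' @export
build_contingency <- function(target_set, profile) {
  stopifnot(inherits(profile, "differential_profile"))
  target_set <- intersect(unique(as.character(target_set)), profile$universe)
  a <- length(intersect(target_set, profile$de_genes))
  b <- length(target_set) - a
  c_ <- profile$n_de - a
  d <- length(profile$universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d, M = a + b + c_ + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      " (M=", x$M, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, d = x$d, M = x$M)
}

# log10 of the upper hypergeometric tail P(X >= a) for a population of M
# with K successes and k draws, summed in log space (log-sum-exp over the
# log pmf) so that p-values far below double-precision linear range remain
# representable. a <= 0 returns 0 (the whole tail, p = 1).
log10_hyper_tail <- function(M, K, k, a) {
  if (a <= 0) return(0)
  xmax <- min(K, k)
  if (a > xmax) {
    stop("overlap a = ", a, " exceeds min(successes, draws)", call. = FALSE)
  }
  x <- a:xmax
  lt <- lchoose(K, x) + lchoose(M - K, k - x) - lchoose(M, k)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0L) return(-Inf)
  m <- max(lt)
  min((m + log(sum(exp(lt - m)))) / log(10), 0)
}

#' One-sided Fisher p-value of a contingency table, in log10
#'
#' Returns `log10 P(X >= a)` for X hypergeometric with population `M`,
#' `a + c` successes and `a + b` draws - the probability that an overlap at
#' least as large as the observed one arises by chance. Computed by
#' log-space tail summation so extreme enrichments (log10 p near -40 and
#' below) never underflow. `a = 0` gives `log10(1) = 0`.
#'
#' @param table A `contingency_table` from [build_contingency()], or any
#'   list/vector with elements `a`, `b`, `c`, `d`.
#' @return A single non-positive number: `log10` of the right-tail p-value.
#' @export
log_fisher_right <- function(table) {
  a <- as.numeric(table[["a"]])
  b <- as.numeric(table[["b"]])
  c_ <- as.numeric(table[["c"]])
  d <- as.numeric(table[["d"]])
  stopifnot(all(is.finite(c(a, b, c_, d))), all(c(a, b, c_, d) >= 0))
  log10_hyper_tail(M = a + b + c_ + d, K = a + c_, k = a + b, a = a)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Number of hypotheses tested (>= 1); here, the number of TFs with
#'   non-zero DE overlap in the profile.
#' @return `min(1, m * p_raw)`, vectorized over `p_raw`.
#' @export
bonferroni <- function(p_raw, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  pmin(1, m * p_raw)
}

# Bonferroni on the log10 scale: log10(min(1, m p)) = min(0, log10 m + lp).
bonferroni_log10 <- function(log10_p, m) {
  pmin(0, log10(m) + log10_p)
}

#' Per-TF ("default") enrichment test
#'
#' The standard approach: each relevant TF's target set is tested separately
#' for over-representation in the DE set with a one-sided Fisher exact test,
#' and p-values are Bonferroni-adjusted over the `m` TFs tested. Only TFs
#' with non-zero DE overlap are tested (a TF with `a = 0` cannot be
#' enriched), and by default `m` equals their count.
#'
#' @inheritParams relevant_tfs
#' @param alpha Significance level in `(0, 1]` applied to the adjusted
#'   p-value with strict `<`.
#' @param m_mode `"overlap"` (default): Bonferroni m = number of relevant
#'   TFs; `"all"`: m = total TF count in the network.
#' @return Tibble of class `tf_enrichment`, one row per tested TF, sorted by
#'   ascending raw p (lexicographic tie-break), with columns `tf`, `a`, `b`,
#'   `c`, `d`, `log10_p`, `p_raw`, `log10_p_adj`, `p_adj`, `significant`.
#'   Attributes `alpha` and `m` record the test setup.
#' @export
default_enrichment <- function(net, profile, alpha = 0.05,
                               m_mode = c("overlap", "all")) {
  m_mode <- match.arg(m_mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  tested <- relevant_tfs(net, profile)
  m <- if (m_mode == "overlap") length(tested) else length(net$tf_ids)
  if (length(tested) == 0L) {
    out <- tibble::tibble(
      tf = character(), a = integer(), b = integer(), c = integer(),
      d = integer(), log10_p = double(), p_raw = double(),
      log10_p_adj = double(), p_adj = double(), significant = logical()
    )
    return(structure(out, class = c("tf_enrichment", class(out)),
                     alpha = alpha, m = m))
  }
  rows <- purrr::map(tested, function(tf) {
    tab <- build_contingency(net$targets_of[[tf]], profile)
    lp <- log_fisher_right(tab)
    tibble::tibble(tf = tf, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                   log10_p = lp)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      p_raw = 10^.data$log10_p,
      log10_p_adj = bonferroni_log10(.data$log10_p, m),
      p_adj = 10^.data$log10_p_adj,
      significant = .data$log10_p_adj < log10(alpha)
    ) |>
    dplyr::arrange(.data$log10_p, .data$tf)
  structure(out, class = c("tf_enrichment", class(out)),
            alpha = alpha, m = m)
}

#' @export
glance.tf_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    m = attr(x, "m"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant),
    min_log10_p = if (nrow(x)) min(x$log10_p) else NA_real_
  )
}

#' Combined log10 p-value of a TF set
#'
#' The objective minimized by every search procedure: the one-sided Fisher
#' log10 p-value of the *union* of the member TFs' target sets against the
#' DE set. The empty set scores 0 (p = 1). No multiple-testing correction is
#' applied inside the search - the combined p is raw.
#'
#' @inheritParams relevant_tfs
#' @param tf_set Character vector of TF identifiers (a set; order
#'   irrelevant). May be empty.
#' @return A single non-positive number: log10 of the combined p-value.
#' @examples
#' net <- regulatory_network(tibble::tibble(
#'   tf = c("a", "a", "b"), gene = c("g1", "g2", "g3")
#' ))
#' prof <- differential_profile(paste0("g", 1:8), c("g1", "g2", "g3"))
#' combined_log_p(net, c("a", "b"), prof) # log10(1/56)
#' @export
combined_log_p <- function(net, tf_set, profile) {
  stopifnot(inherits(net, "regulatory_network"))
  tf_set <- unique(as.character(tf_set))
  if (length(tf_set) == 0L) return(0)
  unknown <- setdiff(tf_set, net$tf_ids)
  if (length(unknown) > 0L) {
    stop("unknown TF identifier(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  union_targets <- unique(unlist(net$targets_of[tf_set], use.names = FALSE))
  log_fisher_right(build_contingency(union_targets, profile))
}
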