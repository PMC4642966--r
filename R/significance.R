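#' Profile-randomization null distribution for the combinatorial p-value
#'
#' The combinatorial search always returns *some* TF combination, so its
#' log10 p needs an objective yardstick. This negative control redistributes
#' the DE label: in each replicate, `n_de` genes are drawn uniformly without
#' replacement from the network's gene set (the universe is held fixed so M
#' is comparable), the search is re-run, and the optimal log10 p recorded.
#' The observed log10 p is standardized against this baseline as a z-score,
#' and a Kolmogorov-Smirnov test (against a normal with the sample's own
#' mean and sd; parameters estimated, so the usual Lilliefors caveat
#' applies) checks that a z-score is a sensible summary.
#'
#' @inheritParams relevant_tfs
#' @param reps Number of null replicates (default 1000; at least 2).
#' @param seed Optional integer seed.
#' @param search Search function `(net, profile) -> tf_solution` used for
#'   both the observed profile and the null replicates (default
#'   [method_c()]).
#' @return Object of class `null_distribution`: list with `log_p_samples`,
#'   `mean`, `sd`, `ks_statistic`, `ks_p`, `observed_log_p`, `z_observed`,
#'   `reps`.
#' @export
randomized_null <- function(net, profile, reps = 1000, seed = NULL,
                            search = method_c) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(net, "regulatory_network"),
            inherits(profile, "differential_profile"))
  if (reps < 2) {
    stop("`reps` must be >= 2: a single replicate has no standard deviation",
         call. = FALSE)
  }
  n <- profile$n_de
  if (n < 1) stop("profile has no DE genes to redistribute", call. = FALSE)
  pool <- intersect(net$gene_ids, profile$universe)
  if (length(pool) < length(net$gene_ids)) {
    warning(length(net$gene_ids) - length(pool), " network gene(s) outside ",
            "the universe are excluded from the null draw", call. = FALSE)
  }
  if (n > length(pool)) {
    stop("n_de = ", n, " exceeds the ", length(pool),
         " network genes available for the null draw", call. = FALSE)
  }
  observed <- search(net, profile)$log_p
  samples <- vapply(seq_len(reps), function(i) {
    de_r <- sample(pool, n)
    prof_r <- differential_profile(profile$universe, de_r,
                                   case_normalize = FALSE)
    search(net, prof_r)$log_p
  }, double(1))
  mu <- mean(samples)
  sdev <- sd(samples)
  z_obs <- if (is.finite(sdev) && sdev > 0) {
    null_zscore(observed, mu, sdev)
  } else {
    warning("null log p-values are constant across replicates; ",
            "z-score undefined", call. = FALSE)
    NA_real_
  }
  ks <- suppressWarnings(ks.test(samples, "pnorm", mean = mu, sd = sdev))
  structure(
    list(log_p_samples = samples, mean = mu, sd = sdev,
         ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         observed_log_p = observed,
         z_observed = z_obs,
         reps = reps),
    class = "null_distribution"
  )
}

#' Standardize an observed log10 p against a null distribution
#'
#' @param observed_log_p Observed combinatorial log10 p-value.
#' @param null A `null_distribution` from [randomized_null()], or the null
#'   mean (with `sd` supplied as the third argument).
#' @param sd Null standard deviation when `null` is given as a mean.
#' @return `(observed - mean) / sd`; negative values mean the observed
#'   profile is more significant than random relabelings.
#' @export
null_zscore <- function(observed_log_p, null, sd = NULL) {
  if (inherits(null, "null_distribution")) {
    mu <- null$mean
    sdev <- null$sd
  } else {
    mu <- null
    sdev <- sd
  }
  if (is.null(sdev) || !is.finite(sdev) || sdev <= 0) {
    stop("null distribution has no positive standard deviation; ",
         "z-score undefined", call. = FALSE)
  }
  (observed_log_p - mu) / sdev
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>: ", x$reps, " replicates, mean = ",
      format(x$mean, digits = 4), ", sd = ", format(x$sd, digits = 4),
      "\n  observed log10 p = ", format(x$observed_log_p, digits = 6),
      "  z = ", format(x$z_observed, digits = 4),
      "  (K-S normality p = ", format(x$ks_p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$log_p_samples),
                 log10_p = x$log_p_samples)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(reps = x$reps, mean = x$mean, sd = x$sd,
                 ks_statistic = x$ks_statistic, ks_p = x$ks_p,
                 observed_log10_p = x$observed_log_p,
                 z_observed = x$z_observed)
}
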