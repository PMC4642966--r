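#' Simulated-annealing configuration
#'
#' Parameters of the exponential (geometric) cooling schedule
#' `T[n+1] = r * T[n]`. The schedule length and cooling factor are linked:
#' given `T_i`, `T_f` and `r`, the number of steps is
#' `N_SA = ceiling(log(T_f / T_i) / log(r))`; conversely a requested `N_SA`
#' implies `r = (T_f / T_i)^(1 / N_SA)`. By default the initial temperature
#' is calibrated from the landscape (see
#' [calibrate_initial_temperature()]), the final temperature is fixed at
#' 0.01, and a grid of schedule lengths `{5, 10, 15, 20, 25} * N` is run
#' with 10 independent restarts each.
#'
#' @param t_initial Initial temperature (> 0), or `NULL` to calibrate at run
#'   time.
#' @param t_final Final temperature (default 0.01).
#' @param r Geometric cooling factor in (0, 1); overrides
#'   `schedule_multipliers` when given.
#' @param n_steps Total steps in one run; overrides `schedule_multipliers`
#'   when given.
#' @param runs_per_schedule Independent restarts per schedule (default 10).
#' @param schedule_multipliers Schedule lengths as multiples of N (default
#'   `c(5, 10, 15, 20, 25)`).
#' @return Object of class `annealing_config`.
#' @export
annealing_config <- function(t_initial = NULL, t_final = 0.01, r = NULL,
                             n_steps = NULL, runs_per_schedule = 10,
                             schedule_multipliers = c(5, 10, 15, 20, 25)) {
  if (!is.null(t_initial) && (!is.numeric(t_initial) || t_initial <= 0)) {
    stop("`t_initial` must be a positive number", call. = FALSE)
  }
  stopifnot(is.numeric(t_final), t_final > 0)
  if (!is.null(t_initial) && t_final >= t_initial) {
    stop("`t_final` must be below `t_initial`", call. = FALSE)
  }
  if (!is.null(r) && (!is.numeric(r) || r <= 0 || r >= 1)) {
    stop("cooling factor `r` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(n_steps) && (!is.numeric(n_steps) || n_steps < 1)) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  stopifnot(runs_per_schedule >= 1, length(schedule_multipliers) >= 1,
            all(schedule_multipliers > 0))
  structure(
    list(t_initial = t_initial, t_final = t_final, r = r,
         n_steps = n_steps, runs_per_schedule = as.integer(runs_per_schedule),
         schedule_multipliers = schedule_multipliers),
    class = "annealing_config"
  )
}

#' Schedule length implied by a cooling factor
#'
#' `N_SA = ceiling(log(T_f / T_i) / log(r))` for the geometric schedule.
#'
#' @param t_initial,t_final Initial and final temperatures.
#' @param r Cooling factor in (0, 1).
#' @return Integer number of steps.
#' @examples
#' sa_schedule_length(1, 0.01, 0.9) # 44
#' @export
sa_schedule_length <- function(t_initial, t_final, r) {
  stopifnot(t_final < t_initial, r > 0, r < 1)
  as.integer(ceiling(log(t_final / t_initial) / log(r)))
}

# Metropolis acceptance for a proposed change in log10 p at temperature T.
# The exponent uses natural-log p-value differences, so log10 deltas are
# scaled by ln(10).
sa_acceptance_prob <- function(delta_log10_p, temperature) {
  delta <- delta_log10_p * log(10)
  min(1, exp(-delta / temperature))
}

# T_i such that exp(-D / T_i) = target_accept for mean worsening step D
# (natural-log units).
t_initial_from_mean_delta <- function(mean_delta, target_accept) {
  stopifnot(target_accept > 0, target_accept < 1)
  mean_delta / log(1 / target_accept)
}

#' Calibrate the initial annealing temperature
#'
#' Samples random configurations, draws one random worsening single-TF move
#' from each (states with no worsening neighbor are skipped), and sets
#' `T_i = D / ln(1 / target_accept)` where D is the mean worsening step in
#' natural-log p-value units - so the average initial acceptance probability
#' for non-optimal jumps is `target_accept`.
#'
#' @inheritParams relevant_tfs
#' @param n_probe Number of probe configurations (default 100).
#' @param target_accept Desired initial acceptance probability for worsening
#'   moves (default 0.8).
#' @param seed Optional integer seed.
#' @return A positive temperature. If no worsening move exists anywhere the
#'   landscape is monotone and `T_i = 1` is returned with a warning; the
#'   result is capped at 1e6 (with a warning) as `target_accept` approaches
#'   1.
#' @export
calibrate_initial_temperature <- function(net, profile, n_probe = 100,
                                          target_accept = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target_accept > 0, target_accept < 1)
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  deltas <- numeric(0)
  for (i in seq_len(n_probe)) {
    st <- ctx_state(ctx, ctx_random_sel(ctx))
    d <- vapply(seq_len(ctx$N), function(j) ctx_flip_lp(ctx, st, j) - st$lp,
                double(1))
    worse <- d[d > 0]
    if (length(worse) > 0L) {
      deltas <- c(deltas, worse[[sample.int(length(worse), 1L)]] * log(10))
    }
  }
  if (length(deltas) == 0L) {
    warning("no worsening move found in any probe; landscape appears ",
            "monotone, using T_i = 1", call. = FALSE)
    return(1)
  }
  t_i <- t_initial_from_mean_delta(mean(deltas), target_accept)
  if (t_i > 1e6) {
    warning("calibrated T_i exceeds 1e6; capping", call. = FALSE)
    t_i <- 1e6
  }
  t_i
}

#' Simulated annealing over TF combinations
#'
#' Stochastic search that escapes local minima by accepting worsening moves
#' with probability `exp(-delta(log p) / T)` under the geometric cooling
#' schedule of [annealing_config()]. Each run starts from a uniform random
#' configuration and proposes one uniformly chosen single-TF flip per step;
#' improving or neutral moves are always accepted. The best state visited
#' during a run is polished with [steepest_descent()] after the schedule
#' ends, and the best polished state across the whole grid (schedule
#' multipliers x restarts) is returned.
#'
#' @inheritParams relevant_tfs
#' @param config An [annealing_config()].
#' @param seed Optional integer seed (fixes the whole grid).
#' @return A `tf_solution` with method `"sa"`; `trace` is the polishing
#'   descent trace of the winning run, and fields `t_initial` and
#'   `grid` (tibble: one row per run with `n_steps`, `r`, `run`,
#'   `best_log10_p`) document the search.
#' @export
simulated_annealing <- function(net, profile, config = annealing_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "annealing_config"))
  ctx <- search_context(net, profile)
  ctx_require_relevant(ctx)
  t_f <- config$t_final
  t_i <- config$t_initial %||%
    calibrate_initial_temperature(net, profile)
  if (t_f >= t_i) {
    stop("final temperature ", t_f, " is not below initial temperature ",
         format(t_i), call. = FALSE)
  }
  lengths <- if (!is.null(config$n_steps)) {
    as.integer(config$n_steps)
  } else if (!is.null(config$r)) {
    sa_schedule_length(t_i, t_f, config$r)
  } else {
    as.integer(ceiling(config$schedule_multipliers * ctx$N))
  }
  best_overall <- NULL
  grid <- list()
  for (n_sa in lengths) {
    r <- (t_f / t_i)^(1 / n_sa)
    for (run in seq_len(config$runs_per_schedule)) {
      st <- ctx_state(ctx, ctx_random_sel(ctx))
      best_lp <- st$lp
      best_sel <- st$sel
      temp <- t_i
      for (step in seq_len(n_sa)) {
        j <- sample.int(ctx$N, 1L)
        delta <- ctx_flip_lp(ctx, st, j) - st$lp
        if (delta <= 0 || runif(1) < sa_acceptance_prob(delta, temp)) {
          ctx_flip_apply(ctx, st, j)
          if (st$lp < best_lp) {
            best_lp <- st$lp
            best_sel <- st$sel
          }
        }
        temp <- temp * r
      }
      polished <- descent_from_state(ctx, ctx_state(ctx, best_sel))
      grid[[length(grid) + 1L]] <- tibble::tibble(
        n_steps = n_sa, r = r, run = run, best_log10_p = polished$log_p
      )
      if (is.null(best_overall) || polished$log_p < best_overall$log_p) {
        best_overall <- polished
      }
    }
  }
  new_tf_solution(best_overall$tfs, best_overall$log_p, best_overall$trace,
                  "sa", ctx$N, t_initial = t_i,
                  grid = dplyr::bind_rows(grid))
}
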