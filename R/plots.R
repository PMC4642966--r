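#' @export
autoplot.tf_solution <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$log10_p)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "accepted update",
      y = expression(log[10] ~ "combined p-value"),
      title = paste0("Search trace (method ", object$method, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tf_enrichment <- function(object, top_n = 20, ...) {
  df <- head(tibble::as_tibble(object), top_n)
  df$tf <- factor(df$tf, levels = rev(df$tf))
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$log10_p_adj, y = .data$tf,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ruggedness_report <- function(object, ...) {
  ggplot2::ggplot(object$minima_curve,
                  ggplot2::aes(x = .data$run, y = .data$n_distinct)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "descent runs", y = "distinct local minima",
                  title = "Local-minima census") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_distribution <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$log10_p)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_log_p,
                        color = "red") +
    ggplot2::labs(
      x = expression(log[10] ~ "combined p (randomized profiles)"),
      y = "replicates",
      title = sprintf("Randomization null (z = %.2f)", object$z_observed)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- object$per_tf |>
    dplyr::arrange(.data$out_degree) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    tidyr::pivot_longer(
      cols = c("freq_input", "freq_default", "freq_combo"),
      names_to = "set", names_prefix = "freq_", values_to = "frequency"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$frequency,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(input = "forestgreen",
                                           default = "firebrick",
                                           combo = "steelblue")) +
    ggplot2::labs(x = "TFs ranked by out-degree",
                  y = "occurrence frequency", color = NULL,
                  title = "TF occurrence: input vs recovered") +
    ggplot2::theme_minimal()
}
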