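#' Plot a benchmark report
#'
#' The benchmark figure layout: one panel per metric (call rate, error
#' rate), points at the per-cell median with bars spanning the
#' minimum-maximum range over replicate samples, against the
#' observed-genotype ladder (or against the calling threshold when the
#' design has a single observed count), coloured by calling threshold.
#'
#' @param object a `benchmark_report`.
#' @param metrics which metrics to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.benchmark_report <- function(object,
                                      metrics = c("call_rate", "error_rate"),
                                      ...) {
  agg <- object$aggregates
  long <- agg |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(paste0(rep(metrics, each = 3),
                                  c("_median", "_min", "_max"))),
      names_to = c("metric", "stat"),
      names_pattern = "(.*)_(median|min|max)"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  single_count <- length(unique(agg$n_observed_target)) == 1
  if (single_count) {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$q_gp),
                                            y = .data$median))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n_observed_target,
                                            y = .data$median,
                                            colour = factor(.data$q_gp))) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(colour = "GP threshold")
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min,
                                          ymax = .data$max),
                             position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = if (single_count) "GP calling threshold" else "observed genotypes",
      y = "median (bars: min-max over replicates)"
    ) +
    ggplot2::theme_bw()
}

#' Plot a posterior field
#'
#' Genotype-probability (gp) track along the chromosome, distinguishing
#' observed from unobserved sites when an observation is supplied.
#'
#' @param object a `posterior_field`.
#' @param obs optional [observed_genotypes] used to colour sites by
#'   observed/missing status.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.posterior_field <- function(object, obs = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$status <- if (!is.null(obs)) {
    ifelse(is.na(obs$g_obs), "missing (imputed)", "observed")
  } else {
    "site"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$gp,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "position (bp)", y = "genotype probability (gp)") +
    ggplot2::theme_bw()
}

#' Plot an error-mode comparison
#'
#' @param object an `error_mode_comparison`.
#' @param q_gp calling threshold to display (default the largest).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.error_mode_comparison <- function(object, q_gp = NULL, ...) {
  agg <- object$aggregates
  if (is.null(q_gp)) q_gp <- max(agg$q_gp)
  agg <- dplyr::filter(agg, .data$q_gp == !!q_gp)
  long <- agg |>
    tidyr::pivot_longer(
      cols = c("call_rate_median", "error_rate_median"),
      names_to = "metric", values_to = "median"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_observed_target,
                                     y = .data$median,
                                     colour = .data$error_mode)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "observed genotypes", colour = "error mode",
                  y = paste0("median at q_gp = ", q_gp)) +
    ggplot2::theme_bw()
}
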