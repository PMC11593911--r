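#' Tidy a benchmark report
#'
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return the aggregate table: one row per design cell x threshold with
#'   median/min/max call rate, error rate and imputed-genotype count.
#' @export
tidy.benchmark_report <- function(x, ...) {
  x$aggregates
}

#' @rdname tidy.benchmark_report
#' @return for `glance()`, a one-row tibble summarising the run: design
#'   size, replicate count, and the median call/error rate at the highest
#'   calling threshold.
#' @export
glance.benchmark_report <- function(x, ...) {
  q_top <- max(x$config$thresholds)
  top <- dplyr::filter(x$aggregates, .data$q_gp == q_top)
  tibble::tibble(
    n_cells = nrow(x$aggregates),
    n_records = nrow(x$records),
    n_replicates = x$config$n_replicates,
    q_top = q_top,
    call_rate_median_top = median(top$call_rate_median),
    error_rate_median_top = median(top$error_rate_median),
    seed = x$config$seed
  )
}

#' Tidy called genotypes into a per-site tibble
#'
#' @param x a `called_genotypes` object.
#' @param ... unused.
#' @return a tibble with site coordinates, genotype, call source and gp.
#' @export
tidy.called_genotypes <- function(x, ...) {
  tibble::tibble(
    chrom = x$sites$chrom, pos = x$sites$pos,
    g = x$g, source = x$source, gp = x$gp,
    unimputable = x$unimputable
  )
}

#' Tidy an error-mode comparison
#'
#' @param x an `error_mode_comparison`.
#' @param ... unused.
#' @return the combined aggregate table over the three error modes.
#' @export
tidy.error_mode_comparison <- function(x, ...) {
  x$aggregates
}

#' Tidy a panel-composition comparison
#'
#' @param x a `panel_comparison`.
#' @param ... unused.
#' @return the per-cell delta table (excluded minus included scenario).
#' @export
tidy.panel_comparison <- function(x, ...) {
  x$deltas
}
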