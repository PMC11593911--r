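#' Score a called genotype set against the truth
#'
#' Computes the two benchmark metrics over the target site list:
#' call rate = (observed + imputed genotypes) / total targeted genotypes,
#' and error rate = erroneous assigned genotypes / (observed + imputed
#' genotypes).  By default the error numerator counts every assigned
#' genotype that differs from the truth — wrong imputed calls *and*
#' injected observed errors; set `include_observed_errors = FALSE` to
#' restrict it to imputed sites (sensitivity analysis).  An empty
#' denominator yields an error rate of 0 with a warning.  All counts are
#' exact integers.
#'
#' @param called a `called_genotypes` object (from [call_imputed()] /
#'   [impute_sample()]).
#' @param truth the matching [truth_genotypes] object.
#' @param include_observed_errors count observed-but-wrong genotypes in
#'   the error numerator (default `TRUE`).
#' @param labels named list of condition labels (observed count,
#'   threshold, error mode, scenario, replicate, ...) appended as columns.
#' @return a one-row tibble (a metrics record) with columns `n_total`,
#'   `n_observed`, `n_imputed`, `n_erroneous`, `call_rate`, `error_rate`
#'   plus any label columns.
#' @export
score_sample <- function(called, truth, include_observed_errors = TRUE,
                         labels = list()) {
  if (length(called$g) != length(truth$g) ||
      !identical(as.integer(called$sites$pos), as.integer(truth$sites$pos))) {
    stop("site-list mismatch between called genotypes and truth")
  }
  n_total <- length(truth$g)
  obs_mask <- !is.na(called$source) & called$source == "OBSERVED"
  imp_mask <- !is.na(called$source) & called$source == "IMPUTED"
  n_obs <- sum(obs_mask)
  n_imp <- sum(imp_mask)
  wrong <- !is.na(called$g) & called$g != truth$g
  n_err <- if (include_observed_errors) sum(wrong) else sum(wrong & imp_mask)
  denom <- n_obs + n_imp
  error_rate <- if (denom == 0) {
    if (n_total > 0) warning("no assigned genotypes; error rate defined as 0")
    0
  } else {
    n_err / denom
  }
  out <- tibble::tibble(
    n_total = n_total, n_observed = n_obs, n_imputed = n_imp,
    n_erroneous = n_err,
    call_rate = if (n_total == 0) 0 else denom / n_total,
    error_rate = error_rate
  )
  if (length(labels) > 0) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(labels))
  }
  out
}

#' Sweep genotype-probability calling thresholds over one posterior
#'
#' Re-calls and re-scores a single posterior at each threshold, so the
#' (expensive) forward-backward computation is done once.  The number of
#' imputed genotypes and the call rate are non-increasing in the
#' threshold by construction of the inclusive `>=` calling rule.
#'
#' @param post a `posterior_field`.
#' @param obs the matching [observed_genotypes].
#' @param truth the matching [truth_genotypes].
#' @param thresholds numeric thresholds in `[0, 1]` (default the
#'   benchmark grid 0.5 / 0.9 / 0.95 / 0.99).
#' @param include_observed_errors passed to [score_sample()].
#' @param labels condition labels appended to every record.
#' @return a tibble with one metrics record per threshold (column `q_gp`).
#' @export
threshold_sweep <- function(post, obs, truth,
                            thresholds = c(0.5, 0.9, 0.95, 0.99),
                            include_observed_errors = TRUE, labels = list()) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  purrr::map_dfr(thresholds, function(q) {
    called <- call_imputed(post, obs, q_gp = q)
    score_sample(called, truth,
                 include_observed_errors = include_observed_errors,
                 labels = c(list(q_gp = q), labels))
  })
}

#' Aggregate replicate metrics records into median / min / max
#'
#' The benchmark reports per-condition medians with minimum and maximum
#' over the replicate test samples (the median of an even count is the
#' mean of the central pair, as with [stats::median()]).
#'
#' @param records a tibble of metrics records ([score_sample()] rows).
#' @param by character vector of grouping columns; defaults to every
#'   label column except replicate identifiers (`replicate`, `sample`,
#'   `seed`).
#' @return a tibble with one row per condition: `n_samples` and
#'   median/min/max of `call_rate`, `error_rate` and `n_imputed`.
#' @export
aggregate_samples <- function(records, by = NULL) {
  if (nrow(records) == 0) stop("no records to aggregate")
  metric_cols <- c("n_total", "n_observed", "n_imputed", "n_erroneous",
                   "call_rate", "error_rate")
  if (is.null(by)) {
    by <- setdiff(names(records), c(metric_cols, "replicate", "sample", "seed"))
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      call_rate_median = median(.data$call_rate),
      call_rate_min = min(.data$call_rate),
      call_rate_max = max(.data$call_rate),
      error_rate_median = median(.data$error_rate),
      error_rate_min = min(.data$error_rate),
      error_rate_max = max(.data$error_rate),
      n_imputed_median = median(.data$n_imputed),
      n_imputed_min = min(.data$n_imputed),
      n_imputed_max = max(.data$n_imputed),
      .groups = "drop"
    )
  out
}

#' Extrapolate single-chromosome counts to a genome-wide target set
#'
#' The bench runs on one synthetic chromosome; results are extrapolated
#' linearly to the full target count (the study's 1.3 million SNPs by
#' default).  Counts are scaled by `n_total_genome / n_total` and rounded
#' to the nearest integer; rates are unchanged by construction.  Real
#' chromosomes differ, so genuine chromosome-to-genome extrapolation
#' carries model error of the order of 10%.
#'
#' @param rec a one-row metrics record (or a tibble of them).
#' @param n_total_genome genome-wide target genotype count.
#' @return the record(s) with scaled counts and `extrapolated = TRUE`.
#' @export
extrapolate_genome <- function(rec, n_total_genome = 1300000) {
  if (any(rec$n_total <= 0)) stop("cannot extrapolate a zero-size record")
  f <- n_total_genome / rec$n_total
  rec |>
    dplyr::mutate(
      n_total = as.integer(round(.data$n_total * f)),
      n_observed = as.integer(round(.data$n_observed * f)),
      n_imputed = as.integer(round(.data$n_imputed * f)),
      n_erroneous = as.integer(round(.data$n_erroneous * f)),
      extrapolated = TRUE
    )
}

#' Compare matched panel-composition scenarios
#'
#' Signed differences (excluded minus included) of the aggregated median
#' call rate and error rate between two runs that differ only in
#' reference-panel composition — e.g. the target's population present in
#' vs absent from the panel.  No significance test is attached.
#'
#' @param agg_with aggregate tibble for the reference scenario (panel
#'   includes the focal population).
#' @param agg_without aggregate tibble for the comparison scenario (focal
#'   population excluded), with identical design columns.
#' @param by columns identifying the design cell (default: the shared
#'   non-metric columns).
#' @return a tibble with per-cell deltas `d_call_rate_median` and
#'   `d_error_rate_median` (without minus with).
#' @export
compare_panel_scenarios <- function(agg_with, agg_without, by = NULL) {
  stat_cols <- c("n_samples", "call_rate_median", "call_rate_min",
                 "call_rate_max", "error_rate_median", "error_rate_min",
                 "error_rate_max", "n_imputed_median", "n_imputed_min",
                 "n_imputed_max")
  if (is.null(by)) {
    by <- setdiff(intersect(names(agg_with), names(agg_without)),
                  c(stat_cols, "scenario"))
  }
  a <- dplyr::select(agg_with, dplyr::all_of(c(by, "call_rate_median",
                                               "error_rate_median")))
  b <- dplyr::select(agg_without, dplyr::all_of(c(by, "call_rate_median",
                                                  "error_rate_median")))
  j <- dplyr::inner_join(a, b, by = by, suffix = c("_with", "_without"))
  if (nrow(j) == 0) stop("no matching design cells between the scenarios")
  j |>
    dplyr::mutate(
      d_call_rate_median = .data$call_rate_median_without -
        .data$call_rate_median_with,
      d_error_rate_median = .data$error_rate_median_without -
        .data$error_rate_median_with
    )
}
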