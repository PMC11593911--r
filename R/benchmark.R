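#' Benchmark configuration
#'
#' One object describes a full design matrix at desk scale: the synthetic
#' panel geometry, the observed-count (or observed-fraction) ladder, the
#' calling thresholds, the error mode, the population scenario and the
#' replicate count.  The defaults are the package's scaled-down version
#' of the study design: one synthetic chromosome of 20,000 target sites
#' standing in for chromosome 22's share of a 1.3 M-SNP genome-wide
#' target set (all counts divided by ~65, so the 4k-300k observed ladder
#' becomes 400-10,000), 10 replicate samples per design cell, calling
#' thresholds {0.5, 0.9, 0.95, 0.99} and drop-in/drop-out rates of 0.1.
#'
#' @param n_sites number of target SNP sites on the synthetic chromosome.
#' @param n_founders founder haplotypes for the panel simulation.
#' @param n_haplotypes reference-panel haplotypes (per population when a
#'   population scenario is set).
#' @param n_generations mosaic depth controlling panel LD.  The default
#'   geometry (20 founders expanded to 100 panel haplotypes at depth 50
#'   per Morgan) gives every ancestral segment ~5 carriers in the panel —
#'   the haplotype sharing that makes imputation possible — with ~2 cM
#'   founder tracks.
#' @param maf_min,beta_shape1,beta_shape2 founder frequency-spectrum
#'   controls (see [simulate_founders()]).
#' @param bp_per_site,rate_cm_per_mb physical spacing and map rate.
#' @param observed_counts ladder of observed-genotype counts.
#' @param fractions optional ladder of observed fractions (WGS-style
#'   cells), used alongside or instead of `observed_counts`.
#' @param thresholds genotype-probability calling thresholds.
#' @param error_mode `"none"`, `"dropin"` or `"dropout"`.
#' @param dropin_rate,dropout_rate error-injection rates.
#' @param populations optional population scenario: a list with
#'   `n_pops`, `divergence`, optional `sizes`, optional `focal`
#'   (population the test samples come from, default the first) and
#'   `exclude_focal` (drop the focal population from the reference panel).
#' @param n_replicates replicate test samples per design cell.
#' @param ne,eps imputation-engine parameters (see [hmm_params()]).  The
#'   benchmark default `ne = 2500` matches the copying model's switch
#'   intensity (`4 ne / k` per Morgan) to the panel's effective
#'   segment-break rate (both the target's and the template's mosaics
#'   break, i.e. ~`2 * n_generations` per Morgan), which keeps the
#'   genotype-probability scores calibrated on the synthetic panels.
#' @param include_observed_errors error-rate numerator mode (see
#'   [score_sample()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_sites = 20000, n_founders = 20,
                             n_haplotypes = 100, n_generations = 50,
                             maf_min = 0.05, beta_shape1 = 0.8,
                             beta_shape2 = 0.8, bp_per_site = 1750,
                             rate_cm_per_mb = 1.2,
                             observed_counts = c(400, 1000, 2000, 5000, 10000),
                             fractions = NULL,
                             thresholds = c(0.5, 0.9, 0.95, 0.99),
                             error_mode = c("none", "dropin", "dropout"),
                             dropin_rate = 0.1, dropout_rate = 0.1,
                             populations = NULL, n_replicates = 10,
                             ne = 2500, eps = 1e-3,
                             include_observed_errors = TRUE, seed = 1) {
  error_mode <- match.arg(error_mode)
  if (!is.null(observed_counts) && any(observed_counts > n_sites)) {
    stop("infeasible geometry: observed count exceeds n_sites")
  }
  if (!is.null(fractions) && any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  stopifnot(all(thresholds >= 0), all(thresholds <= 1), n_replicates >= 1)
  if (!is.null(populations)) {
    populations$n_pops <- populations$n_pops %||% 2
    populations$divergence <- populations$divergence %||% 0.1
    populations$sizes <- populations$sizes %||%
      rep(n_haplotypes, populations$n_pops)
    populations$focal <- populations$focal %||% "POP1"
    populations$exclude_focal <- isTRUE(populations$exclude_focal)
  }
  structure(
    list(n_sites = n_sites, n_founders = n_founders,
         n_haplotypes = n_haplotypes, n_generations = n_generations,
         maf_min = maf_min, beta_shape1 = beta_shape1,
         beta_shape2 = beta_shape2, bp_per_site = bp_per_site,
         rate_cm_per_mb = rate_cm_per_mb,
         observed_counts = observed_counts, fractions = fractions,
         thresholds = thresholds, error_mode = error_mode,
         dropin_rate = dropin_rate, dropout_rate = dropout_rate,
         populations = populations, n_replicates = n_replicates,
         ne = ne, eps = eps,
         include_observed_errors = include_observed_errors, seed = seed),
    class = "benchmark_config"
  )
}

#' Read a benchmark configuration from a YAML file
#'
#' Flat keys matching the arguments of [benchmark_config()]; a nested
#' `populations` block configures the population scenario.
#'
#' @param path YAML file path.
#' @return a `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(benchmark_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(benchmark_config, vals)
}

# Build the panel for a config (deterministic given config$seed).
build_benchmark_panel <- function(config) {
  founders <- simulate_founders(
    config$n_founders, config$n_sites, maf_min = config$maf_min,
    beta_shape1 = config$beta_shape1, beta_shape2 = config$beta_shape2,
    bp_per_site = config$bp_per_site,
    rate_cm_per_mb = config$rate_cm_per_mb,
    seed = derive_seed(config$seed, "founders")
  )
  if (is.null(config$populations)) {
    recombine_panel(founders, config$n_haplotypes,
                    n_generations = config$n_generations,
                    seed = derive_seed(config$seed, "panel"))
  } else {
    p <- config$populations
    split_populations(founders, n_pops = p$n_pops,
                      divergence = p$divergence, sizes = p$sizes,
                      n_generations = config$n_generations,
                      seed = derive_seed(config$seed, "panel"))
  }
}

benchmark_cells <- function(config) {
  cells <- tibble::tibble(n_target = integer(), fraction = numeric())
  if (!is.null(config$observed_counts)) {
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      n_target = as.integer(config$observed_counts), fraction = NA_real_))
  }
  if (!is.null(config$fractions)) {
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      n_target = as.integer(round(config$fractions * config$n_sites)),
      fraction = config$fractions))
  }
  if (nrow(cells) == 0) stop("config defines no design cells")
  cells
}

#' Run the full benchmark design matrix
#'
#' For every design cell: simulate the panel, draw replicate truth
#' individuals (whose haplotypes are removed from the reference), degrade
#' (prune + error injection), impute with the copying HMM, sweep the
#' calling thresholds on the single posterior, score against truth, and
#' aggregate median/min/max over replicates.  Fully deterministic under
#' the master seed: each stage of each cell/replicate uses a child seed
#' from [derive_seed()], so any cell can be reproduced in isolation, and
#' removing a cell does not change another cell's numbers.
#'
#' @param config a [benchmark_config()].
#' @param progress print per-cell progress lines (default `FALSE`).
#' @return a `benchmark_report`: list with `config`, `records` (one
#'   metrics row per replicate x cell x threshold) and `aggregates`
#'   (median/min/max per cell x threshold).
#' @export
run_benchmark <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  panel <- build_benchmark_panel(config)
  cells <- benchmark_cells(config)
  params <- hmm_params(ne = config$ne, eps = config$eps)
  focal <- if (is.null(config$populations)) "any" else
    config$populations$focal
  exclude_focal <- !is.null(config$populations) &&
    config$populations$exclude_focal
  scenario <- if (is.null(config$populations)) "single_pop" else
    paste0(if (exclude_focal) "noFOCAL" else "FOCAL")
  records <- vector("list", config$n_replicates)
  for (rep_i in seq_len(config$n_replicates)) {
    draw <- sample_truth_individual(panel, pop = focal,
                                    seed = derive_seed(config$seed, "sample", rep_i))
    reference <- drop_haplotypes(panel, draw$exclude)
    if (exclude_focal) {
      reference <- drop_haplotypes(reference, which(reference$pop == focal))
    }
    cell_recs <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      obs <- degrade(draw$truth, n_target = cells$n_target[ci],
                     error_mode = config$error_mode,
                     dropin_rate = config$dropin_rate,
                     dropout_rate = config$dropout_rate,
                     seed = derive_seed(config$seed, "degrade",
                                        cells$n_target[ci],
                                        !is.na(cells$fraction[ci]), rep_i))
      post <- forward_backward(reference, obs, params = params)
      cell_recs[[ci]] <- threshold_sweep(
        post, obs, draw$truth, thresholds = config$thresholds,
        include_observed_errors = config$include_observed_errors,
        labels = list(n_observed_target = cells$n_target[ci],
                      fraction = cells$fraction[ci],
                      error_mode = config$error_mode,
                      scenario = scenario, replicate = rep_i))
      if (progress) {
        message("replicate ", rep_i, " cell ", ci, "/", nrow(cells),
                " (", cells$n_target[ci], " observed) done")
      }
    }
    records[[rep_i]] <- dplyr::bind_rows(cell_recs)
  }
  records <- dplyr::bind_rows(records)
  aggregates <- aggregate_samples(records)
  structure(list(config = config, records = records,
                 aggregates = aggregates),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$records), " records over ",
      nrow(x$aggregates), " design cells (seed ", x$config$seed, ")\n",
      sep = "")
  print(x$aggregates, n = 12)
  invisible(x)
}

#' Compare error modes with matched seeds
#'
#' Runs the design matrix three times — no errors, allelic drop-in,
#' allelic drop-out — sharing the panel, truth-sample and pruning seeds,
#' so the three runs differ only in the injected errors.
#'
#' @param config a [benchmark_config()]; its `error_mode` is ignored.
#' @param modes error modes to compare.
#' @return a list of class `error_mode_comparison` with one
#'   `benchmark_report` per mode (`$reports`) and a combined aggregate
#'   table (`$aggregates`).
#' @export
run_error_mode_comparison <- function(config,
                                      modes = c("none", "dropin", "dropout")) {
  reports <- lapply(modes, function(mode) {
    cfg <- config
    cfg$error_mode <- mode
    run_benchmark(cfg)
  })
  names(reports) <- modes
  aggregates <- dplyr::bind_rows(lapply(reports, function(r) r$aggregates))
  structure(list(reports = reports, aggregates = aggregates),
            class = "error_mode_comparison")
}

#' Compare panel-composition scenarios with matched seeds
#'
#' Runs a two-population design twice: once with the full reference panel
#' and once with the test samples' own (focal) population excluded from
#' it.  Panel, truth samples and degradation share seeds, so the runs
#' differ only in reference composition.
#'
#' @param config a [benchmark_config()] whose `populations` block is set;
#'   `exclude_focal` is overridden per scenario.
#' @return a list of class `panel_comparison` with both reports and the
#'   per-cell deltas from [compare_panel_scenarios()].
#' @export
run_panel_comparison <- function(config) {
  if (is.null(config$populations)) {
    stop("config must define a population scenario")
  }
  cfg_with <- cfg_without <- config
  cfg_with$populations$exclude_focal <- FALSE
  cfg_without$populations$exclude_focal <- TRUE
  rep_with <- run_benchmark(cfg_with)
  rep_without <- run_benchmark(cfg_without)
  deltas <- compare_panel_scenarios(rep_with$aggregates,
                                    rep_without$aggregates,
                                    by = c("n_observed_target", "q_gp",
                                           "error_mode"))
  structure(list(included = rep_with, excluded = rep_without,
                 deltas = deltas),
            class = "panel_comparison")
}

#' Write a benchmark report to disk
#'
#' Emits tidy delimited tables (`records.tsv`, `aggregates.tsv`) and a
#' machine-readable JSON summary (`report.json`) containing the
#' configuration and the aggregate table.  Output is byte-identical for
#' identical configurations and seeds.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$records, file.path(dir, "records.tsv"))
  readr::write_tsv(report$aggregates, file.path(dir, "aggregates.tsv"))
  cfg <- report$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, aggregates = report$aggregates),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
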