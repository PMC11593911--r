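#' Diploid genotype containers
#'
#' `truth_genotypes` holds a sample's complete true genotypes over the
#' target site list (alt-allele counts 0/1/2, no missing values).
#' `observed_genotypes` holds the degraded observation of a truth set:
#' genotypes are `NA` where missing, and every non-missing site carries a
#' provenance tag — `"OBSERVED"` (agrees with truth), `"OBSERVED_ERRONEOUS"`
#' (an injected error), or `"MISSING"`.  When the truth is known it is kept
#' alongside (`g_truth`) so provenance stays exact even when several error
#' injections are chained; objects read back from VCF carry provenance only.
#'
#' @param sites site tibble (as in [haplotype_panel()]).
#' @param g integer vector of alt-allele counts in `{0, 1, 2}`.
#' @return a `truth_genotypes` object.
#' @export
truth_genotypes <- function(sites, g) {
  sites <- tibble::as_tibble(sites)
  g <- as.integer(g)
  stopifnot(length(g) == nrow(sites))
  if (anyNA(g) || any(g < 0L | g > 2L)) {
    stop("truth genotypes must be 0/1/2 with no missing values")
  }
  structure(list(sites = sites, g = g), class = "truth_genotypes")
}

#' @export
print.truth_genotypes <- function(x, ...) {
  cat("<truth_genotypes> ", length(x$g), " sites; genotype counts: ",
      paste(names(table(x$g)), table(x$g), sep = "x", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname truth_genotypes
#' @param g_obs integer vector over `{0, 1, 2, NA}` (`NA` = missing).
#' @param g_truth optional integer truth vector used to derive provenance;
#'   `NA` entries mean truth unknown at that site.
#' @param provenance optional explicit provenance (used when reading from
#'   VCF, where truth is not stored).
#' @return an `observed_genotypes` object.
#' @export
observed_genotypes <- function(sites, g_obs, g_truth = NULL,
                               provenance = NULL) {
  sites <- tibble::as_tibble(sites)
  g_obs <- as.integer(g_obs)
  stopifnot(length(g_obs) == nrow(sites))
  if (any(!is.na(g_obs) & (g_obs < 0L | g_obs > 2L))) {
    stop("observed genotypes must be 0/1/2 or NA")
  }
  if (!is.null(g_truth)) {
    g_truth <- as.integer(g_truth)
    stopifnot(length(g_truth) == length(g_obs))
    provenance <- dplyr::case_when(
      is.na(g_obs) ~ "MISSING",
      !is.na(g_truth) & g_obs != g_truth ~ "OBSERVED_ERRONEOUS",
      .default = "OBSERVED"
    )
  } else if (is.null(provenance)) {
    provenance <- ifelse(is.na(g_obs), "MISSING", "OBSERVED")
  }
  provenance <- as.character(provenance)
  stopifnot(length(provenance) == length(g_obs),
            all(provenance %in% c("OBSERVED", "OBSERVED_ERRONEOUS", "MISSING")))
  if (any((provenance == "MISSING") != is.na(g_obs))) {
    stop("provenance MISSING must coincide with NA genotypes")
  }
  structure(list(sites = sites, g_obs = g_obs,
                 g_truth = g_truth, provenance = provenance),
            class = "observed_genotypes")
}

#' @export
print.observed_genotypes <- function(x, ...) {
  tab <- table(factor(x$provenance,
                      c("OBSERVED", "OBSERVED_ERRONEOUS", "MISSING")))
  cat("<observed_genotypes> ", length(x$g_obs), " sites (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of non-missing observed genotypes
#' @param obs an `observed_genotypes` object.
#' @return an integer count.
#' @export
n_observed <- function(obs) sum(!is.na(obs$g_obs))
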