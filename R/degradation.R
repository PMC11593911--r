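#' Prune a complete genotype set to a target marker count
#'
#' Emulates a targeted forensic SNP panel: exactly `n_target` sites,
#' drawn uniformly at random without replacement, keep their true
#' genotype; all other sites become missing.  Internally each site gets an
#' independent uniform draw and the `n_target` smallest draws are
#' retained, which makes the operation equivariant under site reordering
#' when the same per-site draws are supplied.
#'
#' @param truth a [truth_genotypes] object.
#' @param n_target number of sites to retain (`0 <= n_target <= L`).
#' @param seed integer seed.
#' @param .u optional per-site uniform draws (length L), overriding the
#'   seeded draws; intended for reproducibility checks.
#' @return an [observed_genotypes] object.
#' @export
prune_to_panel <- function(truth, n_target, seed = 1, .u = NULL) {
  l <- length(truth$g)
  n_target <- as.integer(n_target)
  if (n_target < 0 || n_target > l) {
    stop("n_target must be between 0 and ", l)
  }
  u <- if (is.null(.u)) with_seed(seed, runif(l)) else .u
  stopifnot(length(u) == l)
  keep <- order(u)[seq_len(n_target)]
  g_obs <- rep(NA_integer_, l)
  g_obs[keep] <- truth$g[keep]
  observed_genotypes(truth$sites, g_obs, g_truth = truth$g)
}

#' Prune a complete genotype set to a fraction of markers
#'
#' Emulates a WGS-like input where a fraction of all target SNPs is
#' observed: equivalent to [prune_to_panel()] with
#' `n_target = round(fraction * L)`.
#'
#' @param truth a [truth_genotypes] object.
#' @param fraction fraction of sites to retain in `[0, 1]`.
#' @param seed integer seed.
#' @return an [observed_genotypes] object.
#' @export
prune_to_fraction <- function(truth, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  prune_to_panel(truth, round(fraction * length(truth$g)), seed = seed)
}

#' Inject allelic drop-in errors
#'
#' Each non-missing homozygous genotype (0 or 2) independently gains a
#' single spurious allele of the opposite type with probability `rate`,
#' becoming heterozygous.  Drop-in is limited to homozygous genotypes and
#' never flips hom-ref to hom-alt; heterozygous and missing entries are
#' untouched.  Changed sites are tagged `OBSERVED_ERRONEOUS`.
#'
#' @param obs an [observed_genotypes] object.
#' @param rate per-genotype drop-in probability in `[0, 1]`.
#' @param seed integer seed.
#' @param .u optional per-site uniform draws (length L); sites with
#'   `.u < rate` among the eligible ones are hit.
#' @return an [observed_genotypes] object.
#' @export
inject_dropin <- function(obs, rate = 0.1, seed = 1, .u = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  g <- obs$g_obs
  l <- length(g)
  u <- if (is.null(.u)) with_seed(seed, runif(l)) else .u
  stopifnot(length(u) == l)
  hit <- !is.na(g) & (g == 0L | g == 2L) & u < rate
  g[hit] <- 1L
  rebuild_observed(obs, g)
}

#' Inject allelic drop-out errors
#'
#' In the default genotype-level mode, each non-missing heterozygous
#' genotype independently loses one allele with probability `rate`,
#' becoming homozygous for the surviving allele (survivor chosen uniformly
#' at random); homozygotes and missing entries are untouched.  In
#' `mode = "allele"` the rate applies independently to each of the two
#' alleles of any non-missing genotype: losing one allele of a
#' heterozygote makes it homozygous for the survivor, losing one allele of
#' a homozygote is undetectable, and a double loss collapses to a
#' uniformly chosen single surviving allele (conditioning on the genotype
#' remaining typeable) so drop-out never creates missing entries.
#' Changed sites are tagged `OBSERVED_ERRONEOUS`.
#'
#' @param obs an [observed_genotypes] object.
#' @param rate drop-out probability in `[0, 1]`.
#' @param seed integer seed.
#' @param mode `"genotype"` (default) or `"allele"`.
#' @param .u,.v,.w optional per-site uniform draws (length L): `.u` (and
#'   `.w` in allele mode) decide the loss events, `.v` the surviving
#'   allele.
#' @return an [observed_genotypes] object.
#' @export
inject_dropout <- function(obs, rate = 0.1, seed = 1,
                           mode = c("genotype", "allele"),
                           .u = NULL, .v = NULL, .w = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  mode <- match.arg(mode)
  g <- obs$g_obs
  l <- length(g)
  if (is.null(.u) || is.null(.v) || is.null(.w)) {
    draws <- with_seed(seed, list(u = runif(l), v = runif(l), w = runif(l)))
    if (is.null(.u)) .u <- draws$u
    if (is.null(.v)) .v <- draws$v
    if (is.null(.w)) .w <- draws$w
  }
  stopifnot(length(.u) == l, length(.v) == l, length(.w) == l)
  het <- !is.na(g) & g == 1L
  if (mode == "genotype") {
    hit <- het & .u < rate
    g[hit] <- ifelse(.v[hit] < 0.5, 0L, 2L)
  } else {
    # independent per-allele losses (only detectable on heterozygotes)
    lose_ref <- het & .u < rate
    lose_alt <- het & .w < rate
    both <- lose_ref & lose_alt
    g[lose_ref & !both] <- 2L  # ref copy lost -> hom alt
    g[lose_alt & !both] <- 0L  # alt copy lost -> hom ref
    g[both] <- ifelse(.v[both] < 0.5, 0L, 2L)
  }
  rebuild_observed(obs, as.integer(g))
}

# Recompute provenance after an injection, preferring exact comparison to
# truth when the object carries it.
rebuild_observed <- function(obs, g_new) {
  if (!is.null(obs$g_truth)) {
    observed_genotypes(obs$sites, g_new, g_truth = obs$g_truth)
  } else {
    prov <- dplyr::case_when(
      is.na(g_new) ~ "MISSING",
      g_new != obs$g_obs | obs$provenance == "OBSERVED_ERRONEOUS" ~
        "OBSERVED_ERRONEOUS",
      .default = "OBSERVED"
    )
    observed_genotypes(obs$sites, g_new, provenance = prov)
  }
}

#' Degrade a truth genotype set in one step
#'
#' Convenience pipeline: prune to a count or fraction, then inject the
#' requested error mode.  Pruning and each error injection use dedicated
#' child seeds derived from `seed`, so the stages are independently
#' reproducible.
#'
#' @param truth a [truth_genotypes] object.
#' @param n_target target observed-site count (exclusive with `fraction`).
#' @param fraction target observed fraction (exclusive with `n_target`).
#' @param error_mode `"none"`, `"dropin"` or `"dropout"`.
#' @param dropin_rate,dropout_rate error rates (default 0.1, the forensic
#'   degradation level the bench emulates).
#' @param dropout_mode passed to [inject_dropout()].
#' @param seed integer seed.
#' @return an [observed_genotypes] object.
#' @export
degrade <- function(truth, n_target = NULL, fraction = NULL,
                    error_mode = c("none", "dropin", "dropout"),
                    dropin_rate = 0.1, dropout_rate = 0.1,
                    dropout_mode = "genotype", seed = 1) {
  error_mode <- match.arg(error_mode)
  if (is.null(n_target) == is.null(fraction)) {
    stop("supply exactly one of n_target / fraction")
  }
  obs <- if (!is.null(n_target)) {
    prune_to_panel(truth, n_target, seed = derive_seed(seed, "prune"))
  } else {
    prune_to_fraction(truth, fraction, seed = derive_seed(seed, "prune"))
  }
  switch(error_mode,
    none = obs,
    dropin = inject_dropin(obs, dropin_rate,
                           seed = derive_seed(seed, "dropin")),
    dropout = inject_dropout(obs, dropout_rate,
                             seed = derive_seed(seed, "dropout"),
                             mode = dropout_mode)
  )
}
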