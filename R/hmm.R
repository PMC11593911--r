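#' HMM parameters for the haplotype-copying imputation engine
#'
#' @param ne effective population size: the dimensionless scale of
#'   recombination intensity in the copying model.  The switch probability
#'   across `d` cM against `k` reference haplotypes is
#'   `tau = 1 - exp(-4 * ne * (d / 100) / k)`.  Default 10,000 — the scale
#'   at which, against a ~100-haplotype panel, copying tracks average
#'   ~0.25 cM.
#' @param eps per-allele miscopy probability in `[0, 0.5)`; `"auto"`
#'   selects the Watterson heuristic `theta / (2 * (theta + k))` with
#'   `theta = 1 / sum(1/i, i < k)`.
#' @return a list of class `hmm_params`.
#' @export
hmm_params <- function(ne = 10000, eps = 1e-3) {
  stopifnot(ne > 0)
  if (!identical(eps, "auto")) {
    stopifnot(is.numeric(eps), eps >= 0, eps < 0.5)
  }
  structure(list(ne = ne, eps = eps), class = "hmm_params")
}

resolve_eps <- function(params, k) {
  if (identical(params$eps, "auto")) {
    theta <- 1 / sum(1 / seq_len(max(k - 1, 1)))
    theta / (2 * (theta + k))
  } else {
    params$eps
  }
}

#' Haplotype switch probability across a genetic distance
#'
#' `tau = 1 - exp(-4 * ne * (d_cm / 100) / k)`: the probability that a
#' copying chain leaves its current template across `d_cm` centiMorgans.
#' After a switch the chain picks a template uniformly, so it stays on the
#' same haplotype with probability `(1 - tau) + tau / k` and moves to each
#' specific other haplotype with probability `tau / k`.
#'
#' @param d_cm genetic distance in cM (vectorised, `>= 0`).
#' @param ne effective population size scale.
#' @param k number of reference haplotypes.
#' @return switch probabilities in `[0, 1]`.
#' @examples
#' switch_probability(0.01, ne = 10000, k = 100) # 1 - exp(-0.04)
#' @export
switch_probability <- function(d_cm, ne, k) {
  stopifnot(ne > 0, k >= 1)
  if (any(d_cm < 0)) stop("genetic distance must be non-negative")
  -expm1(-4 * ne * (d_cm / 100) / k)
}

#' Genotype emission probability under the miscopy model
#'
#' Each allele of the observed genotype is copied from its template allele
#' with per-allele miscopy probability `eps`:
#' `P(x | a) = 1 - eps` if `x == a`, else `eps`.  A homozygous genotype
#' `(x, x)` has probability `P(x | a1) P(x | a2)`; the heterozygote sums
#' the two orderings.  A missing genotype (`NA`) has probability 1, so
#' unobserved sites carry no emission information.
#'
#' @param g_obs observed genotype in `{0, 1, 2}` or `NA` (vectorised).
#' @param a1,a2 template alleles in `{0, 1}`.
#' @param eps per-allele miscopy probability.
#' @return emission probabilities; for fixed alleles they sum to 1 over
#'   `g_obs` in `{0, 1, 2}`.
#' @examples
#' emission_probability(1, 0, 1, eps = 0) # 1
#' emission_probability(0, 1, 1, eps = 1e-3) # 1e-6
#' @export
emission_probability <- function(g_obs, a1, a2, eps) {
  stopifnot(all(a1 %in% 0:1), all(a2 %in% 0:1), eps >= 0, eps < 0.5)
  if (any(!is.na(g_obs) & !(g_obs %in% 0:2))) {
    stop("invalid genotype code: genotypes are 0, 1, 2 or NA")
  }
  p_match <- function(x, a) ifelse(x == a, 1 - eps, eps)
  p0 <- p_match(0, a1) * p_match(0, a2)
  p2 <- p_match(1, a1) * p_match(1, a2)
  p1 <- 1 - p0 - p2
  out <- rep(1, length(g_obs))
  out[!is.na(g_obs) & g_obs == 0] <- p0[!is.na(g_obs) & g_obs == 0]
  out[!is.na(g_obs) & g_obs == 1] <- p1[!is.na(g_obs) & g_obs == 1]
  out[!is.na(g_obs) & g_obs == 2] <- p2[!is.na(g_obs) & g_obs == 2]
  out
}

#' Exact genotype posteriors by forward-backward
#'
#' Runs the diploid Li-Stephens copying HMM over the ordered site list
#' shared by the panel and the observation: the hidden state at each site
#' is the ordered pair of copied reference haplotypes, the two chains
#' switch independently per [switch_probability()], and observed genotypes
#' are emitted per [emission_probability()].  Returns, for every site, the
#' exact posterior probability of each diploid genotype given all observed
#' genotypes, computed with per-site rescaling (no underflow at any
#' length) in `O(L * k^2)` time via the factorised transition.
#'
#' @param panel a [haplotype_panel()] (the reference; must not contain the
#'   target's haplotypes).
#' @param obs an [observed_genotypes] object on the same ordered site list
#'   as the panel.
#' @param map optional [genetic_map]; defaults to the panel's `cm` column.
#' @param params an [hmm_params()] object.
#' @return a `posterior_field`: a tibble with one row per site and columns
#'   `chrom`, `pos`, `p0`, `p1`, `p2`, `dosage` (`p1 + 2 p2`), `gp`
#'   (`max(p0, p1, p2)`) and `g_map` (argmax genotype, ties broken toward
#'   the lower genotype code).  The HMM log-likelihood is attached as
#'   attribute `loglik`.
#' @export
forward_backward <- function(panel, obs, map = NULL, params = hmm_params()) {
  k <- n_haplotypes(panel)
  if (k < 2) stop("panel must have at least 2 haplotypes")
  if (!identical(nrow(obs$sites), nrow(panel$sites)) ||
      !identical(as.integer(obs$sites$pos), as.integer(panel$sites$pos)) ||
      !identical(as.character(obs$sites$chrom), as.character(panel$sites$chrom))) {
    stop("site-list mismatch between observation and panel")
  }
  if (all(c("ref", "alt") %in% names(obs$sites))) {
    bad <- which(obs$sites$ref != panel$sites$ref |
                 obs$sites$alt != panel$sites$alt)
    if (length(bad) > 0) {
      stop("REF/ALT mismatch between target and panel at ",
           panel$sites$chrom[bad[1]], ":", panel$sites$pos[bad[1]],
           " (allele harmonisation is out of scope)")
    }
  }
  cm <- if (is.null(map)) panel$sites$cm else
    map_cm(map, panel$sites$pos, panel$sites$chrom)
  l <- ncol(panel$alleles)
  d_cm <- if (l > 1) c(0, pmax(diff(cm), 0)) else 0
  eps <- resolve_eps(params, k)
  g <- obs$g_obs
  g[is.na(g)] <- -1L
  post <- ls_fb_cpp(panel$alleles, as.integer(g), as.numeric(d_cm),
                    params$ne, eps)
  new_posterior_field(panel$sites, post, params, eps)
}

new_posterior_field <- function(sites, post, params, eps) {
  out <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    p0 = post[, 1], p1 = post[, 2], p2 = post[, 3],
    dosage = post[, 2] + 2 * post[, 3],
    gp = pmax(post[, 1], post[, 2], post[, 3]),
    g_map = max.col(post, ties.method = "first") - 1L
  )
  class(out) <- c("posterior_field", class(out))
  attr(out, "loglik") <- attr(post, "loglik")
  attr(out, "hmm_params") <- list(ne = params$ne, eps = eps)
  out
}

#' Call imputed genotypes at a genotype-probability threshold
#'
#' Observed (non-missing) sites pass through unchanged with source
#' `OBSERVED`.  A missing site is imputed with its maximum-posterior
#' genotype when its genotype probability meets or exceeds `q_gp`
#' (inclusive comparison); otherwise it stays missing.
#'
#' @param post a `posterior_field` from [forward_backward()].
#' @param obs the [observed_genotypes] the posterior was computed from.
#' @param q_gp calling threshold in `[0, 1]`.
#' @return a `called_genotypes` object: site list plus per-site genotype
#'   (`NA` = uncalled), `source` (`"OBSERVED"`, `"IMPUTED"`, or `NA`), and
#'   `gp` (posterior genotype probability, `NA` at observed sites).
#' @export
call_imputed <- function(post, obs, q_gp = 0.95) {
  stopifnot(q_gp >= 0, q_gp <= 1)
  if (nrow(post) != length(obs$g_obs)) {
    stop("posterior and observation have different site counts")
  }
  g <- obs$g_obs
  source <- ifelse(is.na(g), NA_character_, "OBSERVED")
  gp <- rep(NA_real_, length(g))
  miss <- is.na(g)
  callable <- miss & post$gp >= q_gp
  g[callable] <- post$g_map[callable]
  source[callable] <- "IMPUTED"
  gp[callable] <- post$gp[callable]
  structure(
    list(sites = obs$sites, g = as.integer(g), source = source, gp = gp,
         q_gp = q_gp,
         unimputable = attr(obs, "unimputable") %||% rep(FALSE, length(g))),
    class = "called_genotypes"
  )
}

#' @export
print.called_genotypes <- function(x, ...) {
  cat("<called_genotypes> ", length(x$g), " sites at q_gp = ", x$q_gp,
      ": ", sum(x$source == "OBSERVED", na.rm = TRUE), " observed, ",
      sum(x$source == "IMPUTED", na.rm = TRUE), " imputed, ",
      sum(is.na(x$g)), " missing\n", sep = "")
  invisible(x)
}

#' Impute one degraded sample against a reference panel
#'
#' High-level wrapper: aligns the observation's site list onto the
#' panel's, runs [forward_backward()], and calls genotypes at `q_gp`.
#' Target sites absent from the panel cannot be imputed (alleles not
#' represented in the reference are never predicted); they are returned as
#' missing and flagged in the `unimputable` field of the result.
#'
#' @inheritParams forward_backward
#' @param q_gp calling threshold in `[0, 1]`.
#' @return a list with elements `called` ([call_imputed()] result over the
#'   observation's site list) and `posterior` (the `posterior_field` over
#'   the panel's site list).
#' @export
impute_sample <- function(panel, obs, map = NULL, params = hmm_params(),
                          q_gp = 0.95) {
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  key_o <- paste(obs$sites$chrom, obs$sites$pos)
  idx <- match(key_o, key_p)
  unimputable <- is.na(idx)
  if (!any(unimputable) && length(key_o) == length(key_p)) {
    post <- forward_backward(panel, obs, map = map, params = params)
    called <- call_imputed(post, obs, q_gp = q_gp)
    called$unimputable <- rep(FALSE, length(called$g))
    return(list(called = called, posterior = post))
  }
  # project observed genotypes onto the panel's site list
  g_panel <- rep(NA_integer_, length(key_p))
  g_panel[idx[!unimputable]] <- obs$g_obs[!unimputable]
  obs_panel <- observed_genotypes(panel$sites, g_panel)
  post <- forward_backward(panel, obs_panel, map = map, params = params)
  # map calls back onto the target site list
  g <- obs$g_obs
  source <- ifelse(is.na(g), NA_character_, "OBSERVED")
  gp <- rep(NA_real_, length(g))
  miss_in_panel <- which(is.na(g) & !unimputable)
  pi <- idx[miss_in_panel]
  callable <- post$gp[pi] >= q_gp
  g[miss_in_panel[callable]] <- post$g_map[pi[callable]]
  source[miss_in_panel[callable]] <- "IMPUTED"
  gp[miss_in_panel[callable]] <- post$gp[pi[callable]]
  called <- structure(
    list(sites = obs$sites, g = as.integer(g), source = source, gp = gp,
         q_gp = q_gp, unimputable = unimputable & is.na(g)),
    class = "called_genotypes"
  )
  list(called = called, posterior = post)
}
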