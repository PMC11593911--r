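#' Haplotype reference panels
#'
#' A haplotype panel is the phased reference an imputation engine copies
#' from: a K x L binary matrix (K haplotypes, L biallelic SNP sites, 0 =
#' reference allele, 1 = alternate allele) together with ordered site
#' metadata and a per-haplotype population label.
#'
#' @param sites a tibble with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within a chromosome), `id`, `ref`, `alt` (single distinct
#'   nucleotides) and `cm` (genetic-map position, non-decreasing).
#' @param alleles integer matrix of 0/1 with `K` rows (haplotypes) and
#'   `nrow(sites)` columns.
#' @param pop character vector of population labels, one per haplotype.
#' @param samples optional character vector of diploid donor ids (length
#'   `K/2`); haplotype rows `2i - 1` and `2i` belong to donor `i`.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sites, alleles, pop = NULL, samples = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!is.matrix(alleles)) alleles <- matrix(alleles, nrow = NROW(alleles))
  storage.mode(alleles) <- "integer"
  if (is.null(pop)) pop <- rep("POP1", nrow(alleles))
  obj <- structure(
    list(sites = sites, alleles = alleles, pop = as.character(pop),
         samples = samples),
    class = "haplotype_panel"
  )
  validate_panel(obj)
  obj
}

validate_panel <- function(panel) {
  sites <- panel$sites
  need <- c("chrom", "pos", "ref", "alt", "cm")
  if (!all(need %in% names(sites))) {
    stop("panel sites must have columns ", paste(need, collapse = ", "))
  }
  if (ncol(panel$alleles) != nrow(sites)) {
    stop("allele matrix has ", ncol(panel$alleles), " columns but ",
         nrow(sites), " sites")
  }
  if (length(panel$pop) != nrow(panel$alleles)) {
    stop("pop labels must match the number of haplotypes")
  }
  if (nrow(sites) > 0) {
    by_chrom <- split(sites$pos, sites$chrom)
    if (!all(vapply(by_chrom, function(p) all(diff(p) > 0), logical(1)))) {
      stop("site positions must be strictly increasing within a chromosome")
    }
    if (any(diff(sites$cm) < -1e-12 & diff(sites$pos) > 0 &
            sites$chrom[-1] == sites$chrom[-nrow(sites)])) {
      stop("cm must be non-decreasing with position")
    }
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  }
  bad <- panel$alleles != 0L & panel$alleles != 1L
  if (any(bad, na.rm = TRUE) || anyNA(panel$alleles)) {
    stop("panel alleles must be 0/1 with no missing values")
  }
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " sites\n", sep = "")
  if (nrow(x$alleles) > 0) {
    tab <- table(x$pop)
    cat("  populations: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$sites) > 0) {
    cat("  span: ", x$sites$chrom[1], ":", x$sites$pos[1], "-",
        x$sites$pos[nrow(x$sites)], " (",
        round(x$sites$cm[nrow(x$sites)] - x$sites$cm[1], 2), " cM)\n",
        sep = "")
  }
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a `haplotype_panel`.
#' @return an integer count.
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_panel_sites <- function(panel) ncol(panel$alleles)

#' Panel alternate-allele frequencies
#' @param panel a `haplotype_panel`.
#' @return numeric vector of per-site alt-allele frequencies.
#' @export
allele_frequencies <- function(panel) {
  if (n_haplotypes(panel) == 0) return(numeric(ncol(panel$alleles)))
  colMeans(panel$alleles)
}

#' Remove haplotype rows from a panel
#'
#' Used to honour the leave-one-out contract: a test individual's two
#' haplotypes are removed from the panel before it is used as the
#' imputation reference.
#'
#' @param panel a `haplotype_panel`.
#' @param idx integer indices of haplotype rows to drop.
#' @return a `haplotype_panel` without those rows.
#' @export
drop_haplotypes <- function(panel, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0) return(panel)
  stopifnot(all(idx >= 1), all(idx <= n_haplotypes(panel)))
  keep <- setdiff(seq_len(n_haplotypes(panel)), idx)
  haplotype_panel(panel$sites, panel$alleles[keep, , drop = FALSE],
                  pop = panel$pop[keep])
}

# ---- simulation ------------------------------------------------------------

#' Simulate founder haplotypes with a controlled frequency spectrum
#'
#' Sites are independent: each gets a target alternate-allele frequency
#' drawn from a Beta(`beta_shape1`, `beta_shape2`) distribution truncated to
#' `[maf_min, 1 - maf_min]`, and founder alleles are Bernoulli draws at that
#' frequency.  Sites whose realised minor-allele count falls below
#' `max(1, ceiling(maf_min * n_founders))` are redrawn, so every site is
#' polymorphic in the panel.  Linkage disequilibrium is added afterwards by
#' [recombine_panel()].
#'
#' @param n_founders number of founder haplotypes (K >= 2).
#' @param n_sites number of SNP sites.
#' @param maf_min minimum panel minor-allele frequency in `[0, 0.5)`.
#' @param beta_shape1,beta_shape2 shape parameters of the founder frequency
#'   spectrum (defaults 0.8/0.8: a mildly U-shaped spectrum without a heavy
#'   rare tail, matching dense forensic target panels).
#' @param bp_per_site mean physical spacing in bp; positions are a uniform
#'   random draw over `n_sites * bp_per_site` bp.
#' @param rate_cm_per_mb constant recombination rate used to place sites on
#'   the genetic map (cM per Mb).
#' @param chrom chromosome label.
#' @param pop population label for all founders.
#' @param seed integer seed; results are bit-identical for a fixed seed.
#' @return a `haplotype_panel`.
#' @examples
#' p <- simulate_founders(20, 100, maf_min = 0.05, seed = 1)
#' range(allele_frequencies(p))
#' @export
simulate_founders <- function(n_founders, n_sites, maf_min = 0.05,
                              beta_shape1 = 0.8, beta_shape2 = 0.8,
                              bp_per_site = 1750, rate_cm_per_mb = 1.2,
                              chrom = "chrS", pop = "POP1", seed = 1) {
  stopifnot(n_founders >= 2, n_sites >= 0, maf_min >= 0, maf_min < 0.5)
  min_count <- max(1L, as.integer(ceiling(maf_min * n_founders - 1e-9)))
  if (min_count > floor(n_founders / 2)) {
    stop("maf_min = ", maf_min, " is not representable with ",
         n_founders, " founders")
  }
  if (n_sites == 0) {
    sites <- tibble::tibble(chrom = character(), pos = integer(),
                            id = character(), ref = character(),
                            alt = character(), cm = numeric())
    return(haplotype_panel(sites, matrix(integer(), n_founders, 0),
                           pop = rep(pop, n_founders)))
  }
  nucs <- c("A", "C", "G", "T")
  with_seed(seed, {
    pos <- sort(sample.int(as.integer(n_sites * bp_per_site), n_sites))
    ref <- sample(nucs, n_sites, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(nucs, r), 1),
                         character(1)))
    p <- draw_trunc_beta(n_sites, beta_shape1, beta_shape2, maf_min)
    alleles <- matrix(rbinom(n_founders * n_sites, 1L, rep(p, each = n_founders)),
                      nrow = n_founders)
    mac <- pmin(colSums(alleles), n_founders - colSums(alleles))
    it <- 0
    while (any(bad <- mac < min_count)) {
      it <- it + 1
      if (it > 10000) stop("failed to satisfy maf_min after 10000 redraws")
      nb <- sum(bad)
      p[bad] <- draw_trunc_beta(nb, beta_shape1, beta_shape2, maf_min)
      alleles[, bad] <- rbinom(n_founders * nb, 1L, rep(p[bad], each = n_founders))
      mac[bad] <- pmin(colSums(alleles[, bad, drop = FALSE]),
                       n_founders - colSums(alleles[, bad, drop = FALSE]))
    }
  })
  sites <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    id = paste0("snp", seq_len(n_sites)),
    ref = ref, alt = alt,
    cm = rate_cm_per_mb * pos / 1e6
  )
  storage.mode(alleles) <- "integer"
  haplotype_panel(sites, alleles, pop = rep(pop, n_founders))
}

# Truncated-Beta sampling via the inverse CDF so truncation is exact.
draw_trunc_beta <- function(n, a, b, maf_min) {
  lo <- stats::pbeta(maf_min, a, b)
  hi <- stats::pbeta(1 - maf_min, a, b)
  qbeta(runif(n, lo, hi), a, b)
}

# Mosaic copying core: build n_out haplotypes as founder mosaics with
# switch points drawn as a Poisson process of rate n_generations per Morgan.
# Assumes the RNG is already seeded by the caller.
mosaic_haplotypes <- function(founder_alleles, n_out, d_cm, n_generations) {
  k <- nrow(founder_alleles)
  l <- ncol(founder_alleles)
  if (l == 0) return(matrix(integer(), n_out, 0))
  if (n_generations == 0) {
    donors <- if (n_out <= k) sample.int(k, n_out) else
      sample.int(k, n_out, replace = TRUE)
    return(founder_alleles[donors, , drop = FALSE])
  }
  p_switch <- -expm1(-n_generations * d_cm / 100)
  out <- matrix(0L, n_out, l)
  for (h in seq_len(n_out)) {
    sw <- runif(l - 1) < p_switch
    seg <- cumsum(c(1L, as.integer(sw)))
    donors <- sample.int(k, seg[l], replace = TRUE)
    out[h, ] <- founder_alleles[cbind(donors[seg], seq_len(l))]
  }
  out
}

#' Expand a founder panel into recombinant haplotypes
#'
#' Each output haplotype is a mosaic of founder haplotypes, with switch
#' points drawn as a Poisson process on the genetic-map (cM) scale at rate
#' `n_generations` per Morgan and donors drawn uniformly at each segment.
#' `n_generations` tunes the panel's linkage disequilibrium: 0 returns
#' resampled copies of the founders (a permutation when `n_haplotypes`
#' equals the founder count, so allele frequencies are conserved exactly);
#' larger values give shorter shared segments and faster LD decay.
#'
#' @param founders a `haplotype_panel` of founder haplotypes.
#' @param n_haplotypes number of output haplotypes.
#' @param map optional [genetic_map]; defaults to the founders' `cm` column.
#' @param n_generations mosaic depth (switch rate per Morgan).
#' @param seed integer seed.
#' @param pop label for the output haplotypes; defaults to the founders'
#'   label when unique.
#' @return a `haplotype_panel`.
#' @export
recombine_panel <- function(founders, n_haplotypes, map = NULL,
                            n_generations = 400, seed = 1, pop = NULL) {
  stopifnot(n_haplotypes >= 1, n_generations >= 0)
  if (n_haplotypes(founders) < 1 || n_panel_sites(founders) == 0) {
    if (n_panel_sites(founders) == 0 && n_haplotypes(founders) >= 1) {
      return(haplotype_panel(founders$sites,
                             matrix(integer(), n_haplotypes, 0),
                             pop = rep(founders$pop[1], n_haplotypes)))
    }
    stop("founder panel is empty")
  }
  cm <- if (is.null(map)) founders$sites$cm else
    map_cm(map, founders$sites$pos, founders$sites$chrom)
  d_cm <- c(0, pmax(diff(cm), 0))
  alleles <- with_seed(seed,
    mosaic_haplotypes(founders$alleles, n_haplotypes, d_cm[-1], n_generations))
  if (is.null(pop)) {
    pop <- if (length(unique(founders$pop)) == 1) founders$pop[1] else "MIX"
  }
  haplotype_panel(founders$sites, alleles, pop = rep(pop, n_haplotypes))
}

#' Split a founder panel into diverged populations
#'
#' Emulates reference panels whose populations differ from (or match) the
#' target individual's ancestry.  For each population, founder allele
#' frequencies are perturbed Balding-Nichols style —
#' `p_pop ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = divergence`
#' interpreted as the target Fst — a fresh founder set is drawn at the
#' perturbed frequencies, and recombinant haplotypes are generated within
#' the population by [recombine_panel()]'s mosaic process.  With
#' `divergence = 0` the original founder set is reused for every
#' population, so the populations are statistically identical.
#'
#' @param founders a `haplotype_panel` (ancestral founders).
#' @param n_pops number of populations.
#' @param divergence drift parameter in `[0, 1)`; target Fst.
#' @param sizes integer vector of output haplotypes per population
#'   (default: equal sizes of `n_haplotypes(founders)` each).
#' @param map optional [genetic_map].
#' @param n_generations mosaic depth within each population.
#' @param pop_names labels (default `POP1`, `POP2`, ...).
#' @param seed integer seed.
#' @return a `haplotype_panel` with per-haplotype population labels.
#' @export
split_populations <- function(founders, n_pops = 2, divergence = 0.1,
                              sizes = NULL, map = NULL, n_generations = 400,
                              pop_names = NULL, seed = 1) {
  stopifnot(n_pops >= 1, divergence >= 0, divergence < 1)
  if (is.null(sizes)) sizes <- rep(n_haplotypes(founders), n_pops)
  stopifnot(length(sizes) == n_pops, all(sizes >= 0))
  if (is.null(pop_names)) pop_names <- paste0("POP", seq_len(n_pops))
  k <- n_haplotypes(founders)
  l <- n_panel_sites(founders)
  cm <- if (is.null(map)) founders$sites$cm else
    map_cm(map, founders$sites$pos, founders$sites$chrom)
  d_cm <- pmax(diff(cm), 0)
  p_anc <- pmin(pmax(allele_frequencies(founders), 1 / (2 * k)),
                1 - 1 / (2 * k))
  parts <- with_seed(seed, {
    lapply(seq_len(n_pops), function(i) {
      if (sizes[i] == 0) return(matrix(integer(), 0, l))
      fa <- if (divergence > 0) {
        f <- divergence
        p_pop <- rbeta(l, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
        matrix(rbinom(k * l, 1L, rep(p_pop, each = k)), nrow = k)
      } else {
        founders$alleles
      }
      mosaic_haplotypes(fa, sizes[i], d_cm, n_generations)
    })
  })
  alleles <- do.call(rbind, parts)
  storage.mode(alleles) <- "integer"
  haplotype_panel(founders$sites, alleles,
                  pop = rep(pop_names, times = sizes))
}

#' Draw a diploid truth individual from a panel
#'
#' Draws two haplotypes without replacement (optionally recombining them
#' through one extra mosaic pass) and returns the individual's true
#' genotypes together with the panel rows that must be excluded from the
#' reference before imputing this individual.
#'
#' @param panel a `haplotype_panel`.
#' @param pop population label to draw from, or `"any"`.
#' @param n_generations extra mosaic depth applied to the two drawn
#'   haplotypes (0 = use them as is).
#' @param seed integer seed.
#' @return a list of class `truth_sample` with elements `truth` (a
#'   [truth_genotypes] object), `haplotypes` (2 x L matrix) and `exclude`
#'   (the two panel row indices to drop from the reference).
#' @export
sample_truth_individual <- function(panel, pop = "any", n_generations = 0,
                                    seed = 1) {
  eligible <- if (identical(pop, "any")) seq_len(n_haplotypes(panel)) else
    which(panel$pop == pop)
  if (length(eligible) < 2) {
    stop("need at least 2 haplotypes with population tag '", pop, "'")
  }
  d_cm <- pmax(diff(panel$sites$cm), 0)
  res <- with_seed(seed, {
    idx <- sample(eligible, 2)
    haps <- panel$alleles[idx, , drop = FALSE]
    if (n_generations > 0) {
      haps <- mosaic_haplotypes(haps, 2L, d_cm, n_generations)
    }
    list(idx = idx, haps = haps)
  })
  g <- as.integer(colSums(res$haps))
  structure(
    list(truth = truth_genotypes(panel$sites, g),
         haplotypes = res$haps,
         exclude = as.integer(res$idx)),
    class = "truth_sample"
  )
}

#' Weir-Cockerham Fst over panel populations
#'
#' Multi-site ratio-of-averages Weir-Cockerham estimator for haploid
#' (haplotype) samples, used to check that [split_populations()] hits its
#' target divergence.
#'
#' @param panel a `haplotype_panel` with at least two population labels.
#' @return a single Fst estimate.
#' @export
fst_wc <- function(panel) {
  pops <- unique(panel$pop)
  r <- length(pops)
  if (r < 2) stop("fst_wc needs at least two populations")
  n_i <- vapply(pops, function(p) sum(panel$pop == p), numeric(1))
  p_i <- t(vapply(pops,
                  function(p) colMeans(panel$alleles[panel$pop == p, , drop = FALSE]),
                  numeric(n_panel_sites(panel))))
  n_tot <- sum(n_i)
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  p_bar <- colSums(p_i * n_i) / n_tot
  msp <- colSums(n_i * sweep(p_i, 2, p_bar)^2) / (r - 1)
  msg <- colSums(n_i * p_i * (1 - p_i)) / (n_tot - r)
  num <- msp - msg
  den <- msp + (n_c - 1) * msg
  sum(num) / sum(den)
}
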