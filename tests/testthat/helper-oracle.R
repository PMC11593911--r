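# Independent oracle for the diploid copying HMM: literal enumeration of
# all (K^2)^L state paths.  Shares only the model *definitions* (switch
# probability, emission table) with the implementation under test; the
# posterior itself is computed by brute force, not by forward-backward.

# genotype predictive P(g | a1, a2, eps) for one state at one site
oracle_genotype_predictive <- function(a1, a2, eps) {
  q0 <- function(a) ifelse(a == 0, 1 - eps, eps)
  p0 <- q0(a1) * q0(a2)
  p2 <- (1 - q0(a1)) * (1 - q0(a2))
  c(p0, 1 - p0 - p2, p2)
}

# alleles: K x L 0/1 matrix; g_obs: length-L vector with NA = missing;
# d_cm: length-L inter-site distances (first entry ignored).
# Returns an L x 3 matrix of genotype posteriors.
oracle_posteriors <- function(alleles, g_obs, d_cm, ne, eps) {
  k <- nrow(alleles)
  l <- ncol(alleles)
  k2 <- k * k
  i_of <- rep(seq_len(k), times = k)
  j_of <- rep(seq_len(k), each = k)

  # haploid transition matrix per interval, then the diploid product
  trans <- lapply(seq_len(l), function(m) {
    if (m == 1) return(NULL)
    tau <- 1 - exp(-0.04 * ne * d_cm[m] / k)
    a_h <- diag(k) * (1 - tau) + tau / k
    # T[s, s'] = a_h[i, i'] * a_h[j, j']
    a_h[i_of, i_of] * a_h[j_of, j_of]
  })
  # per-site per-state emission and genotype predictive
  pred <- lapply(seq_len(l), function(m) {
    t(mapply(function(i, j) {
      oracle_genotype_predictive(alleles[i, m], alleles[j, m], eps)
    }, i_of, j_of))
  })
  emis <- vapply(seq_len(l), function(m) {
    if (is.na(g_obs[m])) rep(1, k2) else pred[[m]][, g_obs[m] + 1]
  }, numeric(k2))

  paths <- as.matrix(expand.grid(rep(list(seq_len(k2)), l)))
  prob <- rep(1 / k2, nrow(paths))
  for (m in seq_len(l)) {
    if (m > 1) {
      prob <- prob * trans[[m]][cbind(paths[, m - 1], paths[, m])]
    }
    prob <- prob * emis[paths[, m], m]
  }
  post <- matrix(0, l, 3)
  for (m in seq_len(l)) {
    for (g in 0:2) {
      post[m, g + 1] <- sum(prob * pred[[m]][paths[, m], g + 1])
    }
    post[m, ] <- post[m, ] / sum(post[m, ])
  }
  post
}

# wrap a raw allele matrix into a minimal panel / observation pair
toy_panel <- function(alleles, spacing_cm = 0.05, chrom = "chrT") {
  l <- ncol(alleles)
  pos <- as.integer(seq_len(l) * 1000)
  sites <- tibble::tibble(
    chrom = chrom, pos = pos, id = paste0("s", seq_len(l)),
    ref = "A", alt = "G", cm = (seq_len(l) - 1) * spacing_cm
  )
  haplotype_panel(sites, alleles)
}

toy_obs <- function(panel, g_obs) {
  observed_genotypes(panel$sites, g_obs)
}

# random small HMM instance for property sweeps
random_hmm_instance <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  l <- sample(2:5, 1)
  alleles <- matrix(rbinom(k * l, 1, runif(1, 0.2, 0.8)), k, l)
  # ensure the panel is not totally degenerate in a single allele
  if (all(alleles == alleles[1])) alleles[1, 1] <- 1L - alleles[1, 1]
  g_obs <- sample(c(0:2, NA), l, replace = TRUE)
  spacing <- runif(1, 0.001, 0.5)
  ne <- sample(c(100, 1000, 10000), 1)
  eps <- sample(c(1e-4, 1e-3, 0.01, 0.1), 1)
  list(alleles = alleles, g_obs = g_obs, spacing = spacing, ne = ne,
       eps = eps)
}
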