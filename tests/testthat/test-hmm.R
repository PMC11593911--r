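test_that("switch_probability follows the Li-Stephens form", {
  expect_equal(switch_probability(0, ne = 1000, k = 10), 0)
  expect_equal(switch_probability(1e9, ne = 1000, k = 10), 1)
  expect_equal(switch_probability(0.01, ne = 10000, k = 100),
               1 - exp(-0.04), tolerance = 1e-12)
  d <- seq(0, 5, by = 0.1)
  expect_true(all(diff(switch_probability(d, ne = 500, k = 20)) > 0))
  expect_error(switch_probability(-1, ne = 100, k = 5), "non-negative")
})

test_that("emission probabilities implement the miscopy model", {
  expect_equal(emission_probability(1, 0, 1, eps = 0), 1)
  expect_equal(emission_probability(0, 1, 1, eps = 1e-3), 1e-6)
  expect_equal(emission_probability(NA, 1, 0, eps = 0.01), 1)
  # normalisation over genotypes for every allele pair
  for (a1 in 0:1) for (a2 in 0:1) {
    tot <- sum(vapply(0:2, emission_probability, numeric(1),
                      a1 = a1, a2 = a2, eps = 0.05))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  expect_error(emission_probability(3, 0, 1, eps = 0.1), "invalid genotype")
})

test_that("a degenerate identical-haplotype panel forces its genotype", {
  l <- 30
  sites <- simple_sites(l)
  h <- rbinom(l, 1, 0.5)
  panel <- haplotype_panel(sites, matrix(rep(h, 5), 5, byrow = TRUE))
  obs <- observed_genotypes(sites, rep(NA_integer_, l))
  post <- forward_backward(panel, obs, params = hmm_params(eps = 0))
  expect_equal(post$g_map, as.integer(2 * h))
  expect_equal(post$gp, rep(1, l))
})

test_that("forward-backward matches exhaustive path enumeration", {
  for (s in 1:40) {
    inst <- random_hmm_instance(s)
    panel <- toy_panel(inst$alleles, spacing_cm = inst$spacing)
    obs <- toy_obs(panel, inst$g_obs)
    post <- forward_backward(panel, obs,
                             params = hmm_params(ne = inst$ne, eps = inst$eps))
    l <- ncol(inst$alleles)
    orc <- oracle_posteriors(inst$alleles, inst$g_obs,
                             c(0, rep(inst$spacing, l - 1)),
                             inst$ne, inst$eps)
    expect_lt(max(abs(as.matrix(post[, c("p0", "p1", "p2")]) - orc)), 1e-9)
  }
})

test_that("posteriors are normalised and finite on a large instance", {
  panel <- recombine_panel(iid_panel(20, 5000, seed = 3), 60,
                           n_generations = 50, seed = 4)
  dr <- sample_truth_individual(panel, seed = 5)
  ref <- drop_haplotypes(panel, dr$exclude)
  obs <- degrade(dr$truth, n_target = 1500, seed = 6)
  post <- forward_backward(ref, obs, params = hmm_params(ne = 2500))
  expect_lt(max(abs(post$p0 + post$p1 + post$p2 - 1)), 1e-9)
  expect_true(all(is.finite(c(post$p0, post$p1, post$p2, post$dosage))))
  expect_true(all(post$gp >= 1 / 3 - 1e-12 & post$gp <= 1 + 1e-12))
  expect_true(all(post$dosage >= 0 & post$dosage <= 2))
  expect_true(is.finite(attr(post, "loglik")))
})

test_that("genotype posteriors are invariant under haplotype reordering", {
  panel <- iid_panel(8, 60, seed = 7)
  dr <- sample_truth_individual(panel, seed = 8)
  obs <- degrade(dr$truth, n_target = 30, seed = 9)
  post1 <- forward_backward(panel, obs)
  perm <- sample(8)
  panel2 <- haplotype_panel(panel$sites, panel$alleles[perm, , drop = FALSE],
                            pop = panel$pop[perm])
  post2 <- forward_backward(panel2, obs)
  expect_lt(max(abs(as.matrix(post1[, c("p0", "p1", "p2")]) -
                    as.matrix(post2[, c("p0", "p1", "p2")]))), 1e-9)
})

test_that("a perfect panel copy is recovered at unobserved sites", {
  panel <- iid_panel(20, 200, seed = 10)
  truth <- panel_copy_target(panel)
  obs <- prune_to_panel(truth, 100, seed = 11)
  post <- forward_backward(panel, obs, params = hmm_params(eps = 1e-4))
  miss <- is.na(obs$g_obs)
  expect_true(all(post$g_map[miss] == truth$g[miss]))
})

test_that("observing a genotype boosts its own posterior to near-certainty", {
  eps <- 1e-3
  for (s in 1:8) {
    panel <- iid_panel(12, 50, seed = 100 + s)
    truth <- panel_copy_target(panel)
    obs <- prune_to_panel(truth, 15, seed = 200 + s)
    post_before <- forward_backward(panel, obs,
                                    params = hmm_params(eps = eps))
    m <- which(is.na(obs$g_obs))[1]
    g2 <- obs$g_obs
    g2[m] <- truth$g[m]
    obs2 <- observed_genotypes(obs$sites, g2, g_truth = truth$g)
    post_after <- forward_backward(panel, obs2,
                                   params = hmm_params(eps = eps))
    p_true <- function(post, m, g) as.matrix(post[, c("p0", "p1", "p2")])[m, g + 1]
    expect_gte(p_true(post_after, m, truth$g[m]) + 1e-12,
               p_true(post_before, m, truth$g[m]))
    expect_gte(p_true(post_after, m, truth$g[m]), 1 - 20 * eps)
  }
})

test_that("call_imputed applies the inclusive threshold rule", {
  sites <- simple_sites(4)
  post <- manual_posterior(sites, rbind(
    c(0.01, 0.95, 0.04),   # gp = 0.95, missing
    c(0.98, 0.01, 0.01),   # gp = 0.98, observed
    c(0.5, 0.3, 0.2),      # gp = 0.5, missing
    c(1, 0, 0)             # gp = 1, missing
  ))
  obs <- observed_genotypes(sites, c(NA, 0L, NA, NA))

  called <- call_imputed(post, obs, q_gp = 0.95)
  expect_identical(called$g, c(1L, 0L, NA, 0L))
  expect_identical(called$source, c("IMPUTED", "OBSERVED", NA, "IMPUTED"))
  expect_equal(called$gp, c(0.95, NA, NA, 1))

  floor_call <- call_imputed(post, obs, q_gp = 0)
  expect_true(all(!is.na(floor_call$g))) # gp >= 1/3 always
  strict <- call_imputed(post, obs, q_gp = 1)
  expect_identical(strict$g, c(NA, 0L, NA, 0L)) # only gp == 1 called
  expect_error(call_imputed(post, obs, q_gp = 1.2))
})

test_that("argmax ties break toward the lower genotype code", {
  sites <- simple_sites(2)
  post <- manual_posterior(sites, rbind(c(0.4, 0.4, 0.2), c(0.2, 0.4, 0.4)))
  expect_identical(post$g_map, c(0L, 1L))
})

test_that("target sites absent from the panel are flagged unimputable", {
  panel <- iid_panel(10, 50, seed = 12)
  truth <- panel_copy_target(panel)
  # extend the target list with a site the panel does not carry
  extra <- tibble::tibble(chrom = "chrT", pos = max(panel$sites$pos) + 500L,
                          id = "extra", ref = "A", alt = "G",
                          cm = max(panel$sites$cm))
  sites2 <- dplyr::bind_rows(panel$sites, extra)
  g2 <- c(truth$g, 1L)
  obs <- observed_genotypes(sites2, replace(rep(NA_integer_, 51),
                                            seq(1, 41, by = 2),
                                            g2[seq(1, 41, by = 2)]))
  res <- impute_sample(panel, obs, q_gp = 0)
  expect_equal(length(res$called$g), 51)
  expect_true(res$called$unimputable[51])
  expect_true(is.na(res$called$g[51]))
  expect_false(any(res$called$unimputable[1:50]))
  # panel-covered missing sites are all called at threshold 0
  expect_true(all(!is.na(res$called$g[1:50])))
})

test_that("site-list and allele mismatches are hard errors", {
  panel <- iid_panel(6, 20, seed = 13)
  obs_short <- observed_genotypes(panel$sites[1:10, ],
                                  rep(NA_integer_, 10))
  expect_error(forward_backward(panel, obs_short), "mismatch")
  sites_flip <- panel$sites
  sites_flip$ref[3] <- panel$sites$alt[3]
  sites_flip$alt[3] <- panel$sites$ref[3]
  obs_flip <- observed_genotypes(sites_flip, rep(NA_integer_, 20))
  expect_error(forward_backward(panel, obs_flip), "REF/ALT mismatch")
})

test_that("the Watterson auto-eps heuristic is applied when requested", {
  panel <- iid_panel(10, 30, seed = 14)
  obs <- observed_genotypes(panel$sites, rep(NA_integer_, 30))
  post <- forward_backward(panel, obs, params = hmm_params(eps = "auto"))
  theta <- 1 / sum(1 / seq_len(9))
  expect_equal(attr(post, "hmm_params")$eps, theta / (2 * (theta + 10)))
})
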