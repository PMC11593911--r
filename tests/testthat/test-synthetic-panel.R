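test_that("simulate_founders handles the empty and minimal cases", {
  p <- simulate_founders(10, 0, seed = 1)
  expect_s3_class(p, "haplotype_panel")
  expect_equal(n_panel_sites(p), 0)
  expect_equal(n_haplotypes(p), 10)

  p <- simulate_founders(20, 150, maf_min = 0.05, seed = 2)
  mac <- pmin(colSums(p$alleles), 20 - colSums(p$alleles))
  expect_true(all(mac >= 1)) # 0.05 * 20 = 1
  expect_true(all(diff(p$sites$pos) > 0))
  expect_true(all(diff(p$sites$cm) >= 0))
  expect_true(all(p$sites$ref != p$sites$alt))
})

test_that("simulate_founders rejects an unrepresentable maf_min", {
  expect_error(simulate_founders(3, 10, maf_min = 0.4), "not representable")
  expect_error(simulate_founders(10, 10, maf_min = 0.6))
})

test_that("simulate_founders is bit-identical under a fixed seed", {
  a <- simulate_founders(30, 200, seed = 7)
  b <- simulate_founders(30, 200, seed = 7)
  expect_identical(a, b)
  c <- simulate_founders(30, 200, seed = 8)
  expect_false(identical(a$alleles, c$alleles))
})

test_that("founder site-frequency spectrum matches its sampling distribution", {
  k <- 100
  n_sites <- 2000
  maf_min <- 0.05
  p <- simulate_founders(k, n_sites, maf_min = maf_min, seed = 11)
  mac_obs <- pmin(colSums(p$alleles), k - colSums(p$alleles))

  # independent oracle sampler for the stated generative process:
  # truncated-Beta frequency, Binomial alleles, redraw while the
  # minor-allele count is below the floor
  set.seed(4242)
  min_count <- max(1, ceiling(maf_min * k))
  draw_one <- function() {
    repeat {
      u <- runif(1, pbeta(maf_min, 0.8, 0.8), pbeta(1 - maf_min, 0.8, 0.8))
      x <- rbinom(1, k, qbeta(u, 0.8, 0.8))
      mac <- min(x, k - x)
      if (mac >= min_count) return(mac)
    }
  }
  mac_ref <- replicate(20000, draw_one())

  # chi-squared goodness of fit against the oracle's empirical law
  breaks <- c(seq(0, 45, by = 5), 51)
  o <- table(cut(mac_obs, breaks, right = FALSE))
  e_prob <- table(cut(mac_ref, breaks, right = FALSE)) / length(mac_ref)
  keep <- e_prob > 0
  chi2 <- sum((o[keep] - n_sites * e_prob[keep])^2 / (n_sites * e_prob[keep]))
  p_val <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
})

test_that("recombine_panel with zero generations copies founder rows", {
  f <- simulate_founders(15, 80, seed = 3)
  r <- recombine_panel(f, 15, n_generations = 0, seed = 4)
  # a permutation of the founders: same rows as a multiset
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_identical(key(r$alleles), key(f$alleles))
  # frequency conservation is exact
  expect_identical(allele_frequencies(r), allele_frequencies(f))
})

test_that("two-founder mosaics switch at the expected Poisson rate", {
  sites <- simple_sites(2000, rate_cm_per_mb = 10) # 20 cM span
  f <- haplotype_panel(sites, rbind(rep(0L, 2000), rep(1L, 2000)))
  g <- 100
  r <- recombine_panel(f, 200, n_generations = g, seed = 5)
  # every row is a step mosaic of 0- and 1-blocks by construction;
  # its switch count follows the Poisson switch process
  n_switch <- apply(r$alleles, 1, function(h) sum(diff(h) != 0))
  span_morgan <- (max(sites$cm) - min(sites$cm)) / 100
  # switches between the two founders occur at rate g/Morgan, and a
  # switch draw picks the other founder half the time
  expected <- g * span_morgan / 2
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(n_switch) - expected), 5 * se)
})

test_that("LD decays with genetic distance in recombined panels", {
  f <- simulate_founders(20, 800, maf_min = 0.1, seed = 6)
  r <- recombine_panel(f, 500, n_generations = 100, seed = 7)
  r2_close <- mean_r2_in_band(r, 0.005, 0.015)
  r2_far <- mean_r2_in_band(r, 0.9, 1.1)
  expect_gt(r2_close, r2_far)

  # monotone decay across distance bins (non-increasing, small slack)
  bands <- list(c(0, 0.02), c(0.02, 0.1), c(0.1, 0.5), c(0.5, 1.4))
  m <- vapply(bands, function(b) mean_r2_in_band(r, b[1], b[2]), numeric(1))
  expect_true(all(diff(m) <= 0.01))
})

test_that("split_populations hits its target divergence", {
  f <- simulate_founders(100, 5000, maf_min = 0.05, seed = 8)
  # identity case: statistically identical populations
  s0 <- split_populations(f, n_pops = 2, divergence = 0, sizes = c(200, 200),
                          n_generations = 50, seed = 9)
  expect_lt(abs(fst_wc(s0)), 0.01)

  s1 <- split_populations(f, n_pops = 2, divergence = 0.1, sizes = c(200, 200),
                          n_generations = 50, seed = 10)
  expect_lt(abs(fst_wc(s1) - 0.1), 0.03)

  # degenerate split: everything in population 1
  s2 <- split_populations(f, n_pops = 2, divergence = 0.1, sizes = c(100, 0),
                          n_generations = 50, seed = 11)
  expect_true(all(s2$pop == "POP1"))
})

test_that("sample_truth_individual sums two panel haplotypes", {
  sites <- simple_sites(40)
  h <- rbinom(40, 1, 0.5)
  panel <- haplotype_panel(sites, matrix(rep(h, 6), nrow = 6, byrow = TRUE))
  dr <- sample_truth_individual(panel, seed = 1)
  expect_identical(dr$truth$g, as.integer(2 * h))

  all_ref <- haplotype_panel(sites, matrix(0L, 4, 40))
  expect_identical(sample_truth_individual(all_ref, seed = 2)$truth$g,
                   rep(0L, 40))

  expect_error(sample_truth_individual(panel, pop = "EAS"), "at least 2")
})

test_that("truth draws match panel allele frequencies binomially", {
  panel <- simulate_founders(50, 5, maf_min = 0.2, seed = 12)
  p <- allele_frequencies(panel)[1]
  g1 <- vapply(1:1000, function(i) {
    sample_truth_individual(panel, seed = i)$truth$g[1]
  }, integer(1))
  se <- sqrt(p * (1 - p) / (2 * 1000))
  expect_lt(abs(mean(g1) / 2 - p), 3 * se)
})

test_that("sampled individuals are excluded from the downstream reference", {
  panel <- simulate_founders(20, 60, seed = 13)
  dr <- sample_truth_individual(panel, seed = 14)
  ref <- drop_haplotypes(panel, dr$exclude)
  expect_equal(n_haplotypes(ref), 18)
  key <- function(m) apply(m, 1, paste, collapse = "")
  expect_false(any(key(ref$alleles) %in% key(dr$haplotypes)))
})

test_that("panel validation catches malformed objects", {
  sites <- simple_sites(5)
  expect_error(haplotype_panel(sites, matrix(0L, 4, 3)), "columns")
  expect_error(haplotype_panel(sites, matrix(2L, 4, 5)), "0/1")
  bad_sites <- sites
  bad_sites$pos <- rev(bad_sites$pos)
  expect_error(haplotype_panel(bad_sites, matrix(0L, 4, 5)),
               "strictly increasing")
  bad_sites2 <- sites
  bad_sites2$alt <- bad_sites2$ref
  expect_error(haplotype_panel(bad_sites2, matrix(0L, 4, 5)), "differ")
})
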