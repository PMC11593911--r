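random_even_panel <- function(seed, k = NULL, l = NULL) {
  set.seed(seed)
  k <- k %||% (2 * sample(2:6, 1))
  l <- l %||% sample(5:30, 1)
  p <- simulate_founders(k, l, maf_min = 0, seed = seed)
  p$pop <- rep(sample(c("EUR", "EAS", "AFR"), k / 2, replace = TRUE), each = 2)
  p
}

test_that("panel VCF writing and reading are exact inverses", {
  dir <- withr::local_tempdir()
  for (s in 1:8) {
    p <- random_even_panel(s)
    f <- file.path(dir, paste0("panel", s, ".vcf"))
    write_panel_vcf(p, f)
    q <- read_panel_vcf(f)
    expect_identical(q$alleles, p$alleles)
    expect_identical(q$pop, p$pop)
    expect_identical(q$sites$pos, p$sites$pos)
    expect_identical(q$sites$cm, p$sites$cm) # %.17g round-trips doubles
    expect_identical(q$sites$ref, p$sites$ref)
  }
})

test_that("three diploid samples give six haplotypes", {
  dir <- withr::local_tempdir()
  p <- random_even_panel(3, k = 6, l = 10)
  f <- file.path(dir, "p.vcf")
  write_panel_vcf(p, f)
  expect_equal(n_haplotypes(read_panel_vcf(f)), 6)
})

test_that("non-biallelic-SNP records are skipped with a count", {
  dir <- withr::local_tempdir()
  p <- random_even_panel(4, k = 4, l = 10)
  f <- file.path(dir, "p.vcf")
  write_panel_vcf(p, f)
  lines <- readLines(f)
  i <- grep("^chrS\t", lines)[5]
  fields <- strsplit(lines[i], "\t")[[1]]
  fields[5] <- paste0(fields[5], ",T") # make record 5 multiallelic
  fields[5] <- sub("^(.),\\1$", "\\1,C", fields[5])
  lines[i] <- paste(fields, collapse = "\t")
  writeLines(lines, f)
  expect_message(q <- read_panel_vcf(f), "skipped 1")
  expect_equal(n_panel_sites(q), 9)
})

test_that("unphased or missing panel genotypes are hard errors", {
  dir <- withr::local_tempdir()
  p <- random_even_panel(5, k = 4, l = 8)
  f <- file.path(dir, "p.vcf")
  write_panel_vcf(p, f)
  lines <- readLines(f)
  i <- grep("^chrS\t", lines)[3]
  lines[i] <- sub("(\t[01])\\|([01])$", "\\1/\\2", lines[i])
  writeLines(lines, f)
  pos <- strsplit(lines[i], "\t")[[1]][2]
  expect_error(read_panel_vcf(f), pos)
})

test_that("region filters restrict panels to the requested window", {
  dir <- withr::local_tempdir()
  p <- random_even_panel(6, k = 4, l = 20)
  f <- file.path(dir, "p.vcf")
  write_panel_vcf(p, f)
  lo <- p$sites$pos[5]; hi <- p$sites$pos[12]
  q <- read_panel_vcf(f, region = paste0("chrS:", lo, "-", hi))
  expect_identical(q$sites$pos, p$sites$pos[5:12])
  expect_error(read_panel_vcf(f, region = "chrS:nonsense"), "region")
})

test_that("truth and observed genotype sets round-trip through VCF", {
  dir <- withr::local_tempdir()
  for (s in 1:5) {
    set.seed(s)
    l <- sample(10:60, 1)
    truth <- truth_genotypes(simple_sites(l), rbinom(l, 2, 0.5))
    ft <- file.path(dir, "t.vcf")
    write_truth_vcf(truth, ft)
    t2 <- read_truth_vcf(ft)
    expect_identical(t2$g, truth$g)
    expect_identical(t2$sites$pos, truth$sites$pos)

    obs <- inject_dropin(prune_to_panel(truth, round(l / 2), seed = s),
                         0.5, seed = s)
    fo <- file.path(dir, "o.vcf")
    write_observed_vcf(obs, fo)
    o2 <- read_observed_vcf(fo)
    expect_identical(o2$g_obs, obs$g_obs)
    expect_identical(o2$provenance, obs$provenance)
  }
})

test_that("imputed VCF output matches the GT:DS:GP dialect exactly", {
  dir <- withr::local_tempdir()
  sites <- simple_sites(3)
  post <- manual_posterior(sites, rbind(
    c(0.01, 0.95, 0.04),
    c(0.98, 0.015, 0.005),
    c(0.40, 0.35, 0.25)
  ))
  obs <- observed_genotypes(sites, c(NA, 0L, NA))
  called <- call_imputed(post, obs, q_gp = 0.95)
  f <- file.path(dir, "imp.vcf")
  write_imputed_vcf(called, post, f)
  lines <- readLines(f)
  body <- grep("^chrT\t", lines, value = TRUE)
  expect_match(body[1], "0/1:1.0300:0.0100,0.9500,0.0400:I", fixed = TRUE)
  expect_match(body[2], "0/0:0.0250:0.9800,0.0150,0.0050:O", fixed = TRUE)
  expect_match(body[3], "\\./\\.:0.8500:0.4000,0.3500,0.2500:\\.")
  # rounded GP triplets sum to 1 within 0.0002
  gp <- regmatches(body, regexpr("[0-9.]+,[0-9.]+,[0-9.]+", body))
  sums <- vapply(strsplit(gp, ","), function(x) sum(as.numeric(x)), numeric(1))
  expect_true(all(abs(sums - 1) <= 2e-4))

  rt <- read_imputed_vcf(f)
  expect_identical(rt$called$g, called$g)
  expect_identical(rt$called$source, called$source)
  expect_equal(rt$called$q_gp, 0.95)
  expect_lt(max(abs(as.matrix(rt$posterior[, c("p0", "p1", "p2")]) -
                    as.matrix(post[, c("p0", "p1", "p2")]))), 5.1e-5)
})

test_that("exclude_samples drops both haplotypes of each named sample", {
  p <- random_even_panel(7, k = 10, l = 12)
  p$samples <- paste0("S", 1:5)
  expect_identical(exclude_samples(p, character(0))$alleles, p$alleles)
  q <- exclude_samples(p, "S2")
  expect_equal(n_haplotypes(q), 8)
  expect_identical(q$alleles, p$alleles[-c(3, 4), ])
  expect_identical(q$samples, c("S1", "S3", "S4", "S5"))
  expect_error(exclude_samples(p, "S9"), "unknown sample")
})

test_that("genetic maps are exact linear conversions with flat extrapolation", {
  m <- make_genetic_map(c(1e6, 2e6), rate_cm_per_mb = 1)
  expect_equal(map_cm(m, 1e6), 1.0)
  expect_equal(map_cm(m, 2e6), 2.0)
  expect_equal(map_cm(make_genetic_map(c(1e6, 2e6), 1.3), 2e6), 2.6)
  expect_equal(map_cm(make_genetic_map(c(10, 100), 0), 50), 0)
  # constant extrapolation beyond the knots
  expect_equal(map_cm(m, 5e6), 2.0)
  expect_equal(map_cm(m, 0), 1.0)
  # interpolation between knots
  expect_equal(map_cm(m, 1.5e6), 1.5)
  expect_error(make_genetic_map(c(5, 2)), "sorted")
  expect_error(genetic_map(tibble::tibble(chrom = "c", pos = c(1, 2),
                                          cm = c(2, 1))), "non-decreasing")
})

test_that("hapmap-style and knot-format map files are readable", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "map.txt")
  writeLines(c("Chromosome Position(bp) Rate(cM/Mb) Map(cM)",
               "chr22 100000 1.2 0.12",
               "chr22 200000 1.5 0.27",
               "chr22 400000 1.0 0.47"), f1)
  m1 <- read_genetic_map(f1, format = "hapmap")
  expect_equal(map_cm(m1, c(100000, 400000)), c(0.12, 0.47))
  expect_equal(map_cm(m1, 300000), 0.37)

  f2 <- file.path(dir, "knots.txt")
  writeLines(c("1000 0.0", "2000 0.5"), f2)
  m2 <- read_genetic_map(f2, format = "knots", chrom = "chrZ")
  expect_equal(map_cm(m2, 1500), 0.25)
})
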