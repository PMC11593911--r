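# Shared fixture builders.  Everything is generated in code at test time;
# no stored data.

# iid-site panel (no LD): good enough for HMM unit tests where the target
# is constructed from panel rows
iid_panel <- function(k = 20, l = 200, seed = 1, maf_min = 0.05) {
  simulate_founders(k, l, maf_min = maf_min, seed = seed)
}

# target individual built from two panel haplotypes (kept in the panel)
panel_copy_target <- function(panel, rows = c(1, 2)) {
  g <- as.integer(colSums(panel$alleles[rows, , drop = FALSE]))
  truth_genotypes(panel$sites, g)
}

# quick posterior_field construction for calling/scoring tests
manual_posterior <- function(sites, p) {
  stopifnot(ncol(p) == 3)
  out <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    p0 = p[, 1], p1 = p[, 2], p2 = p[, 3],
    dosage = p[, 2] + 2 * p[, 3],
    gp = pmax(p[, 1], p[, 2], p[, 3]),
    g_map = max.col(p, ties.method = "first") - 1L
  )
  class(out) <- c("posterior_field", class(out))
  out
}

# hand-built called_genotypes (for metric arithmetic tests)
manual_called <- function(sites, g, source, gp = NULL, q_gp = 0.95) {
  structure(
    list(sites = sites, g = as.integer(g), source = source,
         gp = gp %||% rep(NA_real_, length(g)), q_gp = q_gp,
         unimputable = rep(FALSE, length(g))),
    class = "called_genotypes"
  )
}

simple_sites <- function(l, chrom = "chrT", spacing_bp = 1000,
                         rate_cm_per_mb = 1) {
  pos <- as.integer(seq_len(l) * spacing_bp)
  tibble::tibble(chrom = chrom, pos = pos, id = paste0("s", seq_len(l)),
                 ref = "A", alt = "G", cm = rate_cm_per_mb * pos / 1e6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean pairwise r^2 between panel columns whose cM distance falls in
# [lo, hi); at most n_pairs random pairs
mean_r2_in_band <- function(panel, lo, hi, n_pairs = 300, seed = 1) {
  cm <- panel$sites$cm
  l <- length(cm)
  set.seed(seed)
  pairs <- matrix(sample.int(l, 2 * n_pairs * 8, replace = TRUE), ncol = 2)
  d <- abs(cm[pairs[, 1]] - cm[pairs[, 2]])
  sel <- which(d >= lo & d < hi & pairs[, 1] != pairs[, 2])
  sel <- head(sel, n_pairs)
  if (length(sel) < 20) stop("not enough site pairs in band [", lo, ",", hi, ")")
  r2 <- vapply(sel, function(s) {
    x <- panel$alleles[, pairs[s, 1]]
    y <- panel$alleles[, pairs[s, 2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}
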