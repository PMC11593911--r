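#' VCF input/output
#'
#' All pipeline objects round-trip through plain-text VCF 4.2 so that real
#' phased panels can substitute for synthetic ones: reference panels are
#' fully phased (`|` separator), degraded targets and truth samples are
#' unphased (`/`), and missing genotypes are `./.`.  Only biallelic SNP
#' records are supported; other records are skipped with a reported
#' count on reading.  Genetic-map positions are carried in a `CM` INFO
#' field so panels round-trip exactly; degradation provenance rides in a
#' single-character `PV` FORMAT field.  REF/ALT mismatches between target
#' and panel are hard errors — allele harmonisation is delegated to
#' dedicated external tooling.
#'
#' @name vcf_io
NULL

vcf_header <- function(contigs, format_lines = c(), meta = c()) {
  c("##fileformat=VCFv4.2",
    "##source=forensimpute",
    paste0("##contig=<ID=", unique(contigs), ">"),
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in cM\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    format_lines, meta)
}

gt_unphased <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

write_vcf_lines <- function(path, header, sites, format, sample_names,
                            sample_fields) {
  body <- paste(sites$chrom, sites$pos,
                if ("id" %in% names(sites)) sites$id else ".",
                sites$ref, sites$alt, ".", "PASS",
                sprintf("CM=%.17g", sites$cm), format,
                sep = "\t")
  for (f in sample_fields) body <- paste(body, f, sep = "\t")
  writeLines(c(header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_names),
                     collapse = "\t"),
               body),
             path)
  invisible(path)
}

#' Write a phased reference panel as VCF
#'
#' @param panel a [haplotype_panel()] with an even number of haplotypes;
#'   rows `2i - 1` and `2i` form diploid donor `i`.
#' @param path output path (plain-text `.vcf`).
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  k <- n_haplotypes(panel)
  if (k %% 2 != 0) stop("panel must have an even number of haplotypes")
  n_samp <- k / 2
  samples <- panel$samples %||% paste0("S", seq_len(n_samp))
  pops <- panel$pop[seq(1, k, by = 2)]
  meta <- paste0("##SAMPLE=<ID=", samples, ",Population=", pops, ">")
  a1 <- panel$alleles[seq(1, k, by = 2), , drop = FALSE]
  a2 <- panel$alleles[seq(2, k, by = 2), , drop = FALSE]
  fields <- lapply(seq_len(n_samp), function(i) {
    paste0(a1[i, ], "|", a2[i, ])
  })
  write_vcf_lines(path, vcf_header(panel$sites$chrom, meta = meta),
                  panel$sites, "GT", samples, fields)
}

#' Read a phased reference panel from VCF
#'
#' Accepts plain or bgzipped VCF.  Only biallelic SNP records are kept
#' (others are skipped and counted); every genotype must be present and
#' phased, otherwise reading fails naming the offending record.
#'
#' @param path input VCF path.
#' @param region optional region filter `"chrom:start-end"` (1-based,
#'   inclusive).
#' @param map optional [genetic_map] used to assign cM positions; when
#'   absent, cM is taken from the `CM` INFO field if present, else 0.
#' @return a [haplotype_panel()] with `K = 2 * n_samples` haplotypes in
#'   file order.
#' @export
read_panel_vcf <- function(path, region = NULL, map = NULL) {
  parsed <- read_vcf_table(path, region = region, map = map)
  gt <- parsed$gt
  bad <- matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  unphased <- which(bad, arr.ind = TRUE)
  if (nrow(unphased) > 0) {
    r <- unphased[1, 1]
    stop("panel VCF contains an unphased or missing genotype at ",
         parsed$sites$chrom[r], ":", parsed$sites$pos[r],
         " (sample ", colnames(gt)[unphased[1, 2]], ")")
  }
  n_samp <- ncol(gt)
  l <- nrow(gt)
  alleles <- matrix(0L, 2 * n_samp, l)
  alleles[seq(1, 2 * n_samp, by = 2), ] <- t(matrix(as.integer(substr(gt, 1, 1)), l))
  alleles[seq(2, 2 * n_samp, by = 2), ] <- t(matrix(as.integer(substr(gt, 3, 3)), l))
  pops <- parsed$pops[colnames(gt)]
  pops[is.na(pops)] <- "POP1"
  haplotype_panel(parsed$sites, alleles, pop = rep(pops, each = 2),
                  samples = colnames(gt))
}

# Shared VCF reading: biallelic-SNP filter, INFO/CM parsing, region filter.
read_vcf_table <- function(path, region = NULL, map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message("skipped ", n_skip, " non-biallelic-SNP record(s)")
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    pos <- as.integer(fix[, "POS"])
    keep <- keep & fix[, "CHROM"] == m[2] &
      pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  info <- vcf@fix[keep, "INFO"]
  cm_info <- suppressWarnings(as.numeric(sub(".*CM=([^;]+).*", "\\1", info)))
  cm_info[!grepl("CM=", info)] <- NA_real_
  sites <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    id = fix[keep, "ID"],
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"],
    cm = cm_info
  )
  if (!is.null(map)) {
    sites$cm <- map_cm(map, sites$pos, sites$chrom)
  }
  sites$cm[is.na(sites$cm)] <- 0
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  pv <- if ("PV" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    vcfR::extract.gt(vcf, element = "PV")[keep, , drop = FALSE]
  } else {
    NULL
  }
  meta <- vcf@meta
  samp_lines <- meta[grepl("^##SAMPLE=", meta)]
  pops <- setNames(
    sub(".*Population=([^,>]+).*", "\\1", samp_lines),
    sub(".*ID=([^,>]+).*", "\\1", samp_lines)
  )
  list(sites = sites, gt = gt, pv = pv, pops = pops, meta = meta,
       n_skipped = n_skip)
}

#' Write a truth genotype set as unphased VCF
#'
#' @param truth a [truth_genotypes] object.
#' @param path output path.
#' @param sample_id sample column name.
#' @return the path, invisibly.
#' @export
write_truth_vcf <- function(truth, path, sample_id = "TRUTH") {
  write_vcf_lines(path, vcf_header(truth$sites$chrom),
                  truth$sites, "GT", sample_id,
                  list(gt_unphased[as.character(truth$g)]))
}

#' @rdname write_truth_vcf
#' @return for `read_truth_vcf`, a [truth_genotypes] object.
#' @param map optional [genetic_map] for cM positions.
#' @export
read_truth_vcf <- function(path, map = NULL) {
  parsed <- read_vcf_table(path, map = map)
  g <- decode_unphased_gt(parsed$gt[, 1], parsed$sites)
  if (anyNA(g)) stop("truth VCF contains missing genotypes")
  truth_genotypes(parsed$sites, g)
}

decode_unphased_gt <- function(gt, sites) {
  g <- rep(NA_integer_, length(gt))
  known <- !is.na(gt) & gt != "./."
  bad <- known & !gt %in% c("0/0", "0/1", "1/0", "1/1")
  if (any(bad)) {
    r <- which(bad)[1]
    stop("unsupported genotype '", gt[r], "' at ",
         sites$chrom[r], ":", sites$pos[r])
  }
  g[known] <- as.integer(substr(gt[known], 1, 1)) +
    as.integer(substr(gt[known], 3, 3))
  g
}

#' Write a degraded (observed) genotype set as unphased VCF
#'
#' The per-site degradation provenance is written as the single-character
#' `PV` FORMAT field (`O` observed, `E` observed-erroneous, `M` missing)
#' so that truth comparisons survive the round trip.
#'
#' @param obs an [observed_genotypes] object.
#' @param path output path.
#' @param sample_id sample column name.
#' @return the path, invisibly.
#' @export
write_observed_vcf <- function(obs, path, sample_id = "SAMPLE") {
  gt <- rep("./.", length(obs$g_obs))
  known <- !is.na(obs$g_obs)
  gt[known] <- gt_unphased[as.character(obs$g_obs[known])]
  pv <- c(OBSERVED = "O", OBSERVED_ERRONEOUS = "E", MISSING = "M")[obs$provenance]
  fmt_line <- "##FORMAT=<ID=PV,Number=1,Type=Character,Description=\"Degradation provenance: O observed, E observed erroneous, M missing\">"
  write_vcf_lines(path, vcf_header(obs$sites$chrom, format_lines = fmt_line),
                  obs$sites, "GT:PV", sample_id,
                  list(paste0(gt, ":", pv)))
}

#' @rdname write_observed_vcf
#' @param map optional [genetic_map] for cM positions.
#' @return for `read_observed_vcf`, an [observed_genotypes] object (truth
#'   is not stored in the file, so only provenance is recovered).
#' @export
read_observed_vcf <- function(path, map = NULL) {
  parsed <- read_vcf_table(path, map = map)
  g <- decode_unphased_gt(parsed$gt[, 1], parsed$sites)
  prov <- if (!is.null(parsed$pv)) {
    c(O = "OBSERVED", E = "OBSERVED_ERRONEOUS", M = "MISSING")[parsed$pv[, 1]]
  } else {
    NULL
  }
  observed_genotypes(parsed$sites, g, provenance = unname(prov))
}

#' Write imputation output as VCF
#'
#' Conventional imputation-output dialect: FORMAT `GT:DS:GP:SR` with the
#' alt-allele dosage (`DS`) and the three genotype posteriors (`GP`)
#' printed to 4 decimals (after rounding the three GP values sum to 1
#' within 0.0002), plus the call source `SR` (`O` observed, `I` imputed,
#' `.` uncalled).  Uncalled sites get GT `./.` with DS/GP still emitted.
#' The calling threshold is recorded as a header metadata line.
#'
#' @param called a `called_genotypes` object.
#' @param post the matching `posterior_field`.
#' @param path output path.
#' @param sample_id sample column name.
#' @return the path, invisibly.
#' @export
write_imputed_vcf <- function(called, post, path, sample_id = "SAMPLE") {
  if (nrow(post) != length(called$g)) {
    stop("called genotypes and posterior have different site counts")
  }
  gt <- rep("./.", length(called$g))
  known <- !is.na(called$g)
  gt[known] <- gt_unphased[as.character(called$g[known])]
  sr <- dplyr::case_when(is.na(called$source) ~ ".",
                         called$source == "OBSERVED" ~ "O",
                         .default = "I")
  field <- sprintf("%s:%.4f:%.4f,%.4f,%.4f:%s",
                   gt, post$dosage, post$p0, post$p1, post$p2, sr)
  fmt <- c(
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">",
    "##FORMAT=<ID=SR,Number=1,Type=Character,Description=\"Call source: O observed, I imputed\">",
    sprintf("##imputation_q_gp=%.17g", called$q_gp)
  )
  write_vcf_lines(path, vcf_header(called$sites$chrom, format_lines = fmt),
                  called$sites, "GT:DS:GP:SR", sample_id, list(field))
}

#' @rdname write_imputed_vcf
#' @param map optional [genetic_map] for cM positions.
#' @return for `read_imputed_vcf`, a list with `called` (a
#'   `called_genotypes` object) and `posterior` (a `posterior_field`
#'   recovered at print precision).
#' @export
read_imputed_vcf <- function(path, map = NULL) {
  parsed <- read_vcf_table(path, map = map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gp <- vcfR::extract.gt(vcf, element = "GP")[, 1]
  ds <- as.numeric(vcfR::extract.gt(vcf, element = "DS")[, 1])
  sr <- vcfR::extract.gt(vcf, element = "SR")[, 1]
  pmat <- do.call(rbind, lapply(strsplit(gp, ","), as.numeric))
  q_line <- parsed$meta[grepl("^##imputation_q_gp=", parsed$meta)]
  q_gp <- if (length(q_line) > 0) as.numeric(sub(".*=", "", q_line[1])) else NA_real_
  g <- decode_unphased_gt(parsed$gt[, 1], parsed$sites)
  source <- dplyr::case_when(sr == "O" ~ "OBSERVED",
                             sr == "I" ~ "IMPUTED",
                             .default = NA_character_)
  gp_val <- rep(NA_real_, length(g))
  imp <- !is.na(source) & source == "IMPUTED"
  gp_val[imp] <- pmax(pmat[imp, 1], pmat[imp, 2], pmat[imp, 3])
  called <- structure(
    list(sites = parsed$sites, g = g, source = source, gp = gp_val,
         q_gp = q_gp, unimputable = rep(FALSE, length(g))),
    class = "called_genotypes"
  )
  post <- tibble::tibble(
    chrom = parsed$sites$chrom, pos = parsed$sites$pos,
    p0 = pmat[, 1], p1 = pmat[, 2], p2 = pmat[, 3],
    dosage = ds,
    gp = pmax(pmat[, 1], pmat[, 2], pmat[, 3]),
    g_map = max.col(pmat, ties.method = "first") - 1L
  )
  class(post) <- c("posterior_field", class(post))
  list(called = called, posterior = post)
}

#' Remove named diploid samples from a panel
#'
#' Drops both haplotypes of each named sample — the leave-one-out step
#' before imputing a panel member.
#'
#' @param panel a [haplotype_panel()] with an even number of haplotypes.
#' @param sample_ids character ids (matching `panel$samples`, or the
#'   default `S1 ... Sn` numbering).
#' @return a [haplotype_panel()] without those samples.
#' @export
exclude_samples <- function(panel, sample_ids) {
  k <- n_haplotypes(panel)
  if (k %% 2 != 0) stop("panel must pair haplotypes into diploid samples")
  samples <- panel$samples %||% paste0("S", seq_len(k / 2))
  idx <- match(sample_ids, samples)
  if (anyNA(idx)) {
    stop("unknown sample id(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 0) return(panel)
  rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  out <- drop_haplotypes(panel, rows)
  out$samples <- samples[-idx]
  out
}
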