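#' Filter configuration for temporal variant datasets
#'
#' Thresholds for the site- and genotype-level filters that build a merged
#' historical/contemporary ("temporal") dataset from low-coverage genomes:
#' site quality and missingness; the contemporary per-genotype depth/quality
#' filter (DP >= 6, GQ > 15); the temporal variant-allele-depth rule (>= 3
#' reads supporting the variant); the allele-balance window `[0.35, 0.75]`
#' outside of which heterozygotes are recoded to the majority-allele
#' homozygote; and the deamination guard that removes transition sites whose
#' cohort-wide variant allele count is below 3.
#'
#' @param min_qual minimum site QUAL (applied when QUAL is present)
#' @param max_missing_fraction maximum fraction of missing genotypes per site
#' @param min_dp minimum genotype depth (contemporary filter)
#' @param min_gq genotype quality must exceed this (contemporary filter)
#' @param min_variant_depth minimum reads supporting the variant allele for
#'   genotypes asserting it (temporal filter)
#' @param balance allele-balance bounds (closed interval) for heterozygotes
#' @param min_transition_count minimum cohort-wide variant allele count for
#'   transition sites
#' @param autosomes optional character vector of autosomal contig names;
#'   sites on other contigs are removed by [filter_sites()]
#' @return object of class `filter_config`
#' @export
filter_config <- function(min_qual = 40, max_missing_fraction = 0.001,
                          min_dp = 6, min_gq = 15, min_variant_depth = 3,
                          balance = c(0.35, 0.75),
                          min_transition_count = 3, autosomes = NULL) {
  stopifnot(length(balance) == 2, balance[1] > 0, balance[2] < 1,
            balance[1] < balance[2],
            min_dp >= 1, min_variant_depth >= 1, min_transition_count >= 1)
  structure(list(min_qual = min_qual,
                 max_missing_fraction = max_missing_fraction,
                 min_dp = min_dp, min_gq = min_gq,
                 min_variant_depth = min_variant_depth,
                 balance = balance,
                 min_transition_count = min_transition_count,
                 autosomes = autosomes),
            class = "filter_config")
}

#' Site-level filtering of a variant dataset
#'
#' Retains biallelic autosomal SNPs that pass the QUAL threshold (when a
#' `qual` column is present) and the per-site missingness threshold. Site
#' order is preserved.
#'
#' @param gm a [genotype_matrix()]
#' @param sites aligned site table; optional columns `qual` and
#'   `is_biallelic`
#' @param config a [filter_config()]
#' @return list with `genotypes`, `sites` and a `report` data.frame
#' @export
filter_sites <- function(gm, sites, config = filter_config()) {
  check_aligned(gm, sites)
  n0 <- nrow(sites)
  keep <- rep(TRUE, n0)
  removed <- c(non_biallelic = 0L, non_autosomal = 0L, low_qual = 0L,
               missingness = 0L)
  if (!is.null(sites$is_biallelic)) {
    removed["non_biallelic"] <- sum(!sites$is_biallelic)
    keep <- keep & sites$is_biallelic
  } else {
    multi <- grepl(",", sites$alt) | !sites$alt %in% c("A", "C", "G", "T") |
      !sites$ref %in% c("A", "C", "G", "T")
    removed["non_biallelic"] <- sum(multi)
    keep <- keep & !multi
  }
  if (!is.null(config$autosomes)) {
    auto <- sites$chrom %in% config$autosomes
    removed["non_autosomal"] <- sum(keep & !auto)
    keep <- keep & auto
  }
  if (!is.null(sites$qual)) {
    okq <- is.na(sites$qual) | sites$qual > config$min_qual
    removed["low_qual"] <- sum(keep & !okq)
    keep <- keep & okq
  }
  miss <- colMeans(is.na(gm$gt))
  okm <- miss <= config$max_missing_fraction
  removed["missingness"] <- sum(keep & !okm)
  keep <- keep & okm
  report <- data.frame(rule = names(removed),
                       sites_removed = as.integer(removed),
                       genotypes_recoded = 0L, genotypes_missing = 0L)
  out_sites <- sites[keep, , drop = FALSE]
  rownames(out_sites) <- NULL
  list(genotypes = subset_genotypes(gm, sites = keep),
       sites = out_sites, report = report)
}

#' Contemporary per-genotype depth/quality filter
#'
#' Sets genotypes with `DP < min_dp` or `GQ <= min_gq` to missing,
#' mirroring the expression `MIN(FMT/DP)>5 & MIN(FMT/GQ)>15`. Other
#' genotypes are untouched; the filter is idempotent.
#'
#' @param gm a [genotype_matrix()] with `dp` and `gq`
#' @param config a [filter_config()]
#' @param cohorts cohort labels to apply the filter to (default: all)
#' @return list with `genotypes` and a `report` data.frame
#' @export
filter_genotypes_contemporary <- function(gm, config = filter_config(),
                                          cohorts = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$dp) || is.null(gm$gq)) {
    stop("DP and GQ are required for the contemporary genotype filter")
  }
  rows <- if (is.null(cohorts)) seq_len(nrow(gm$gt))
          else which(gm$samples$cohort %in% cohorts)
  gt <- gm$gt
  bad <- !is.na(gt) & (gm$dp < config$min_dp | gm$gq <= config$min_gq)
  bad[setdiff(seq_len(nrow(gt)), rows), ] <- FALSE
  gt[bad] <- NA_integer_
  report <- data.frame(rule = "dp_gq", sites_removed = 0L,
                       genotypes_recoded = 0L,
                       genotypes_missing = sum(bad))
  list(genotypes = genotype_matrix(gt, gm$samples, dp = gm$dp, gq = gm$gq,
                                   ad_ref = gm$ad_ref, ad_alt = gm$ad_alt),
       report = report)
}

#' Harmonize a merged historical/contemporary dataset
#'
#' The bespoke temporal genotype filter, in three steps:
#'
#' 1. heterozygous calls whose variant-allele read fraction
#'    `alt/(ref+alt)` falls outside the closed balance interval are recoded
#'    to the homozygote of the allele with more reads (ties go to the
#'    reference allele);
#' 2. genotypes still asserting the variant allele (het or hom-alt) with
#'    fewer than `min_variant_depth` supporting reads are set missing
#'    (hom-ref calls are never touched);
#' 3. transition sites whose variant allele count across all retained
#'    genotypes in the combined cohort is below `min_transition_count` are
#'    removed entirely — the deamination guard. Transversion sites are
#'    exempt.
#'
#' @param gm a [genotype_matrix()] with allelic depths
#' @param sites aligned site table with `is_transition`
#' @param config a [filter_config()]
#' @return list with `genotypes`, `sites` and a `report` data.frame
#' @export
harmonize_temporal <- function(gm, sites, config = filter_config()) {
  check_aligned(gm, sites)
  if (is.null(gm$ad_ref) || is.null(gm$ad_alt)) {
    no_ad <- gm$samples$sample_id[1]
    stop("allelic depths (AD) are required for harmonize_temporal; ",
         "missing for sample ", no_ad)
  }
  gt <- gm$gt
  tot <- gm$ad_ref + gm$ad_alt

  # (1) Mendelian-balance recode of heterozygotes
  bal <- gm$ad_alt / ifelse(tot == 0, NA, tot)
  het <- !is.na(gt) & gt == 1L
  out_of_balance <- het & !is.na(bal) &
    (bal < config$balance[1] | bal > config$balance[2])
  to_alt <- out_of_balance & gm$ad_alt > gm$ad_ref
  to_ref <- out_of_balance & !to_alt       # ties recoded toward reference
  gt[to_ref] <- 0L
  gt[to_alt] <- 2L

  # (2) variant-allele depth: genotypes asserting the variant need >= 3 reads
  assert_var <- !is.na(gt) & gt >= 1L
  low_support <- assert_var & gm$ad_alt < config$min_variant_depth
  gt[low_support] <- NA_integer_

  # (3) transition sites with cohort-wide variant allele count < 3 removed
  alt_count <- colSums(gt, na.rm = TRUE)
  drop_site <- sites$is_transition & alt_count < config$min_transition_count
  keep <- !drop_site

  report <- data.frame(
    rule = c("balance_recode", "variant_depth", "transition_count"),
    sites_removed = c(0L, 0L, sum(drop_site)),
    genotypes_recoded = c(sum(out_of_balance), 0L, 0L),
    genotypes_missing = c(0L, sum(low_support), 0L)
  )
  gm2 <- genotype_matrix(gt, gm$samples, dp = gm$dp, gq = gm$gq,
                         ad_ref = gm$ad_ref, ad_alt = gm$ad_alt)
  out_sites <- sites[keep, , drop = FALSE]
  rownames(out_sites) <- NULL
  list(genotypes = subset_genotypes(gm2, sites = keep),
       sites = out_sites, report = report)
}

#' Restrict a site table to transversion sites
#'
#' The transversion-only subset serves as a control dataset largely immune
#' to deamination artifacts.
#'
#' @param sites site table with `is_transition`
#' @return the subset of `sites` with transversions only; counts of
#'   removed/retained sites are attached as attributes `removed` and
#'   `retained`
#' @export
transversions_only <- function(sites) {
  stopifnot(is.data.frame(sites), !is.null(sites$is_transition))
  keep <- !sites$is_transition
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  attr(out, "retained") <- sum(keep)
  out
}
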