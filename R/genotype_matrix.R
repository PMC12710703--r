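#' Cohort genotype matrix
#'
#' The central data container: diploid genotype calls for samples x sites,
#' with optional per-cell read-depth (`DP`), genotype-quality (`GQ`) and
#' allelic-depth (`AD`) metadata, plus a sample/cohort table. Genotypes are
#' coded as alt-allele counts: 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` =
#' missing.
#'
#' @param gt integer matrix (samples x sites) of alt-allele counts with
#'   sample ids as rownames
#' @param samples data.frame with at least `sample_id` and `cohort`
#'   columns; optional `mean_depth`, `sampling_year`
#' @param dp,gq,ad_ref,ad_alt optional numeric matrices of the same
#'   dimension as `gt`
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(gt, samples, dp = NULL, gq = NULL,
                            ad_ref = NULL, ad_alt = NULL) {
  stopifnot(is.matrix(gt))
  if (!all(gt %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be coded 0, 1, 2 or NA")
  }
  storage.mode(gt) <- "integer"
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "cohort") %in% names(samples)),
            nrow(samples) == nrow(gt))
  rownames(gt) <- samples$sample_id
  for (m in list(dp, gq, ad_ref, ad_alt)) {
    if (!is.null(m) && !identical(dim(m), dim(gt))) {
      stop("metadata matrices must match the genotype matrix dimensions")
    }
  }
  if (!is.null(ad_ref) && !is.null(ad_alt) && !is.null(dp)) {
    over <- which(ad_ref + ad_alt > dp)
    if (length(over) > 0) stop("allelic depths exceed DP at ",
                               length(over), " cells")
  }
  structure(list(gt = gt, dp = dp, gq = gq, ad_ref = ad_ref,
                 ad_alt = ad_alt, samples = samples),
            class = "genotype_matrix")
}

#' @exportS3Method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$gt), "samples x", ncol(x$gt), "sites\n")
  cat("Cohorts:", paste(sprintf("%s (%d)", names(table(x$samples$cohort)),
                                table(x$samples$cohort)), collapse = ", "), "\n")
  cat("Metadata:", paste(c("DP", "GQ", "AD")[!vapply(
    list(x$dp, x$gq, x$ad_ref), is.null, logical(1))], collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method dim genotype_matrix
dim.genotype_matrix <- function(x) dim(x$gt)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x a [genotype_matrix()]
#' @param samples logical/integer/character index over samples
#' @param sites logical/integer index over sites
#' @return a [genotype_matrix()]
#' @export
subset_genotypes <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(x$gt))
  if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
  if (is.null(sites)) sites <- seq_len(ncol(x$gt))
  take <- function(m) if (is.null(m)) NULL else m[samples, sites, drop = FALSE]
  genotype_matrix(x$gt[samples, sites, drop = FALSE],
                  x$samples[samples, , drop = FALSE],
                  dp = take(x$dp), gq = take(x$gq),
                  ad_ref = take(x$ad_ref), ad_alt = take(x$ad_alt))
}

#' Per-site alternate-allele frequencies among non-missing genotypes
#'
#' @param x a [genotype_matrix()]
#' @param cohort optional cohort label to restrict to
#' @return numeric vector of length `ncol(x$gt)`; `NaN` where a site has no
#'   non-missing genotype
#' @export
allele_frequencies <- function(x, cohort = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt <- x$gt
  if (!is.null(cohort)) gt <- gt[x$samples$cohort %in% cohort, , drop = FALSE]
  colSums(gt, na.rm = TRUE) / (2 * colSums(!is.na(gt)))
}

#' Per-site alternate-allele counts and gene-copy totals
#'
#' @inheritParams allele_frequencies
#' @return data.frame with `alt_count` and `n_copies` (non-missing gene
#'   copies) per site
#' @export
allele_counts <- function(x, cohort = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt <- x$gt
  if (!is.null(cohort)) gt <- gt[x$samples$cohort %in% cohort, , drop = FALSE]
  data.frame(alt_count = colSums(gt, na.rm = TRUE),
             n_copies = 2L * colSums(!is.na(gt)))
}

# internal: validate a site table against a genotype matrix
check_aligned <- function(x, sites) {
  if (!inherits(x, "genotype_matrix")) stop("not a genotype_matrix")
  if (!is.data.frame(sites)) stop("sites must be a data.frame")
  if (nrow(sites) != ncol(x$gt)) {
    stop("site table (", nrow(sites), " rows) and genotype matrix (",
         ncol(x$gt), " sites) are misaligned")
  }
  invisible(TRUE)
}

# internal: transition test for allele pairs
is_transition_pair <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
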