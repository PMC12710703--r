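#' Write a cohort genotype matrix to VCF 4.2
#'
#' Emits a multi-sample VCF with per-genotype GT, DP, AD and GQ fields and
#' an INFO `IMPACT` tag. Contigs are taken from the site table; positions
#' are 1-based. Internal bookkeeping columns of the site table (e.g. the
#' `injected` ground-truth flag of the artifact generator, selection
#' coefficients) are not written.
#'
#' @param gm a [genotype_matrix()]
#' @param sites aligned site table
#' @param path output file path
#' @param contig_lengths optional named vector of contig lengths
#' @return `path`, invisibly
#' @export
write_cohort_vcf <- function(gm, sites, path, contig_lengths = NULL) {
  check_aligned(gm, sites)
  n <- nrow(sites)
  chroms <- chroms_in_order(sites$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(chroms, function(ch) {
      max(sites$pos[sites$chrom == ch])
    }, numeric(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenerode",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            as.integer(contig_lengths[chroms])),
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted functional impact\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  gt_str[is.na(gm$gt)] <- "./."
  has_meta <- !is.null(gm$dp)
  if (has_meta) {
    cells <- sprintf("%s:%d:%d,%d:%d", gt_str, gm$dp, gm$ad_ref, gm$ad_alt,
                     gm$gq)
    cells <- matrix(cells, nrow = nrow(gm$gt))
    cells[is.na(gm$gt)] <- sprintf(
      "./.:%d:%d,%d:%d", gm$dp[is.na(gm$gt)], gm$ad_ref[is.na(gm$gt)],
      gm$ad_alt[is.na(gm$gt)], gm$gq[is.na(gm$gt)])
    fmt <- "GT:DP:AD:GQ"
  } else {
    cells <- gt_str
    fmt <- "GT"
  }
  info <- if (!is.null(sites$impact)) {
    paste0("IMPACT=", sites$impact)
  } else {
    rep(".", n)
  }
  qual <- if (!is.null(sites$qual)) {
    ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE))
  } else {
    rep(".", n)
  }
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, qual,
                "PASS", info, fmt,
                apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample/cohort table to TSV
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cohort_tsv <- function(gm, path) {
  utils::write.table(gm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix and site table
#'
#' Parses GT, DP, GQ and AD FORMAT fields and the INFO `IMPACT` tag.
#' Multiallelic records are retained with `is_biallelic = FALSE` so that
#' [filter_sites()] can remove (and count) them.
#'
#' @param path VCF file path
#' @param cohorts optional data.frame (`sample_id`, `cohort`, ...) or path
#'   to a cohort TSV; samples default to a single `"all"` cohort
#' @return list with `genotypes` and `sites`
#' @export
read_cohort_vcf <- function(path, cohorts = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sample_ids <- colnames(v@gt)[-1]

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  gt <- matrix(code(gt_raw), nrow = nrow(gt_raw))
  num_mat <- function(el) {
    x <- try(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
             silent = TRUE)
    if (inherits(x, "try-error") || all(is.na(x))) return(NULL)
    m <- matrix(as.numeric(x), nrow = nrow(gt_raw))
    t(m)
  }
  ad <- try(vcfR::extract.gt(v, element = "AD"), silent = TRUE)
  ad_ref <- ad_alt <- NULL
  if (!inherits(ad, "try-error") && !all(is.na(ad))) {
    parts <- strsplit(as.character(ad), ",", fixed = TRUE)
    get_part <- function(k) {
      vapply(parts, function(p) {
        if (length(p) >= k) suppressWarnings(as.numeric(p[k])) else NA_real_
      }, numeric(1))
    }
    ad_ref <- t(matrix(get_part(1), nrow = nrow(gt_raw)))
    ad_alt <- t(matrix(get_part(2), nrow = nrow(gt_raw)))
  }

  if (is.character(cohorts)) {
    cohorts <- utils::read.table(cohorts, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  if (is.null(cohorts)) {
    cohorts <- data.frame(sample_id = sample_ids, cohort = "all",
                          stringsAsFactors = FALSE)
  }
  cohorts <- cohorts[match(sample_ids, cohorts$sample_id), , drop = FALSE]
  if (anyNA(cohorts$sample_id)) {
    stop("cohort table is missing VCF samples: ",
         paste(setdiff(sample_ids, cohorts$sample_id), collapse = ", "))
  }

  impact <- rep(NA_character_, nrow(fix))
  has_imp <- grepl("IMPACT=", fix$INFO %||% "")
  impact[has_imp] <- sub(".*IMPACT=([^;]+).*", "\\1", fix$INFO[has_imp])
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    is_biallelic = !grepl(",", fix$ALT) &
      fix$ALT %in% c("A", "C", "G", "T") & fix$REF %in% c("A", "C", "G", "T"),
    impact = impact, stringsAsFactors = FALSE
  )
  sites$is_transition <- sites$is_biallelic &
    is_transition_pair(sites$ref, sites$alt)

  gm <- genotype_matrix(t(gt), cohorts, dp = num_mat("DP"),
                        gq = num_mat("GQ"), ad_ref = ad_ref, ad_alt = ad_alt)
  list(genotypes = gm, sites = sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
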