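#' Polarize sites into ancestral and derived alleles
#'
#' An allele is deemed ancestral iff its combined-cohort frequency among
#' non-missing genotypes exceeds `freq_threshold` (0.95) AND it matches at
#' least one outgroup allele. The remaining allele is derived. Sites where
#' no allele qualifies are dropped and counted.
#'
#' @param gm a [genotype_matrix()] (all cohorts combined)
#' @param sites aligned site table
#' @param outgroups character matrix/data.frame (sites x outgroups) of
#'   outgroup alleles, or the names of columns of `sites` holding them
#' @param freq_threshold ancestral-frequency threshold (> 0.5 required)
#' @return list with `sites` (the polarized subset, plus columns
#'   `derived_is_alt` and `derived`), `index` (positions of the kept sites
#'   in the input table) and `dropped` (count)
#' @export
polarize <- function(gm, sites, outgroups = c("outgroup1", "outgroup2"),
                     freq_threshold = 0.95) {
  check_aligned(gm, sites)
  stopifnot(freq_threshold > 0.5)
  if (is.character(outgroups) && length(dim(outgroups)) != 2) {
    missing_cols <- setdiff(outgroups, names(sites))
    if (length(missing_cols) > 0) {
      stop("outgroup columns not found in site table: ",
           paste(missing_cols, collapse = ", "))
    }
    og <- as.matrix(sites[outgroups])
  } else {
    og <- as.matrix(outgroups)
    stopifnot(nrow(og) == nrow(sites))
  }
  f_alt <- allele_frequencies(gm)
  matches_ref <- rowSums(og == sites$ref, na.rm = TRUE) > 0
  matches_alt <- rowSums(og == sites$alt, na.rm = TRUE) > 0
  ref_anc <- !is.na(f_alt) & (1 - f_alt) > freq_threshold & matches_ref
  alt_anc <- !is.na(f_alt) & f_alt > freq_threshold & matches_alt
  stopifnot(!any(ref_anc & alt_anc))  # impossible with threshold > 0.5
  keep <- ref_anc | alt_anc
  out <- sites[keep, , drop = FALSE]
  out$derived_is_alt <- ref_anc[keep]
  out$derived <- ifelse(out$derived_is_alt, out$alt, out$ref)
  rownames(out) <- NULL
  list(sites = out, index = which(keep), dropped = sum(!keep))
}

# internal: per-sample derived-allele dosage matrix for polarized sites
derived_dosage <- function(gm, polarized) {
  gt <- gm$gt[, polarized$index, drop = FALSE]
  flip <- !polarized$sites$derived_is_alt
  if (any(flip)) gt[, flip] <- 2L - gt[, flip]
  gt
}

#' Potential and realized mutation load per sample
#'
#' Potential load counts the sites at which a sample carries at least one
#' derived allele; realized load is the proportion of those sites that are
#' homozygous derived (undefined, reported `NA`, when a sample carries no
#' derived variant in a category).
#'
#' @param gm a [genotype_matrix()]
#' @param polarized output of [polarize()]
#' @param categories impact categories to report (default: all present)
#' @return data.frame with `sample_id`, `cohort`, `category`, `potential`,
#'   `realized`
#' @export
load_per_sample <- function(gm, polarized, categories = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dos <- derived_dosage(gm, polarized)
  impact <- polarized$sites$impact
  if (is.null(categories)) {
    categories <- intersect(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                            unique(impact))
  }
  res <- list()
  for (cat_ in categories) {
    cols <- which(impact == cat_)
    d <- dos[, cols, drop = FALSE]
    potential <- rowSums(d >= 1L, na.rm = TRUE)
    homo <- rowSums(d == 2L, na.rm = TRUE)
    res[[cat_]] <- data.frame(
      sample_id = gm$samples$sample_id, cohort = gm$samples$cohort,
      category = cat_, potential = potential,
      realized = ifelse(potential > 0, homo / potential, NA_real_),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# internal: per-cohort derived frequencies and copy totals at polarized sites
cohort_derived_freqs <- function(gm, polarized, cohort) {
  dos <- derived_dosage(gm, polarized)
  rows <- gm$samples$cohort %in% cohort
  d <- colSums(dos[rows, , drop = FALSE], na.rm = TRUE)
  n <- 2L * colSums(!is.na(dos[rows, , drop = FALSE]))
  list(d = d, n = n, f = ifelse(n > 0, d / n, NA_real_))
}

#' The R_x/y statistic for derived-allele accumulation between cohorts
#'
#' For impact category C, `L_x,y(C) = sum_i f_i^x * (1 - f_i^y)` over
#' genome positions i in C, where `f_i` is the derived-allele frequency
#' among non-missing gene copies of a cohort, and
#' `R_x/y = L_x,y / L_y,x`. Values above one indicate a relative
#' accumulation of derived alleles in cohort x. Only positions with at
#' least one derived copy in the union of the two cohorts, and with
#' non-missing data in both, are included. The variance is estimated by
#' deleting one chromosome at a time (block jackknife); the 95% CI is the
#' jackknife mean +/- 1.96 SE.
#'
#' @param gm a [genotype_matrix()] containing both cohorts
#' @param polarized output of [polarize()]
#' @param cohort_x,cohort_y cohort labels
#' @param category impact category (`NULL` = all sites)
#' @return object of class `rxy_result`: list with `estimate`, `l_xy`,
#'   `l_yx`, `jackknife_mean`, `se`, `ci` and `n_blocks`
#' @export
rxy <- function(gm, polarized, cohort_x, cohort_y, category = NULL) {
  fx <- cohort_derived_freqs(gm, polarized, cohort_x)
  fy <- cohort_derived_freqs(gm, polarized, cohort_y)
  keep <- fx$n > 0 & fy$n > 0 & (fx$d + fy$d) > 0
  if (!is.null(category)) keep <- keep & polarized$sites$impact %in% category
  if (!any(keep)) stop("no qualifying sites for R_x/y in this category")
  lsum <- function(i) c(l_xy = sum(fx$f[i] * (1 - fy$f[i])),
                        l_yx = sum(fy$f[i] * (1 - fx$f[i])))
  full <- lsum(which(keep))
  if (full["l_yx"] == 0) stop("L_y,x is zero: R_x/y undefined")
  est <- unname(full["l_xy"] / full["l_yx"])

  chroms <- unique(polarized$sites$chrom[keep])
  loo <- vapply(chroms, function(ch) {
    i <- which(keep & polarized$sites$chrom != ch)
    l <- lsum(i)
    if (l["l_yx"] == 0) return(NA_real_)
    unname(l["l_xy"] / l["l_yx"])
  }, numeric(1))
  loo <- loo[!is.na(loo)]
  m <- length(loo)
  jk_mean <- mean(loo)
  se <- if (m > 1) sqrt((m - 1) / m * sum((loo - jk_mean)^2)) else NA_real_
  structure(list(category = if (is.null(category)) "ALL" else category,
                 estimate = est, l_xy = unname(full["l_xy"]),
                 l_yx = unname(full["l_yx"]),
                 jackknife_mean = jk_mean, se = se,
                 ci = jk_mean + c(-1.96, 1.96) * se,
                 n_blocks = m),
            class = "rxy_result")
}

#' @exportS3Method print rxy_result
print.rxy_result <- function(x, ...) {
  cat(sprintf("R_x/y (%s) = %.4f  [95%% CI %.4f, %.4f; %d jackknife blocks]\n",
              x$category, x$estimate, x$ci[1], x$ci[2], x$n_blocks))
  invisible(x)
}

#' Two-sided Mann-Whitney U comparison of two cohorts
#'
#' Exact null distribution for small samples (total n <= 20, no ties);
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors of per-sample values
#' @return list with `u`, `p_value` and `method`
#' @export
compare_cohorts <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
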