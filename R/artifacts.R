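#' Attach read-depth metadata to true genotypes
#'
#' Emulates low-coverage sequencing of a cohort: per-genotype depths are
#' Poisson(`target_depth`), allelic depths of true heterozygotes are
#' Binomial(depth, 0.5), homozygotes have all reads supporting their allele,
#' and a simple depth-scaled genotype quality (capped at 99) is attached.
#' Genotypes that receive zero reads are set missing.
#'
#' @param gm a [genotype_matrix()]
#' @param target_depth mean sequencing depth
#' @param seed integer seed
#' @return a [genotype_matrix()] with `dp`, `gq`, `ad_ref`, `ad_alt` filled
#'   and `mean_depth` updated in the sample table
#' @export
attach_read_depths <- function(gm, target_depth = 6, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"), target_depth > 0)
  with_seed(seed, {
    gt <- gm$gt
    n <- length(gt)
    dp <- matrix(stats::rpois(n, target_depth), nrow = nrow(gt))
    alt <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt))
    het <- !is.na(gt) & gt == 1L
    alt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
    homalt <- !is.na(gt) & gt == 2L
    alt[homalt] <- dp[homalt]
    ref <- dp - alt
    gt[dp == 0L] <- NA_integer_
    dp[is.na(gt)] <- 0L
    alt[is.na(gt)] <- 0L
    ref[is.na(gt)] <- 0L
    gq <- pmin(matrix(as.integer(10 + 12 * dp), nrow = nrow(gt)), 99L)
    gq[is.na(gt)] <- 0L
    samples <- gm$samples
    samples$mean_depth <- rowMeans(dp)
    genotype_matrix(gt, samples, dp = dp, gq = gq,
                    ad_ref = ref, ad_alt = alt)
  })
}

#' Inject deamination-style artifacts and depth fields into a cohort
#'
#' Prepares a simulated cohort for use as a "historical" (museum-specimen)
#' dataset: draws per-genotype read depths around `target_depth` via
#' [attach_read_depths()], then injects spurious C>T / G>A transition sites
#' carrying 1-2 derived copies across the cohort, mimicking post-mortem
#' cytosine deamination. Injected genotypes are heterozygous calls supported
#' by only 1-2 alternate reads. The returned site table carries an
#' `injected` logical column as ground truth for filter validation; the
#' column is internal and is not written to VCF output.
#'
#' @param gm a [genotype_matrix()] of true genotypes
#' @param sites the matching site table
#' @param deamination_rate expected number of injected artifact sites per
#'   real site, in `[0, 1)`
#' @param target_depth mean sequencing depth
#' @param seed integer seed
#' @return list with elements `genotypes` and `sites`
#' @export
add_historical_artifacts <- function(gm, sites, deamination_rate = 0.1,
                                     target_depth = 6, seed = 1) {
  check_aligned(gm, sites)
  if (deamination_rate < 0 || deamination_rate >= 1) {
    stop("deamination_rate must be in [0, 1)")
  }
  gm <- attach_read_depths(gm, target_depth = target_depth,
                           seed = derive_seed(seed, salt = 2))
  sites$injected <- rep(FALSE, nrow(sites))
  if (deamination_rate == 0 || nrow(sites) == 0) {
    return(list(genotypes = gm, sites = sites))
  }
  with_seed(derive_seed(seed, salt = 3), {
    n_inject <- stats::rpois(1, deamination_rate * nrow(sites))
    if (n_inject == 0) return(list(genotypes = gm, sites = sites))
    occupied <- paste(sites$chrom, sites$pos)
    chroms <- unique(sites$chrom)
    span <- max(sites$pos)
    new_sites <- data.frame(
      chrom = sample(chroms, n_inject, replace = TRUE),
      pos = sample.int(span, n_inject, replace = TRUE)
    )
    keep <- !paste(new_sites$chrom, new_sites$pos) %in% occupied &
      !duplicated(paste(new_sites$chrom, new_sites$pos))
    new_sites <- new_sites[keep, , drop = FALSE]
    n_inject <- nrow(new_sites)
    if (n_inject == 0) return(list(genotypes = gm, sites = sites))

    ct <- stats::runif(n_inject) < 0.5
    add <- data.frame(
      chrom = new_sites$chrom, pos = new_sites$pos,
      ref = ifelse(ct, "C", "G"), alt = ifelse(ct, "T", "A"),
      is_transition = TRUE, injected = TRUE, stringsAsFactors = FALSE
    )
    # carry any extra columns of the input table as neutral placeholders
    for (col in setdiff(names(sites), names(add))) {
      add[[col]] <- if (col == "impact") "MODIFIER"
        else if (col == "s" || col == "h") 0
        else if (col == "ancestral") add$ref
        else sites[[col]][NA_integer_]
    }

    ns <- nrow(gm$samples)
    gt_add <- matrix(0L, nrow = ns, ncol = n_inject)
    dp_add <- matrix(stats::rpois(ns * n_inject, target_depth), nrow = ns)
    ref_add <- dp_add
    alt_add <- matrix(0L, nrow = ns, ncol = n_inject)
    for (j in seq_len(n_inject)) {
      carriers <- sample.int(ns, sample(1:2, 1))
      gt_add[carriers, j] <- 1L
      reads <- sample(1:2, length(carriers), replace = TRUE)
      alt_add[carriers, j] <- reads
      dp_add[carriers, j] <- pmax(dp_add[carriers, j], reads + 1L)
      ref_add[carriers, j] <- dp_add[carriers, j] - reads
    }
    gq_add <- pmin(matrix(as.integer(10 + 12 * dp_add), nrow = ns), 99L)

    all_sites <- rbind(sites, add[names(sites)])
    ord <- order(match(all_sites$chrom, chroms_in_order(all_sites$chrom)),
                 all_sites$pos)
    comb <- genotype_matrix(
      cbind(gm$gt, gt_add)[, ord, drop = FALSE], gm$samples,
      dp = cbind(gm$dp, dp_add)[, ord, drop = FALSE],
      gq = cbind(gm$gq, gq_add)[, ord, drop = FALSE],
      ad_ref = cbind(gm$ad_ref, ref_add)[, ord, drop = FALSE],
      ad_alt = cbind(gm$ad_alt, alt_add)[, ord, drop = FALSE]
    )
    all_sites <- all_sites[ord, , drop = FALSE]
    rownames(all_sites) <- NULL
    list(genotypes = comb, sites = all_sites)
  })
}

# internal: natural ordering of chromosome names (chr1, chr2, ..., chr10)
chroms_in_order <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.integer(sub("^chr", "", u)))
  u[order(num, u)]
}

#' Generate a synthetic catch series from a census-size trajectory
#'
#' Produces the whaling-record analogue for the demography at hand: catches
#' in each step equal the census decline `max(0, -delta_Nc)`, perturbed by
#' multiplicative reporting noise. Cumulative catches are therefore
#' non-decreasing, and with zero noise the cumulative series reconstructs
#' the census decline exactly.
#'
#' @param nc per-step census sizes (non-negative), most ancient first
#' @param years calendar year of each `nc` entry (same length); defaults to
#'   consecutive years
#' @param reporting_noise standard deviation of the multiplicative noise
#' @param seed integer seed
#' @return data.frame with `year` and `catches` (one row per interval)
#' @export
generate_catch_series <- function(nc, years = NULL, reporting_noise = 0,
                                  seed = 1) {
  if (any(nc < 0)) stop("census sizes must be non-negative")
  if (is.null(years)) years <- seq_along(nc)
  stopifnot(length(years) == length(nc), reporting_noise >= 0)
  if (length(nc) < 2) return(data.frame(year = integer(0), catches = numeric(0)))
  drop_ <- -diff(nc)
  noise <- if (reporting_noise > 0) {
    with_seed(derive_seed(seed, salt = 4),
              stats::rnorm(length(drop_), 0, reporting_noise))
  } else {
    rep(0, length(drop_))
  }
  data.frame(year = years[-1], catches = pmax(0, drop_ * (1 + noise)))
}
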