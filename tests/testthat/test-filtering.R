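test_that("site filters drop exactly the planted failures", {
  set.seed(4)
  n <- 100
  gt <- matrix(sample(0:2, 8 * n, replace = TRUE), nrow = 8)
  sites <- manual_sites(n)
  sites$qual <- 50
  sites$is_biallelic <- TRUE
  bad_tri <- 1:5          # planted multiallelic records
  bad_qual <- 11:13       # planted low-quality records
  bad_miss <- 21:22       # planted high-missingness records
  sites$is_biallelic[bad_tri] <- FALSE
  sites$qual[bad_qual] <- 35
  gt[1:6, bad_miss] <- NA
  gm <- manual_gm(asplit(gt, 1))
  res <- filter_sites(gm, sites, filter_config(max_missing_fraction = 0.5))
  expect_equal(nrow(res$sites), 90)
  expect_equal(ncol(res$genotypes$gt), 90)
  # brute-force re-check of each rule, site by site
  oracle_keep <- vapply(seq_len(n), function(i) {
    sites$is_biallelic[i] && sites$qual[i] > 40 &&
      mean(is.na(gt[, i])) <= 0.5
  }, logical(1))
  expect_equal(paste(res$sites$chrom, res$sites$pos),
               paste(sites$chrom, sites$pos)[oracle_keep])
  # order preserved and idempotent
  expect_true(!is.unsorted(res$sites$pos))
  res2 <- filter_sites(res$genotypes, res$sites,
                       filter_config(max_missing_fraction = 0.5))
  expect_equal(res2$sites, res$sites)
})

test_that("the contemporary DP/GQ filter matches its thresholds exactly", {
  gt <- rbind(c(1L, 1L, 1L, 1L))
  dp <- rbind(c(6, 5, 6, 10))
  gq <- rbind(c(16, 99, 15, 99))
  gm <- manual_gm(list(gt[1, ]), cohort = "contemporary", dp = dp, gq = gq)
  res <- filter_genotypes_contemporary(gm, filter_config())
  expect_equal(unname(res$genotypes$gt[1, ]), c(1L, NA, NA, 1L))
  expect_equal(res$report$genotypes_missing, 2L)
  # idempotent
  res2 <- filter_genotypes_contemporary(res$genotypes, filter_config())
  expect_identical(res2$genotypes$gt, res$genotypes$gt)
})

test_that("allele-balance recoding follows the read majority", {
  # het genotypes at four sites: balances 0.25 (-> hom-ref), 0.50 (kept),
  # 0.90 (-> hom-alt), tie 0/0 handled by the depth rule
  gt <- list(c(1L, 1L, 1L, 2L))
  ad_ref <- rbind(c(6, 5, 1, 0))
  ad_alt <- rbind(c(2, 5, 9, 2))
  dp <- ad_ref + ad_alt
  gm <- manual_gm(gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
  sites <- manual_sites(4, ref = "G", alt = "T")   # transversions: no site loss
  res <- harmonize_temporal(gm, sites, filter_config())
  expect_equal(unname(res$genotypes$gt[1, ]),
               c(0L,   # balance 0.25, more ref reads -> hom-ref
                 1L,   # balance 0.50, inside [0.35, 0.75]
                 2L,   # balance 0.90, more alt reads -> hom-alt
                 NA))  # hom-alt with only 2 supporting reads -> missing
  expect_equal(res$report$genotypes_recoded[1], 2L)
})

test_that("variant-depth rule hits het and hom-alt but never hom-ref", {
  gt <- list(c(1L, 2L, 0L))
  ad_ref <- rbind(c(3, 0, 8))
  ad_alt <- rbind(c(2, 2, 0))
  gm <- manual_gm(gt, dp = ad_ref + ad_alt, ad_ref = ad_ref,
                  ad_alt = ad_alt)
  sites <- manual_sites(3, ref = "G", alt = "T")
  res <- harmonize_temporal(gm, sites, filter_config())
  expect_equal(unname(res$genotypes$gt[1, ]), c(NA, NA, 0L))
})

test_that("the deamination guard removes low-count transitions only", {
  # two sites with cohort alt count 2: one C/T transition, one G/T
  # transversion; plus a C/T transition with count 3 that must stay
  gt <- list(c(1L, 1L, 1L), c(1L, 0L, 1L), c(0L, 0L, 1L))
  ad_ref <- matrix(4, 3, 3)
  ad_alt <- matrix(4, 3, 3)
  gm <- manual_gm(gt, dp = ad_ref + ad_alt, ad_ref = ad_ref,
                  ad_alt = ad_alt)
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      ref = c("C", "G", "C"), alt = c("T", "T", "T"),
                      is_transition = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  res <- harmonize_temporal(gm, sites, filter_config())
  expect_equal(res$sites$pos, c(200L, 300L))
  expect_equal(res$report$sites_removed[res$report$rule == "transition_count"],
               1L)
})

test_that("harmonization never invents alleles and reduces heterozygosity", {
  fx <- frequency_cohort(2000, seed = 29)
  gm <- attach_read_depths(fx$genotypes, 6, seed = 31)
  res <- harmonize_temporal(gm, fx$sites, filter_config())
  expect_true(all(res$genotypes$gt %in% c(0L, 1L, 2L, NA)))
  before <- rowSums(gm$gt == 1L, na.rm = TRUE)
  after <- rowSums(res$genotypes$gt == 1L, na.rm = TRUE)
  expect_true(all(after <= before))
  # idempotence on its own output
  res2 <- harmonize_temporal(res$genotypes, res$sites, filter_config())
  expect_identical(res2$genotypes$gt, res$genotypes$gt)
  expect_equal(res2$sites, res$sites)
})

test_that("harmonization requires allelic depths and names the sample", {
  gm <- manual_gm(list(c(0L, 1L)))
  expect_error(harmonize_temporal(gm, manual_sites(2), filter_config()),
               "s01")
})

test_that("transversion subsetting is exact", {
  sites <- data.frame(chrom = "chr1", pos = 1:4,
                      ref = c("A", "A", "C", "G"),
                      alt = c("G", "T", "T", "C"), stringsAsFactors = FALSE)
  sites$is_transition <- is_transition_pair(sites$ref, sites$alt)
  out <- transversions_only(sites)
  expect_equal(out$pos, c(2L, 4L))
  expect_equal(attr(out, "removed"), 2L)
  all_tv <- transversions_only(out)
  expect_equal(all_tv$pos, out$pos)
  # on a simulated table the retained count equals the planted transversions
  r <- cached_replicate()
  out2 <- transversions_only(r$sites)
  expect_equal(nrow(out2), sum(!r$sites$is_transition))
})
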