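test_that("polarization requires high frequency plus outgroup support", {
  # 10 diploids; site 1: alt rare (ref freq 0.95+), outgroup carries ref;
  # site 2: same frequencies but outgroups carry only the alt allele;
  # site 3: intermediate frequency - never polarizable
  gt <- rbind(c(1L, 1L, 1L), matrix(0L, 11, 3))
  gt[, 3] <- rep(1L, 12)
  gm <- manual_gm(asplit(gt, 1))
  sites <- manual_sites(3, ref = "A", alt = "C")
  sites$outgroup1 <- c("A", "C", "A")
  sites$outgroup2 <- c("A", "C", "A")
  pol <- polarize(gm, sites)
  expect_equal(pol$index, 1L)
  expect_true(pol$sites$derived_is_alt[1])
  expect_equal(pol$dropped, 2L)
  # alt nearly fixed and matched by an outgroup: reference is derived
  gt2 <- matrix(2L, 12, 1)
  gt2[1, 1] <- 1L
  gm2 <- manual_gm(asplit(gt2, 1))
  s2 <- manual_sites(1, ref = "A", alt = "C")
  s2$outgroup1 <- "C"
  s2$outgroup2 <- NA_character_
  pol2 <- polarize(gm2, s2)
  expect_false(pol2$sites$derived_is_alt[1])
  expect_equal(pol2$sites$derived[1], "A")
})

test_that("polarization error rate on simulated truth is below 5%", {
  r <- cached_replicate()
  sites <- r$sites
  set.seed(43)
  mism <- stats::runif(nrow(sites)) < 0.01
  sites$outgroup1 <- ifelse(mism, sites$alt, sites$ancestral)
  sites$outgroup2 <- sites$ancestral
  both <- genotype_matrix(
    rbind(r$cohorts$pre_bottleneck$gt, r$cohorts$post_recovery$gt),
    rbind(r$cohorts$pre_bottleneck$samples, r$cohorts$post_recovery$samples))
  pol <- polarize(both, sites)
  expect_gt(nrow(pol$sites), 10)
  # truth: the simulator's ancestral allele is the reference
  err <- mean(!pol$sites$derived_is_alt)
  expect_lt(err, 0.05)
})

test_that("potential and realized load follow their definitions", {
  # one sample, three sites in one category: het, hom-derived, hom-ancestral
  gm <- manual_gm(list(c(1L, 2L, 0L)))
  sites <- manual_sites(3)
  sites$impact <- "MODERATE"
  sites$outgroup1 <- sites$ref
  sites$outgroup2 <- sites$ref
  pol <- list(sites = cbind(sites, derived_is_alt = TRUE, derived = sites$alt),
              index = 1:3, dropped = 0L)
  ls <- load_per_sample(gm, pol)
  expect_equal(ls$potential, 2)
  expect_equal(ls$realized, 0.5)
  # all derived homozygous
  gm2 <- manual_gm(list(c(2L, 2L, 2L)))
  ls2 <- load_per_sample(gm2, pol)
  expect_equal(ls2$realized, 1)
  # no derived variants: realized undefined
  gm3 <- manual_gm(list(c(0L, 0L, 0L)))
  ls3 <- load_per_sample(gm3, pol)
  expect_equal(ls3$potential, 0)
  expect_true(is.na(ls3$realized))
  # counts are invariant to sample order
  gm4 <- manual_gm(list(c(1L, 2L, 0L), c(0L, 1L, 1L)))
  gm5 <- manual_gm(list(c(0L, 1L, 1L), c(1L, 2L, 0L)))
  expect_equal(sort(load_per_sample(gm4, pol)$potential),
               sort(load_per_sample(gm5, pol)$potential))
})

test_that("R_x/y matches the hand-computed single-site example", {
  # one site: f_x = 0.5 (1 het of 1 diploid), f_y = 0.1 (1 het of 5)
  gm <- two_cohort_gm(list(1L), list(1L, 0L, 0L, 0L, 0L))
  pol <- fake_polarized(1)
  r <- rxy(gm, pol, "x", "y")
  expect_equal(r$l_xy, 0.45)
  expect_equal(r$l_yx, 0.05)
  expect_equal(r$estimate, 9)
})

test_that("R_x/y is 1 for identical cohorts and inverts exactly", {
  set.seed(3)
  rows <- lapply(1:6, function(i) stats::rbinom(40, 2, 0.3))
  gm <- two_cohort_gm(rows[1:3], rows[1:3])
  pol <- fake_polarized(40, chrom = rep(c("chr1", "chr2"), each = 20))
  expect_equal(rxy(gm, pol, "x", "y")$estimate, 1)
  gm2 <- two_cohort_gm(rows[1:3], rows[4:6])
  fwd <- rxy(gm2, pol, "x", "y")$estimate
  rev_ <- rxy(gm2, pol, "y", "x")$estimate
  expect_equal(fwd * rev_, 1, tolerance = 1e-12)
})

test_that("chromosomes without derived sites leave jackknife replicates unchanged", {
  set.seed(5)
  rows_x <- lapply(1:4, function(i) c(stats::rbinom(20, 2, 0.4), rep(0L, 10)))
  rows_y <- lapply(1:4, function(i) c(stats::rbinom(20, 2, 0.2), rep(0L, 10)))
  gm <- two_cohort_gm(rows_x, rows_y)
  # sites 21:30 on chr3 carry no derived allele in either cohort
  pol <- fake_polarized(30, chrom = rep(c("chr1", "chr2", "chr3"), each = 10))
  r <- rxy(gm, pol, "x", "y")
  expect_equal(r$n_blocks, 2)       # chr3 contributes no block
  # CI contains the jackknife mean
  expect_true(r$ci[1] <= r$jackknife_mean && r$jackknife_mean <= r$ci[2])
  # removing the empty chromosome by hand reproduces the full estimate
  keep <- pol$sites$chrom != "chr3"
  pol2 <- fake_polarized(20, chrom = rep(c("chr1", "chr2"), each = 10))
  gm2 <- two_cohort_gm(lapply(rows_x, function(z) z[keep]),
                       lapply(rows_y, function(z) z[keep]))
  expect_equal(rxy(gm2, pol2, "x", "y")$estimate, r$estimate)
})

test_that("R_x/y of neutral same-generation cohorts is near 1 with covering CIs", {
  demo <- demography_model(data.frame(duration = 600L, n_start = 100,
                                      n_end = 100, shape = "constant"))
  genome <- genome_model(n_genes = 150, gene_length = 1000, mu = 3e-6,
                         n_chromosomes = 15)
  cover <- logical(0)
  ests <- numeric(0)
  for (rep_i in 1:20) {
    s <- simulate_replicate(demo, dfe_model(p_neutral = 1), genome,
                            sample_size = 24, timepoints = "post_recovery",
                            seed = 61, replicate = rep_i)
    gm <- s$cohorts$post_recovery
    gm$samples$cohort <- rep(c("x", "y"), each = 12)
    sites <- s$sites
    sites$outgroup1 <- sites$ancestral
    sites$outgroup2 <- sites$ancestral
    pol <- polarize(gm, sites)
    if (nrow(pol$sites) < 10) next
    r <- rxy(gm, pol, "x", "y")
    ests <- c(ests, r$estimate)
    cover <- c(cover, r$ci[1] <= 1 && 1 <= r$ci[2])
  }
  expect_gt(length(ests), 14)
  expect_equal(mean(ests), 1, tolerance = 0.15)
  expect_gte(mean(cover), 0.9)
})

test_that("the R_x/y error cases are explicit", {
  gm <- two_cohort_gm(list(c(1L, 0L)), list(c(0L, 0L)))
  pol <- fake_polarized(2)
  expect_error(rxy(gm, pol, "x", "y"), "L_y,x")
  gm2 <- two_cohort_gm(list(c(0L, 0L)), list(c(0L, 0L)))
  expect_error(rxy(gm2, pol, "x", "y"), "no qualifying sites")
})

test_that("Mann-Whitney comparisons match exact enumeration", {
  res <- compare_cohorts(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(mw_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(9)
  for (i in 1:8) {
    x <- round(stats::rnorm(sample(3:6, 1)), 3)
    y <- round(stats::rnorm(sample(3:6, 1), mean = 0.5), 3)
    expect_equal(compare_cohorts(x, y)$p_value, mw_exact_p(x, y),
                 tolerance = 0.01)
  }
  ident <- compare_cohorts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-6)
})

test_that("realized load does not fall after the bottleneck in most replicates", {
  demo <- demography_model(data.frame(
    duration = c(400L, 5L, 10L), n_start = c(120, 120, 30),
    n_end = c(120, 30, 80),
    shape = c("constant", "exponential", "exponential")))
  genome <- genome_model(n_genes = 200, gene_length = 1000, mu = 5e-6,
                         n_chromosomes = 5)
  higher <- logical(0)
  for (rep_i in 1:20) {
    s <- simulate_replicate(demo, dfe_model(), genome, sample_size = 12,
                            seed = 71, replicate = rep_i)
    sites <- s$sites
    sites$outgroup1 <- sites$ancestral
    sites$outgroup2 <- sites$ancestral
    both <- genotype_matrix(
      rbind(s$cohorts$pre_bottleneck$gt, s$cohorts$post_recovery$gt),
      rbind(s$cohorts$pre_bottleneck$samples,
            s$cohorts$post_recovery$samples))
    pol <- polarize(both, sites)
    ls <- load_per_sample(both, pol, categories = "MODERATE")
    agg <- tapply(ls$realized, ls$cohort, mean, na.rm = TRUE)
    pre <- agg[["pre_bottleneck"]]
    post <- agg[["post_recovery"]]
    if (is.finite(pre) && is.finite(post)) {
      higher <- c(higher, post >= pre)
    }
  }
  expect_gte(length(higher), 15)
  expect_gte(mean(higher), 0.5)
})
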