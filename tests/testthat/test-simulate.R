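test_that("without mutation the simulator emits no variation", {
  g0 <- tiny_genome(mu = 0)
  for (seed in c(1, 99)) {
    r <- simulate_replicate(tiny_demography(), dfe_model(), g0,
                            sample_size = 5, seed = seed)
    expect_equal(nrow(r$sites), 0)
    expect_equal(unname(r$summaries$het), c(0, 0))
  }
})

test_that("replicates are reproducible and streams are independent", {
  a <- simulate_replicate(tiny_demography(), dfe_model(), tiny_genome(),
                          sample_size = 6, seed = 7, replicate = 1)
  b <- simulate_replicate(tiny_demography(), dfe_model(), tiny_genome(),
                          sample_size = 6, seed = 7, replicate = 1)
  expect_identical(a$cohorts$pre_bottleneck$gt, b$cohorts$pre_bottleneck$gt)
  expect_identical(a$sites, b$sites)
  c_ <- simulate_replicate(tiny_demography(), dfe_model(), tiny_genome(),
                           sample_size = 6, seed = 7, replicate = 2)
  expect_false(identical(a$cohorts$pre_bottleneck$gt,
                         c_$cohorts$pre_bottleneck$gt))
})

test_that("invalid sampling requests are rejected", {
  expect_error(simulate_replicate(tiny_demography(), dfe_model(),
                                  tiny_genome(), sample_size = 90, seed = 1),
               "sample_size")
  expect_error(simulate_replicate(tiny_demography(), dfe_model(),
                                  tiny_genome(), timepoints = character(0),
                                  seed = 1),
               "timepoint")
})

test_that("neutral equilibrium heterozygosity matches theta/(1+theta)", {
  # constant N = 100, theta = 4*N*mu = 0.004 per site
  demo <- demography_model(data.frame(duration = 1500L, n_start = 100,
                                      n_end = 100, shape = "constant"))
  genome <- genome_model(n_genes = 200, gene_length = 1000, mu = 1e-5,
                         n_chromosomes = 4)
  neutral <- dfe_model(p_neutral = 1)
  theta <- 4 * 100 * 1e-5
  expected <- theta / (1 + theta)
  hets <- vapply(1:20, function(r) {
    s <- simulate_replicate(demo, neutral, genome, sample_size = 12,
                            timepoints = "post_recovery", seed = 11,
                            replicate = r)
    unname(s$summaries$het)
  }, numeric(1))
  se <- stats::sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se)
})

test_that("neutral bottleneck loss matches the drift-decay closed form", {
  epochs <- data.frame(duration = c(1200L, 4L, 6L),
                       n_start = c(150, 150, 20),
                       n_end = c(150, 20, 100),
                       shape = c("constant", "exponential", "exponential"),
                       mu_factor = c(1, 0, 0))  # no new mutations post-burn-in
  demo <- demography_model(epochs)
  genome <- genome_model(n_genes = 300, gene_length = 1000, mu = 2e-6,
                         n_chromosomes = 4)
  path <- population_path(demo)
  n_post <- path$n[(path$epoch_end[1] + 1):path$epoch_end[3]]
  expected_loss <- 1 - prod(1 - 1 / (2 * n_post))
  losses <- vapply(1:30, function(r) {
    s <- simulate_replicate(demo, dfe_model(p_neutral = 1), genome,
                            sample_size = 12, seed = 23, replicate = r)
    unname(s$summaries$het_loss_pct) / 100
  }, numeric(1))
  se <- stats::sd(losses) / sqrt(length(losses))
  expect_lt(abs(mean(losses) - expected_loss), 3 * se)
})

test_that("mean fitness is monotone in the strength of selection", {
  demo <- demography_model(data.frame(duration = 400L, n_start = 100,
                                      n_end = 100, shape = "constant"))
  genome <- genome_model(n_genes = 100, gene_length = 1000, mu = 1e-5,
                         n_chromosomes = 2)
  fits <- vapply(c(0, -0.005, -0.02), function(ms) {
    dfe <- dfe_model(p_neutral = 0.3, mean_s = ms)
    r <- simulate_replicate(demo, dfe, genome, sample_size = 5,
                            timepoints = "post_recovery", seed = 31)
    unname(r$mean_fitness)
  }, numeric(1))
  expect_equal(fits[1], 1)                 # neutral: no load
  expect_true(all(diff(fits) < 0))         # stronger selection, lower fitness
})

test_that("site tables are valid and internally consistent", {
  r <- cached_replicate()
  s <- r$sites
  expect_true(all(s$pos >= 1))
  expect_true(all(s$ref != s$alt))
  expect_true(all(s$ref %in% c("A", "C", "G", "T")))
  expect_true(all(s$alt %in% c("A", "C", "G", "T")))
  expect_equal(s$is_transition, is_transition_pair(s$ref, s$alt))
  expect_false(any(duplicated(paste(s$chrom, s$pos))))
  # genotypes are diploid dosages over the shared table
  for (gm in r$cohorts) {
    expect_true(all(gm$gt %in% 0:2))
    expect_equal(ncol(gm$gt), nrow(s))
  }
})

test_that("stored summaries equal summaries recomputed from genotypes", {
  r <- cached_replicate()
  re <- replicate_summaries(r)
  expect_equal(r$summaries$het, re$het)
  expect_equal(r$summaries$het_loss_pct, re$het_loss_pct)
  expect_equal(r$summaries$derived_counts, re$derived_counts)
  # and by hand, per definition
  L <- genome_length(r$genome)
  manual <- mean(rowSums(r$cohorts$pre_bottleneck$gt == 1L)) / L
  expect_equal(unname(re$het["pre_bottleneck"]), manual)
})

test_that("impact categories follow the |s| thresholds and DFE mass", {
  expect_equal(assign_impact_categories(-0.5), "HIGH")
  expect_equal(assign_impact_categories(-5e-3), "MODERATE")
  expect_equal(assign_impact_categories(-5e-5), "LOW")
  set.seed(1)
  neutral_labels <- assign_impact_categories(rep(0, 4000))
  expect_true(all(neutral_labels %in% c("MODIFIER", "LOW")))
  frac <- mean(neutral_labels == "MODIFIER")
  expect_lt(abs(frac - 0.5), 0.05)
  expect_error(assign_impact_categories(-1, t1 = 0.1, t2 = 0.01))

  # category counts over a DFE sample match brute-force binning
  set.seed(2)
  dfe <- dfe_model()
  s <- ifelse(stats::runif(10000) < dfe$p_neutral, 0,
              -stats::rgamma(10000, shape = dfe$gamma_shape,
                             scale = abs(dfe$mean_s) / dfe$gamma_shape))
  labels <- assign_impact_categories(s)
  oracle <- table(cut(abs(s), c(-Inf, 0, 1e-4, 1e-2, Inf),
                      labels = c("neutral", "LOW", "MODERATE", "HIGH")))
  expect_equal(sum(labels %in% c("MODIFIER", "LOW")),
               unname(oracle["neutral"] + oracle["LOW"]))
  expect_equal(sum(labels == "MODERATE"), unname(oracle["MODERATE"]))
  expect_equal(sum(labels == "HIGH"), unname(oracle["HIGH"]))
})
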