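test_that("heterozygosity is het count over callable sites", {
  gm <- manual_gm(list(rep(0L, 10), c(rep(1L, 3), rep(0L, 7))))
  het <- genome_wide_heterozygosity(gm, callable_sites = 1000)
  expect_equal(het$het, c(0, 3 / 1000))
  # per-sample non-missing + monomorphic denominator
  gm2 <- manual_gm(list(c(1L, 1L, NA, 0L)))
  het2 <- genome_wide_heterozygosity(gm2, monomorphic_callable = 97)
  expect_equal(het2$callable, 100)
  expect_equal(het2$het, 2 / 100)
  expect_error(genome_wide_heterozygosity(gm, callable_sites = 0),
               "positive")
  expect_error(genome_wide_heterozygosity(gm2, monomorphic_callable = -2),
               "fewer")
})

test_that("on neutral simulated cohorts mean heterozygosity matches theta/(1+theta)", {
  demo <- demography_model(data.frame(duration = 1200L, n_start = 100,
                                      n_end = 100, shape = "constant"))
  genome <- genome_model(n_genes = 250, gene_length = 1000, mu = 1e-5,
                         n_chromosomes = 4)
  theta <- 4 * 100 * 1e-5
  hets <- vapply(1:12, function(r) {
    s <- simulate_replicate(demo, dfe_model(p_neutral = 1), genome,
                            sample_size = 12, timepoints = "post_recovery",
                            seed = 5, replicate = r)
    mean(genome_wide_heterozygosity(
      s$cohorts$post_recovery, callable_sites = genome_length(genome))$het)
  }, numeric(1))
  se <- stats::sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - theta / (1 + theta)), 3 * se)
})

test_that("Viterbi decoding equals exhaustive path enumeration", {
  config <- roh_config(az_entry = 1e-5, az_exit = 1e-5, error_rate = 0.01)
  set.seed(11)
  for (case in 1:15) {
    n <- sample(4:10, 1)
    obs <- stats::rbinom(n, 1, 0.4)
    pos <- cumsum(sample(500:20000, n))
    p <- stats::runif(n, 0.05, 0.95)
    vit <- roh_viterbi(obs, pos, p, config)
    oracle <- enumerate_best_path(obs, pos, p, config)
    # compare path log-probabilities (ties may admit multiple optima)
    expect_equal(roh_path_logprob(vit, obs, pos, p, config), oracle$logp,
                 tolerance = 1e-9)
  }
})

test_that("a fully heterozygous sample yields no ROH segments", {
  gm <- manual_gm(list(rep(1L, 200)))
  sites <- manual_sites(200, spacing = 10000L)
  segs <- call_roh(gm, sites, allele_freqs = rep(0.5, 200),
                   config = roh_config())
  expect_equal(nrow(segs), 0)
})

test_that("a planted 2-Mbp homozygous tract is recovered as one segment", {
  set.seed(13)
  n <- 400
  spacing <- 10000L
  sites <- manual_sites(n, spacing = spacing)        # 4 Mbp of chr1
  tract <- 101:300                                   # 2 Mbp in the middle
  gt <- stats::rbinom(n, 1, 0.5)                     # het density 2p(1-p), p=0.5
  gt[tract] <- 0L
  gm <- manual_gm(list(as.integer(gt)))
  segs <- call_roh(gm, sites, allele_freqs = rep(0.5, n),
                   config = roh_config())
  expect_equal(nrow(segs), 1)
  # rule-based brute-force oracle: the longest run of consecutive
  # homozygous genotypes contains the tract
  runs <- rle(gt == 0L)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values)[which.max(runs$lengths[runs$values])]
  expect_lte(abs(segs$start - sites$pos[starts[k]]), spacing)
  expect_lte(abs(segs$end - sites$pos[ends[k]]), spacing)
  expect_gte(segs$n_sites, 200)
})

test_that("runs below the 50-homozygote minimum are rejected", {
  set.seed(17)
  n <- 200
  gt <- stats::rbinom(n, 1, 0.5)
  gt[81:120] <- 0L                                   # only 40 hom sites
  gt[c(80, 121)] <- 1L
  gm <- manual_gm(list(as.integer(gt)))
  sites <- manual_sites(n, spacing = 10000L)
  segs <- call_roh(gm, sites, allele_freqs = rep(0.5, n),
                   config = roh_config())
  expect_true(nrow(segs) == 0 || all(segs$n_sites >= 50))
  expect_false(any(segs$start <= sites$pos[81] & segs$end >= sites$pos[120]))
})

test_that("F_ROH is the long-segment fraction of the genome", {
  cfg <- roh_config(genome_length = 1e8)
  none <- froh(data.frame(sample_id = character(0), length = numeric(0)),
               cfg, samples = "s1")
  expect_equal(none$froh, 0)
  segs <- data.frame(sample_id = "s1", chrom = "chr1", start = 1,
                     end = 2e6, n_sites = 200, length = 2e6)
  expect_equal(froh(segs, cfg)$froh, 0.02)
  # monotone non-increasing in the length threshold
  segs2 <- rbind(segs, data.frame(sample_id = "s1", chrom = "chr2",
                                  start = 1, end = 7e5, n_sites = 60,
                                  length = 7e5))
  vals <- vapply(c(5e5, 1e6, 2e6), function(thr) {
    froh(segs2, roh_config(froh_threshold = thr, genome_length = 1e8))$froh
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(froh(segs, roh_config()), "genome_length")
})

test_that("segments never overlap and BED conversion shifts correctly", {
  r <- cached_replicate()
  gm <- r$cohorts$post_recovery
  segs <- call_roh(gm, r$sites,
                   config = roh_config(min_hom_sites = 5))
  if (nrow(segs) > 0) {
    by_sc <- split(segs, paste(segs$sample_id, segs$chrom))
    for (b in by_sc) {
      b <- b[order(b$start), ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    }
    bed <- roh_to_bed(segs)
    expect_equal(bed$start, segs$start - 1L)
    expect_equal(bed$end - bed$start, segs$length)
  }
  expect_true(nrow(segs) >= 0)
})

test_that("bottlenecked cohorts are at least as autozygous as their ancestors", {
  r <- cached_replicate()
  cfg <- roh_config(min_hom_sites = 20, froh_threshold = 1e4,
                    genome_length = genome_length(r$genome))
  f <- function(gm) {
    segs <- call_roh(gm, r$sites, config = cfg)
    mean(froh(segs, cfg, samples = gm$samples$sample_id)$froh)
  }
  expect_gte(f(r$cohorts$post_recovery), f(r$cohorts$pre_bottleneck))
})
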