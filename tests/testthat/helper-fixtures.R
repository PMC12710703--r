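# Shared fixtures, built in code. Expensive ones are computed once per test
# run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

tiny_demography <- function(burn = 300L, n = 100L) {
  demography_model(data.frame(
    duration = c(burn, 5L, 10L),
    n_start = c(n, n, 30),
    n_end = c(n, 30, 80),
    shape = c("constant", "exponential", "exponential")
  ))
}

tiny_genome <- function(n_genes = 60L, mu = 2e-6, n_chromosomes = 3L) {
  genome_model(n_genes = n_genes, gene_length = 1000, mu = mu,
               n_chromosomes = n_chromosomes)
}

# a cached small selected replicate used by several test files
cached_replicate <- function() {
  if (is.null(.fixtures$rep)) {
    .fixtures$rep <- simulate_replicate(tiny_demography(), dfe_model(),
                                        tiny_genome(), sample_size = 12,
                                        seed = 42)
  }
  .fixtures$rep
}

# genotype matrix built by hand: `spec` is a list of per-sample genotype
# vectors; depth triplets (dp, ad_ref, ad_alt) optional
manual_gm <- function(gt_rows, cohort = "all", dp = NULL, ad_ref = NULL,
                      ad_alt = NULL, gq = NULL) {
  gt <- do.call(rbind, gt_rows)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(gt))),
    cohort = rep_len(cohort, nrow(gt)), stringsAsFactors = FALSE)
  genotype_matrix(gt, samples, dp = dp, gq = gq,
                  ad_ref = ad_ref, ad_alt = ad_alt)
}

# minimal site table for n sites on one or more chromosomes
manual_sites <- function(n, chrom = "chr1", ref = "A", alt = "C",
                         spacing = 1000L) {
  data.frame(chrom = rep_len(chrom, n),
             pos = seq(1L, by = spacing, length.out = n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             is_transition = is_transition_pair(rep_len(ref, n),
                                                rep_len(alt, n)),
             stringsAsFactors = FALSE)
}

# a synthetic 12-sample cohort drawn from given allele frequencies with a
# realistic mixture of transitions and transversions; used for the
# deamination-filter validation fixture
frequency_cohort <- function(n_sites, n_samples = 12, seed = 7,
                             ti_fraction = 2 / 3) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    f <- stats::rbeta(n_sites, 0.3, 1.2)   # skewed toward rare variants
    gt <- matrix(stats::rbinom(n_samples * n_sites, 2,
                               rep(f, each = n_samples)),
                 nrow = n_samples)
    transition <- stats::runif(n_sites) < ti_fraction
    ref <- ifelse(transition, "C", "A")
    alt <- ifelse(transition, "T", "C")
    samples <- data.frame(sample_id = sprintf("h%02d", seq_len(n_samples)),
                          cohort = "historical", stringsAsFactors = FALSE)
    sites <- data.frame(chrom = "chr1",
                        pos = sort(sample.int(n_sites * 50, n_sites)),
                        ref = ref, alt = alt, is_transition = transition,
                        stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(gt, samples), sites = sites)
  })
}

# helper to build a two-cohort matrix with prescribed derived dosages
two_cohort_gm <- function(x_rows, y_rows) {
  gt <- rbind(do.call(rbind, x_rows), do.call(rbind, y_rows))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(gt))),
    cohort = c(rep("x", length(x_rows)), rep("y", length(y_rows))),
    stringsAsFactors = FALSE)
  genotype_matrix(gt, samples)
}

fake_polarized <- function(n, chrom = "chr1", impact = "MODERATE") {
  sites <- manual_sites(n, chrom = chrom)
  sites$impact <- rep_len(impact, n)
  sites$derived_is_alt <- TRUE
  sites$derived <- sites$alt
  list(sites = sites, index = seq_len(n), dropped = 0L)
}

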