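#' Demographic model as an ordered list of epochs
#'
#' An epoch is a stretch of generations with a population-size trajectory that
#' is either constant or interpolates geometrically ("exponential") between a
#' start and an end size. Sizes are diploid individuals. The per-generation
#' size sequence of an exponential epoch is
#' `round(n_start * (n_end/n_start)^(t/duration))` for `t = 1..duration`,
#' never below 2.
#'
#' @param epochs data.frame with columns `duration` (generations, integer
#'   >= 1), `n_start`, `n_end` (diploid sizes >= 2) and `shape`
#'   ("constant" or "exponential"). Constant epochs must have
#'   `n_start == n_end`.
#' @return object of class `demography_model`
#' @seealso [whaling_demography()], [population_path()]
#' @export
demography_model <- function(epochs) {
  stopifnot(is.data.frame(epochs))
  req <- c("duration", "n_start", "n_end", "shape")
  if (!all(req %in% names(epochs))) {
    stop("epochs must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(epochs) < 1) stop("at least one epoch is required")
  if (any(epochs$duration < 1) || any(epochs$duration != round(epochs$duration))) {
    stop("epoch durations must be integers >= 1")
  }
  if (any(epochs$n_start < 2) || any(epochs$n_end < 2)) {
    stop("population sizes must be >= 2")
  }
  if (!all(epochs$shape %in% c("constant", "exponential"))) {
    stop("epoch shape must be 'constant' or 'exponential'")
  }
  bad <- epochs$shape == "constant" & epochs$n_start != epochs$n_end
  if (any(bad)) stop("constant epochs must have n_start == n_end")
  epochs$duration <- as.integer(epochs$duration)
  if (is.null(epochs$mu_factor)) epochs$mu_factor <- 1
  structure(list(epochs = epochs), class = "demography_model")
}

#' @exportS3Method print demography_model
print.demography_model <- function(x, ...) {
  cat("Demography model:", nrow(x$epochs), "epochs,",
      sum(x$epochs$duration), "generations\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' The whaling-bottleneck demography
#'
#' A 500,000-generation burn-in at a constant size of 16,000 diploids,
#' a rapid exponential bottleneck to 375 over five generations, and an
#' exponential recovery to 8,000 over ten generations. This is the
#' demographic history used throughout the package's simulation study of
#' genomic erosion in a heavily whaled baleen-whale population.
#'
#' @return a [demography_model()] with three epochs
#' @export
whaling_demography <- function() {
  demography_model(data.frame(
    duration = c(500000L, 5L, 10L),
    n_start  = c(16000, 16000, 375),
    n_end    = c(16000, 375, 8000),
    shape    = c("constant", "exponential", "exponential")
  ))
}

#' Distribution of fitness effects for new mutations
#'
#' New mutations are neutral with probability `p_neutral`; otherwise their
#' selection coefficient is drawn from a gamma distribution (negative sign,
#' heterozygote disadvantage `h * s`). Diploid fitness at a site is
#' `1 + h*s` for heterozygotes and `1 + s` for derived homozygotes,
#' multiplicative across sites with each per-site factor floored at 0.
#'
#' The gamma shape/mean defaults follow the parameterisation commonly used
#' for human coding DFEs; they are package defaults, configurable here.
#' Dominance is either a fixed `h` (default 0.5, genic selection) or the
#' `"hs"` mode `h(s) = h / (1 + hs_k * |s|)` under which strongly deleterious
#' mutations are nearly recessive.
#'
#' @param p_neutral proportion of new mutations that are neutral, in `[0,1]`
#' @param gamma_shape shape of the gamma-distributed deleterious class
#' @param mean_s mean selection coefficient of the deleterious class
#'   (negative)
#' @param h dominance coefficient in `[0,1]` (also the `h0` of the `"hs"`
#'   relationship)
#' @param dominance_mode `"fixed"` or `"hs"`
#' @param hs_k slope constant of the `h(s)` relationship
#' @return object of class `dfe_model`
#' @export
dfe_model <- function(p_neutral = 0.3, gamma_shape = 0.186, mean_s = -0.01,
                      h = 0.5, dominance_mode = c("fixed", "hs"),
                      hs_k = 7071.07) {
  dominance_mode <- match.arg(dominance_mode)
  stopifnot(p_neutral >= 0, p_neutral <= 1, gamma_shape > 0,
            mean_s <= 0, h >= 0, h <= 1, hs_k >= 0)
  structure(list(p_neutral = p_neutral, gamma_shape = gamma_shape,
                 mean_s = mean_s, h = h, dominance_mode = dominance_mode,
                 hs_k = hs_k, s_scale = 1),
            class = "dfe_model")
}

#' Genome representation for the simulator
#'
#' The genome is `n_genes` genes of `gene_length` bp each, assigned to
#' `n_chromosomes` chromosomes as evenly as possible; recombination is free
#' between genes and absent within a gene. Defaults mirror the gene content
#' used for the whaling simulation study (25,314 genes of 1 kb on 21
#' autosomes) and a pedigree-based baleen-whale mutation rate.
#'
#' @param n_genes number of genes
#' @param gene_length gene length in bp
#' @param n_chromosomes number of chromosomes (autosomes)
#' @param mu per-site mutation rate, mutations/bp/generation
#' @param ti_fraction fraction of derived alleles that are transitions when
#'   bases are assigned to simulated sites (Ti:Tv of 2 by default)
#' @return object of class `genome_model`
#' @export
genome_model <- function(n_genes = 25314, gene_length = 1000,
                         n_chromosomes = 21, mu = 1.12e-8,
                         ti_fraction = 2 / 3) {
  stopifnot(n_genes >= 1, gene_length >= 1, n_chromosomes >= 1,
            mu >= 0, ti_fraction >= 0, ti_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 mu = mu, ti_fraction = ti_fraction),
            class = "genome_model")
}

#' Total simulated genome length in bp
#' @param genome a [genome_model()]
#' @export
genome_length <- function(genome) {
  as.numeric(genome$n_genes) * genome$gene_length
}

#' Chromosome assignment of genes
#'
#' Genes are distributed over chromosomes as evenly as possible, in order.
#'
#' @param genome a [genome_model()]
#' @return integer vector of length `n_genes` with chromosome indices
#' @export
gene_chromosomes <- function(genome) {
  cuts <- round(seq(0, genome$n_genes, length.out = genome$n_chromosomes + 1))
  rep(seq_len(genome$n_chromosomes), times = diff(cuts))
}

#' Rescale a simulation model to desk scale
#'
#' Standard population-genetics rescaling by a factor `lambda`: the burn-in
#' (first) epoch runs with `N/lambda` individuals for `duration/lambda`
#' generations at a mutation rate `mu * lambda`, which preserves
#' `theta = 4*N*mu`. Selection coefficients are multiplied by `lambda` in all
#' epochs, preserving `N*s` during the burn-in. Later epochs keep their
#' natural generation counts and sizes (so drift per natural generation is
#' preserved) and run at the natural mutation rate, unless
#' `scale_bottleneck = TRUE`, which divides their sizes by `lambda` as well.
#'
#' @param demography a [demography_model()]
#' @param dfe a [dfe_model()]
#' @param genome a [genome_model()]
#' @param lambda rescaling factor >= 1; must leave the burn-in with at least
#'   100 generations and every size >= 2
#' @param scale_bottleneck also divide post-burn-in epoch sizes by `lambda`
#' @return list with rescaled `demography`, `dfe`, `genome`
#' @export
rescale_models <- function(demography, dfe, genome, lambda = 20,
                           scale_bottleneck = FALSE) {
  stopifnot(inherits(demography, "demography_model"),
            inherits(dfe, "dfe_model"), inherits(genome, "genome_model"),
            lambda >= 1)
  ep <- demography$epochs
  if (lambda == 1) {
    return(list(demography = demography, dfe = dfe, genome = genome))
  }
  if (ep$duration[1] / lambda < 100) {
    stop("lambda leaves the burn-in with fewer than 100 generations")
  }
  ep$duration[1] <- as.integer(round(ep$duration[1] / lambda))
  ep$n_start[1] <- round(ep$n_start[1] / lambda)
  ep$n_end[1] <- round(ep$n_end[1] / lambda)
  ep$mu_factor <- c(lambda, rep(1, nrow(ep) - 1L))
  if (scale_bottleneck && nrow(ep) > 1) {
    later <- seq(2, nrow(ep))
    ep$n_start[later] <- round(ep$n_start[later] / lambda)
    ep$n_end[later] <- round(ep$n_end[later] / lambda)
    ep$mu_factor[later] <- lambda
  }
  if (any(ep$n_start < 2) || any(ep$n_end < 2)) {
    stop("lambda yields a population size below 2")
  }
  dfe$s_scale <- dfe$s_scale * lambda
  demography$epochs <- ep
  list(demography = demography, dfe = dfe, genome = genome)
}

#' Per-generation population-size path of a demography
#'
#' Expands the epoch list into one diploid size per generation. Generation 1
#' is the founding population at the burn-in size; exponential epochs
#' interpolate geometrically, rounded to the nearest integer and never below
#' 2.
#'
#' @param demography a [demography_model()]
#' @return list with integer vector `n` (one size per generation), numeric
#'   vector `mu_factor` (per-generation mutation-rate multiplier), and
#'   integer vector `epoch_end` (last generation index of each epoch)
#' @export
population_path <- function(demography) {
  ep <- demography$epochs
  n <- integer(0)
  muf <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    d <- ep$duration[i]
    if (ep$shape[i] == "constant") {
      seg <- rep(ep$n_start[i], d)
    } else {
      seg <- pmax(2, round(ep$n_start[i] * (ep$n_end[i] / ep$n_start[i])^(seq_len(d) / d)))
    }
    n <- c(n, as.integer(seg))
    muf <- c(muf, rep(ep$mu_factor[i], d))
  }
  list(n = n, mu_factor = muf, epoch_end = as.integer(cumsum(ep$duration)))
}
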