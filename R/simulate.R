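#' @useDynLib popgenerode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal: run expr with a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# internal: deterministic 31-bit stream seed from (seed, replicate, salt)
derive_seed <- function(seed, replicate = 1, salt = 0) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(replicate) * 40503 +
          as.numeric(salt) * 69621) %% 2147483647
  as.integer(x) + 1L
}

#' Simulate one forward Wright-Fisher replicate
#'
#' Runs an individual-based Wright-Fisher simulation of the given demography
#' with the given DFE and genome: Poisson mutation at rate
#' `mu * 2N * genome length` per generation, fitness-weighted multinomial
#' resampling of `2N` gametes with free recombination between genes and none
#' within, and diploid cohorts of `sample_size` individuals drawn without
#' replacement at each requested timepoint. `"pre_bottleneck"` samples at the
#' last generation of the first epoch, `"post_recovery"` at the final
#' generation. Sites fixed in the population before the first sampling are
#' dropped; the emitted site table covers every mutation segregating in at
#' least one sampled cohort.
#'
#' @param demography a [demography_model()]
#' @param dfe a [dfe_model()]
#' @param genome a [genome_model()]
#' @param sample_size diploid genomes per cohort (must not exceed the
#'   population size at any sampled generation)
#' @param timepoints character vector of cohort labels, subset of
#'   `c("pre_bottleneck", "post_recovery")`
#' @param seed integer seed; together with `replicate` it fully determines
#'   the replicate
#' @param replicate replicate index (counter-based stream within `seed`)
#' @return object of class `sim_replicate`: list with `cohorts` (named list
#'   of [genotype_matrix()]), `sites` (shared site table), `summaries`, and
#'   the `seed`/`replicate` used
#' @export
simulate_replicate <- function(demography, dfe, genome, sample_size = 12,
                               timepoints = c("pre_bottleneck", "post_recovery"),
                               seed = 1, replicate = 1) {
  stopifnot(inherits(demography, "demography_model"),
            inherits(dfe, "dfe_model"),
            inherits(genome, "genome_model"))
  if (length(timepoints) == 0) stop("at least one timepoint is required")
  if (!all(timepoints %in% c("pre_bottleneck", "post_recovery"))) {
    stop("timepoints must be 'pre_bottleneck' and/or 'post_recovery'")
  }
  path <- population_path(demography)
  gens <- vapply(timepoints, function(tp) {
    if (tp == "pre_bottleneck") path$epoch_end[1] else length(path$n)
  }, integer(1))
  if (any(path$n[gens] < sample_size)) {
    stop("sample_size exceeds the population size at a sampled generation")
  }

  mu_per_copy <- genome$mu * path$mu_factor * genome_length(genome)
  dom_mode <- if (dfe$dominance_mode == "hs") 1L else 0L
  res <- .wf_simulate_cpp(path$n, mu_per_copy, sort(unique(gens)),
                          as.integer(sample_size),
                          genome$n_genes, genome$gene_length,
                          dfe$p_neutral, dfe$gamma_shape, abs(dfe$mean_s),
                          dfe$s_scale, dom_mode, dfe$h, dfe$hs_k,
                          as.numeric(seed), as.numeric(replicate), 100L)

  # mutations present in at least one sampled cohort
  used <- sort(unique(unlist(lapply(res$samples, function(s) {
    unlist(s$copies, use.names = FALSE)
  }))))
  if (is.null(used)) used <- integer(0)

  sites <- with_seed(derive_seed(seed, replicate, 1), {
    build_site_table(res, used, genome, dfe)
  })
  ord <- order(sites$chrom_index, sites$pos)
  # a freed position can be reused by a later mutation; keep one site per
  # position so the emitted table stays strictly biallelic
  dup <- duplicated(data.frame(sites$chrom_index, sites$pos)[ord, ])
  ord <- ord[!dup]
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  cohorts <- list()
  mean_fitness <- numeric(0)
  for (k in seq_along(res$samples)) {
    s <- res$samples[[k]]
    label <- timepoints[match(s$generation, gens)]
    mean_fitness[label] <- s$mean_fitness
    gt <- matrix(0L, nrow = sample_size, ncol = length(used))
    for (i in seq_len(sample_size)) {
      for (c_ in 1:2) {
        ids <- s$copies[[2 * (i - 1) + c_]]
        if (length(ids) > 0) {
          j <- match(ids, used)
          gt[i, j] <- gt[i, j] + 1L
        }
      }
    }
    gt <- gt[, ord, drop = FALSE]
    samples_df <- data.frame(
      sample_id = sprintf("%s_%02d", label, seq_len(sample_size)),
      cohort = label,
      mean_depth = NA_real_,
      sampling_year = NA_integer_,
      stringsAsFactors = FALSE
    )
    cohorts[[label]] <- genotype_matrix(gt, samples_df)
  }
  cohorts <- cohorts[intersect(timepoints, names(cohorts))]

  sites$chrom_index <- NULL
  rep_obj <- structure(list(seed = seed, replicate = replicate,
                            cohorts = cohorts, sites = sites,
                            genome = genome,
                            mean_fitness = mean_fitness[intersect(
                              timepoints, names(mean_fitness))],
                            summaries = NULL),
                       class = "sim_replicate")
  rep_obj$summaries <- replicate_summaries(rep_obj)
  rep_obj
}

# internal: site table for the mutations with ids `used` (0-based)
build_site_table <- function(res, used, genome, dfe) {
  if (length(used) == 0) {
    return(data.frame(chrom = character(0), chrom_index = integer(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), is_transition = logical(0),
                      s = numeric(0), h = numeric(0), impact = character(0),
                      ancestral = character(0), gene = integer(0),
                      stringsAsFactors = FALSE))
  }
  gene <- res$mut_gene[used + 1L]
  offset <- res$mut_offset[used + 1L]
  s_scaled <- res$mut_s[used + 1L]
  h <- res$mut_h[used + 1L]
  chrom_of_gene <- gene_chromosomes(genome)
  # position within the chromosome: genes are laid out end to end
  first_gene <- c(0L, cumsum(tabulate(chrom_of_gene,
                                      nbins = genome$n_chromosomes)))
  chrom_idx <- chrom_of_gene[gene + 1L]
  local_gene <- gene - first_gene[chrom_idx]
  pos <- local_gene * genome$gene_length + offset + 1L

  n <- length(used)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  is_ti <- stats::runif(n) < genome$ti_fraction
  alt <- ifelse(is_ti, transition_of[ref], NA)
  tv <- is.na(alt)
  if (any(tv)) {
    tv_choices <- list(A = c("C", "T"), C = c("A", "G"),
                       G = c("C", "T"), T = c("A", "G"))
    alt[tv] <- vapply(which(tv), function(i) {
      sample(tv_choices[[ref[i]]], 1)
    }, character(1))
  }
  s_natural <- s_scaled / dfe$s_scale
  data.frame(
    chrom = paste0("chr", chrom_idx),
    chrom_index = chrom_idx,
    pos = as.integer(pos),
    ref = unname(ref),
    alt = unname(alt),
    is_transition = unname(is_transition_pair(ref, alt)),
    s = s_natural,
    h = h,
    impact = assign_impact_categories(s_natural),
    ancestral = unname(ref),
    gene = gene,
    stringsAsFactors = FALSE
  )
}

#' Assign functional-impact categories from selection coefficients
#'
#' Maps selection coefficients to the four annotation-style impact
#' categories by thresholding `|s|`: neutral sites are split between
#' MODIFIER and LOW (a seeded 50/50 split by default), `|s|` in `(0, t1]` is
#' LOW, `(t1, t2]` MODERATE, and above `t2` HIGH.
#'
#' @param s numeric vector of (natural-scale) selection coefficients
#' @param t1,t2 thresholds partitioning `|s|`; defaults 1e-4 and 1e-2
#' @param modifier_fraction fraction of neutral sites labelled MODIFIER
#'   (the rest are LOW)
#' @return character vector of categories
#' @export
assign_impact_categories <- function(s, t1 = 1e-4, t2 = 1e-2,
                                     modifier_fraction = 0.5) {
  if (!(t1 > 0 && t2 > t1)) stop("thresholds must satisfy 0 < t1 < t2")
  a <- abs(s)
  out <- character(length(s))
  neutral <- a == 0
  out[neutral] <- ifelse(stats::runif(sum(neutral)) < modifier_fraction,
                         "MODIFIER", "LOW")
  out[!neutral & a <= t1] <- "LOW"
  out[a > t1 & a <= t2] <- "MODERATE"
  out[a > t2] <- "HIGH"
  out
}

#' Summaries of a simulated replicate
#'
#' Recomputes the per-replicate summary block from the stored genotypes:
#' mean per-individual heterozygosity per timepoint (heterozygous genotypes
#' over total genome length), the percent heterozygosity change between the
#' first and last timepoint, per-cohort counts of segregating derived
#' variants per impact category, and total ROH length per cohort under the
#' default ROH model.
#'
#' @param x a `sim_replicate`
#' @param roh also compute total ROH length per cohort (slower)
#' @return list with `het`, `het_loss_pct`, `derived_counts`, `roh_total_bp`
#' @export
replicate_summaries <- function(x, roh = FALSE) {
  stopifnot(inherits(x, "sim_replicate"))
  L <- genome_length(x$genome)
  het <- vapply(x$cohorts, function(gm) {
    mean(rowSums(gm$gt == 1L, na.rm = TRUE)) / L
  }, numeric(1))
  loss <- if (length(het) >= 2) {
    100 * (1 - het[[length(het)]] / het[[1]])
  } else {
    NA_real_
  }
  derived <- lapply(x$cohorts, function(gm) {
    seg <- colSums(gm$gt, na.rm = TRUE) > 0
    table(factor(x$sites$impact[seg],
                 levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  })
  roh_total <- NULL
  if (roh) {
    roh_total <- vapply(x$cohorts, function(gm) {
      segs <- call_roh(gm, x$sites, config = roh_config())
      if (nrow(segs) == 0) 0 else sum(segs$length)
    }, numeric(1))
  }
  list(het = het, het_loss_pct = loss, derived_counts = derived,
       roh_total_bp = roh_total)
}

#' @exportS3Method print sim_replicate
print.sim_replicate <- function(x, ...) {
  cat("Simulated replicate (seed", x$seed, "rep", x$replicate, "):",
      nrow(x$sites), "segregating sites;",
      paste(names(x$cohorts), collapse = ", "), "\n")
  cat(sprintf("Heterozygosity: %s; loss %.2f%%\n",
              paste(sprintf("%.3g", x$summaries$het), collapse = " -> "),
              x$summaries$het_loss_pct))
  invisible(x)
}
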