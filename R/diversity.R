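#' Genome-wide heterozygosity per sample
#'
#' The ratio of heterozygous genotypes to callable sites per individual
#' genome. With variant-only input the callable denominator cannot be
#' recovered from the data, so it is supplied either directly
#' (`callable_sites`, per sample or scalar) or as the number of monomorphic
#' callable positions to add to each sample's non-missing genotype count
#' (`monomorphic_callable`).
#'
#' @param gm a [genotype_matrix()]
#' @param callable_sites callable-site count per sample (scalar or vector
#'   named/ordered as the samples); overrides `monomorphic_callable`
#' @param monomorphic_callable monomorphic callable positions to add to the
#'   per-sample non-missing genotype count
#' @return data.frame with `sample_id`, `cohort`, `het_count`, `callable`,
#'   `het`
#' @export
genome_wide_heterozygosity <- function(gm, callable_sites = NULL,
                                       monomorphic_callable = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  het_count <- rowSums(gm$gt == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(gm$gt))
  callable <- if (!is.null(callable_sites)) {
    rep_len(callable_sites, nrow(gm$gt))
  } else {
    nonmiss + monomorphic_callable
  }
  if (any(callable <= 0)) stop("callable site count must be positive")
  if (any(callable < nonmiss)) {
    stop("callable sites cannot be fewer than genotyped sites")
  }
  data.frame(sample_id = gm$samples$sample_id, cohort = gm$samples$cohort,
             het_count = het_count, callable = callable,
             het = het_count / callable, row.names = NULL)
}

#' Configuration of the ROH hidden Markov model
#'
#' Two hidden states per site — autozygous (within a run of homozygosity)
#' and non-autozygous — with transition probabilities scaled by physical
#' distance and emissions driven by Hardy-Weinberg heterozygosity outside
#' runs and a genotyping-error rate inside them. Default rates follow the
#' published defaults of the standard HMM ROH caller; they are package
#' defaults, not estimates.
#'
#' @param az_entry per-bp rate of entering the autozygous state
#' @param az_exit per-bp rate of leaving the autozygous state
#' @param error_rate probability of observing a heterozygote inside a run
#'   (genotyping error)
#' @param min_hom_sites minimum homozygous genotypes per reported run
#' @param froh_threshold minimum run length (bp) entering F_ROH
#' @param genome_length autosomal genome length in bp (F_ROH denominator)
#' @return object of class `roh_config`
#' @export
roh_config <- function(az_entry = 6.7e-8, az_exit = 5e-9, error_rate = 1e-4,
                       min_hom_sites = 50, froh_threshold = 1e6,
                       genome_length = NULL) {
  stopifnot(az_entry > 0, az_entry < 1, az_exit > 0, az_exit < 1,
            error_rate > 0, error_rate < 1, min_hom_sites >= 1,
            froh_threshold > 0)
  structure(list(az_entry = az_entry, az_exit = az_exit,
                 error_rate = error_rate,
                 min_hom_sites = as.integer(min_hom_sites),
                 froh_threshold = froh_threshold,
                 genome_length = genome_length),
            class = "roh_config")
}

# internal: Viterbi decoding of the 2-state ROH HMM for one sample on one
# chromosome. obs: 0 = hom, 1 = het; pos: 1-based positions; p: alt allele
# frequency per site. Returns integer states (1 = non-autozygous, 2 =
# autozygous).
roh_viterbi <- function(obs, pos, p, config) {
  n <- length(obs)
  phet <- pmin(pmax(2 * p * (1 - p), config$error_rate), 1 - config$error_rate)
  # emission log-probabilities: rows = state (hw, az), cols = site
  le <- rbind(ifelse(obs == 1, log(phet), log1p(-phet)),
              ifelse(obs == 1, log(config$error_rate),
                     log1p(-config$error_rate)))
  delta <- c(log(0.5), log(0.5)) + le[, 1]
  psi <- matrix(0L, nrow = 2, ncol = n)
  if (n > 1) {
    for (i in 2:n) {
      d <- pos[i] - pos[i - 1]
      p_in <- -expm1(-config$az_entry * d)   # 1 - exp(-rate*d)
      p_out <- -expm1(-config$az_exit * d)
      ltr <- matrix(c(log1p(-p_in), log(p_in), log(p_out), log1p(-p_out)),
                    nrow = 2, byrow = TRUE)  # [from, to]
      for (s in 1:2) {
        cand <- delta + ltr[, s]
        psi[s, i] <- which.max(cand)         # ties resolve to state 1 (hw)
      }
      delta <- vapply(1:2, function(s) max(delta + ltr[, s]), numeric(1)) +
        le[, i]
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta)
  if (n > 1) for (i in (n - 1):1) states[i] <- psi[states[i + 1], i + 1]
  states
}

#' Call runs of homozygosity with a two-state HMM
#'
#' Per sample and chromosome, decodes the autozygous/non-autozygous state
#' sequence by Viterbi and reports contiguous autozygous runs containing at
#' least `min_hom_sites` homozygous genotypes. Segment boundaries are the
#' outermost homozygous sites of the run (1-based, inclusive). Allele
#' frequencies default to estimates from the dataset itself.
#'
#' @param gm a [genotype_matrix()]
#' @param sites aligned site table (`chrom`, `pos`)
#' @param allele_freqs optional per-site alt-allele frequencies; estimated
#'   from `gm` when `NULL`
#' @param config a [roh_config()]
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `n_sites`, `length`
#' @export
call_roh <- function(gm, sites, allele_freqs = NULL, config = roh_config()) {
  check_aligned(gm, sites)
  if (is.null(allele_freqs)) allele_freqs <- allele_frequencies(gm)
  stopifnot(length(allele_freqs) == nrow(sites))
  segs <- list()
  for (chrom in unique(sites$chrom)) {
    cidx <- which(sites$chrom == chrom)
    cidx <- cidx[order(sites$pos[cidx])]
    for (si in seq_len(nrow(gm$gt))) {
      gts <- gm$gt[si, cidx]
      ok <- !is.na(gts) & !is.na(allele_freqs[cidx])
      idx <- cidx[ok]
      if (length(idx) < config$min_hom_sites) next
      obs <- as.integer(gm$gt[si, idx] == 1L)
      st <- roh_viterbi(obs, sites$pos[idx], allele_freqs[idx], config)
      r <- rle(st == 2L)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- seq(starts[k], ends[k])
        hom <- run[obs[run] == 0L]
        if (length(hom) < config$min_hom_sites) next
        segs[[length(segs) + 1]] <- data.frame(
          sample_id = gm$samples$sample_id[si], chrom = chrom,
          start = sites$pos[idx[hom[1]]],
          end = sites$pos[idx[hom[length(hom)]]],
          n_sites = length(hom), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0), length = integer(0)))
  }
  out <- do.call(rbind, segs)
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Inbreeding coefficient from runs of homozygosity
#'
#' The fraction of the autosomal genome lying in ROHs longer than the
#' configured threshold (1 Mbp by default), per sample.
#'
#' @param segments segment table from [call_roh()]
#' @param config a [roh_config()] whose `genome_length` must be set
#' @param samples optional sample ids to report (defaults to those present
#'   in `segments`)
#' @return data.frame with `sample_id` and `froh`
#' @export
froh <- function(segments, config, samples = NULL) {
  if (is.null(config$genome_length) || config$genome_length <= 0) {
    stop("config$genome_length (autosomal genome length) must be positive")
  }
  if (is.null(samples)) samples <- unique(segments$sample_id)
  long <- segments[segments$length > config$froh_threshold, , drop = FALSE]
  tot <- tapply(long$length, factor(long$sample_id, levels = samples), sum)
  tot[is.na(tot)] <- 0
  data.frame(sample_id = samples,
             froh = as.numeric(tot) / config$genome_length,
             row.names = NULL)
}

#' Convert ROH segments to BED intervals
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open.
#'
#' @param segments segment table from [call_roh()]
#' @return data.frame with `chrom`, `start`, `end`, `name` in BED
#'   convention
#' @export
roh_to_bed <- function(segments) {
  data.frame(chrom = segments$chrom,
             start = segments$start - 1L,
             end = segments$end,
             name = segments$sample_id,
             stringsAsFactors = FALSE)
}
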