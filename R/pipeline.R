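#' Default pipeline configuration
#'
#' A nested list covering every stage of the erosion pipeline: the
#' simulation study (demography, DFE, genome, rescaling, replicates), the
#' temporal filters, the diversity/ROH stage, the mutation-load stage and
#' the trajectory/catch stage. The configuration round-trips losslessly
#' through a YAML file; unknown keys are rejected by name when read back.
#'
#' @param seed master seed for every stage
#' @param outdir output directory
#' @return nested configuration list of class `pipeline_config`
#' @export
default_config <- function(seed = 1, outdir = "popgenerode-out") {
  structure(list(
    seed = seed,
    outdir = outdir,
    stages = c("simulate", "filter", "diversity", "load", "demography"),
    simulate = list(
      demography = "whaling",
      n_genes = 500L, gene_length = 1000L, n_chromosomes = 21L,
      mu = 1.12e-8, lambda = 20, sample_size = 12L,
      p_neutral = 0.3, gamma_shape = 0.186, mean_s = -0.01, h = 0.5,
      dominance_mode = "fixed", deamination_rate = 0.05, target_depth = 6
    ),
    filter = list(
      min_qual = 40, max_missing_fraction = 0.5, min_dp = 6, min_gq = 15,
      min_variant_depth = 3, balance_low = 0.35, balance_high = 0.75,
      min_transition_count = 3
    ),
    diversity = list(
      az_entry = 6.7e-8, az_exit = 5e-9, error_rate = 1e-4,
      min_hom_sites = 50L, froh_threshold = 1e6
    ),
    load = list(freq_threshold = 0.95, outgroup_mismatch = 0.01),
    demography = list(
      ne_nc_ratio = 4, anchor_year = 1904, anchor_generation = 13,
      sampling_year = 2008, g_threshold = 100, n_ld_samples = 9L,
      n_runs = 50L, run_noise_sd = 0.1, catch_noise_sd = 0.05
    )
  ), class = "pipeline_config")
}

#' Write a pipeline configuration to a YAML file
#' @param config a `pipeline_config`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' Unknown keys (at the top level or within a stage block) are rejected
#' with an error naming the key; missing keys fall back to defaults.
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(default_config())
  bad <- setdiff(names(raw), names(ref))
  if (length(bad) > 0) stop("unknown configuration key: ", bad[1])
  for (blk in intersect(names(raw), names(ref))) {
    if (is.list(ref[[blk]]) && is.list(raw[[blk]])) {
      badk <- setdiff(names(raw[[blk]]), names(ref[[blk]]))
      if (length(badk) > 0) {
        stop("unknown configuration key: ", blk, "$", badk[1])
      }
      ref[[blk]][names(raw[[blk]])] <- raw[[blk]]
    } else {
      ref[[blk]] <- raw[[blk]]
    }
  }
  structure(ref, class = "pipeline_config")
}

# internal: stable hash of a configuration (md5 of its canonical YAML)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the erosion pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate a replicate,
#' add historical sequencing artifacts, apply the temporal filters, compute
#' heterozygosity/ROH/F_ROH, polarize and compute mutation load and R_x/y,
#' and run the trajectory/catch analyses on a synthetic Ne-run table built
#' from the true demographic path. Every output table is written under
#' `config$outdir` together with a run manifest (config hash, seed,
#' package version).
#'
#' @param config a `pipeline_config` (or a path to one)
#' @return list of stage outputs (invisibly also written to disk), of
#'   class `pipeline_result`
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- list(config = config)
  tsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  run_simulate <- "simulate" %in% config$stages
  run_filter <- "filter" %in% config$stages
  run_diversity <- "diversity" %in% config$stages
  run_load <- "load" %in% config$stages
  run_demography <- "demography" %in% config$stages
  if ((run_filter || run_diversity || run_load) && !run_simulate) {
    stop("the filter/diversity/load stages require the simulate stage")
  }

  if (run_simulate) {
    sc <- config$simulate
    genome <- genome_model(n_genes = sc$n_genes, gene_length = sc$gene_length,
                           n_chromosomes = sc$n_chromosomes, mu = sc$mu)
    dfe <- dfe_model(p_neutral = sc$p_neutral, gamma_shape = sc$gamma_shape,
                     mean_s = sc$mean_s, h = sc$h,
                     dominance_mode = sc$dominance_mode)
    demo <- if (identical(sc$demography, "whaling")) {
      whaling_demography()
    } else {
      demography_model(as.data.frame(lapply(sc$demography, unlist)))
    }
    models <- rescale_models(demo, dfe, genome, lambda = sc$lambda)
    rep1 <- simulate_replicate(models$demography, models$dfe, models$genome,
                               sample_size = sc$sample_size, seed = seed)
    hist_art <- add_historical_artifacts(
      rep1$cohorts$pre_bottleneck, rep1$sites,
      deamination_rate = sc$deamination_rate,
      target_depth = sc$target_depth, seed = derive_seed(seed, salt = 10))
    # contemporary cohort sequenced at the same (downsampled) depth,
    # aligned to the artifact-extended site table
    cont_gt <- matrix(0L, nrow = sc$sample_size, ncol = nrow(hist_art$sites))
    idx <- match(paste(rep1$sites$chrom, rep1$sites$pos),
                 paste(hist_art$sites$chrom, hist_art$sites$pos))
    cont_gt[, idx] <- rep1$cohorts$post_recovery$gt
    cont_samples <- rep1$cohorts$post_recovery$samples
    cont_samples$cohort <- "contemporary"
    cont_samples$sample_id <- sub("post_recovery", "contemporary",
                                  cont_samples$sample_id)
    cont_samples$sampling_year <- config$demography$sampling_year
    cont <- attach_read_depths(
      genotype_matrix(cont_gt, cont_samples),
      target_depth = sc$target_depth, seed = derive_seed(seed, salt = 11))
    hist_gm <- hist_art$genotypes
    hist_gm$samples$cohort <- "historical"
    hist_gm$samples$sample_id <- sub("pre_bottleneck", "historical",
                                     hist_gm$samples$sample_id)
    hist_gm$samples$sampling_year <- config$demography$anchor_year
    rownames(hist_gm$gt) <- hist_gm$samples$sample_id
    merged <- genotype_matrix(
      rbind(hist_gm$gt, cont$gt),
      rbind(hist_gm$samples, cont$samples),
      dp = rbind(hist_gm$dp, cont$dp), gq = rbind(hist_gm$gq, cont$gq),
      ad_ref = rbind(hist_gm$ad_ref, cont$ad_ref),
      ad_alt = rbind(hist_gm$ad_alt, cont$ad_alt))
    out$simulate <- list(replicate = rep1, merged = merged,
                         sites = hist_art$sites, genome = genome)
    write_cohort_vcf(merged, hist_art$sites,
                     file.path(config$outdir, "temporal.vcf"))
    write_cohort_tsv(merged, file.path(config$outdir, "cohorts.tsv"))
    tsv(data.frame(timepoint = names(rep1$summaries$het),
                   het = unname(rep1$summaries$het),
                   het_loss_pct = rep1$summaries$het_loss_pct),
        "simulation_summary.tsv")
  }

  if (run_filter) {
    fc <- filter_config(
      min_qual = config$filter$min_qual,
      max_missing_fraction = config$filter$max_missing_fraction,
      min_dp = config$filter$min_dp, min_gq = config$filter$min_gq,
      min_variant_depth = config$filter$min_variant_depth,
      balance = c(config$filter$balance_low, config$filter$balance_high),
      min_transition_count = config$filter$min_transition_count)
    st <- filter_sites(out$simulate$merged, out$simulate$sites, fc)
    hm <- harmonize_temporal(st$genotypes, st$sites, fc)
    out$filter <- list(genotypes = hm$genotypes, sites = hm$sites,
                       report = rbind(st$report, hm$report), config = fc)
    tsv(out$filter$report, "filter_report.tsv")
  }

  if (run_diversity) {
    dc <- config$diversity
    rc <- roh_config(az_entry = dc$az_entry, az_exit = dc$az_exit,
                     error_rate = dc$error_rate,
                     min_hom_sites = dc$min_hom_sites,
                     froh_threshold = dc$froh_threshold,
                     genome_length = genome_length(out$simulate$genome))
    gm <- out$filter$genotypes
    sites <- out$filter$sites
    het <- genome_wide_heterozygosity(
      gm, callable_sites = genome_length(out$simulate$genome))
    segs <- call_roh(gm, sites, config = rc)
    fr <- froh(segs, rc, samples = gm$samples$sample_id)
    out$diversity <- list(het = het, segments = segs, froh = fr)
    tsv(merge(het, fr, by = "sample_id"), "diversity.tsv")
    if (nrow(segs) > 0) tsv(roh_to_bed(segs), "roh.bed")
  }

  if (run_load) {
    gm <- out$filter$genotypes
    sites <- out$filter$sites
    sites <- with_seed(derive_seed(seed, salt = 12), {
      mism <- stats::runif(nrow(sites)) < config$load$outgroup_mismatch
      sites$outgroup1 <- ifelse(mism, sites$alt, sites$ancestral)
      sites$outgroup2 <- sites$ancestral
      sites
    })
    pol <- polarize(gm, sites,
                    freq_threshold = config$load$freq_threshold)
    lps <- load_per_sample(gm, pol)
    rxy_tab <- do.call(rbind, lapply(
      intersect(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                unique(pol$sites$impact)),
      function(cat_) {
        r <- try(rxy(gm, pol, "historical", "contemporary", cat_),
                 silent = TRUE)
        if (inherits(r, "try-error")) return(NULL)
        data.frame(category = cat_, estimate = r$estimate,
                   ci_low = r$ci[1], ci_high = r$ci[2],
                   n_blocks = r$n_blocks)
      }))
    out$load <- list(polarized = pol, per_sample = lps, rxy = rxy_tab)
    tsv(lps, "load.tsv")
    if (!is.null(rxy_tab)) tsv(rxy_tab, "rxy.tsv")
  }

  if (run_demography) {
    dc <- config$demography
    path <- population_path(whaling_demography())
    # most recent generations of the true path, g = 1..60
    recent <- rev(path$n)[seq_len(min(60, length(path$n)))]
    runs <- with_seed(derive_seed(seed, salt = 13), {
      do.call(rbind, lapply(seq_len(dc$n_runs), function(r) {
        data.frame(run = r, generation = seq_along(recent),
                   ne = recent * exp(stats::rnorm(length(recent), 0,
                                                  dc$run_noise_sd)))
      }))
    })
    traj <- summarize_trajectory(runs)
    traj <- ne_to_nc(traj, ratio = dc$ne_nc_ratio)
    gen_time <- calibrate_generation_time(dc$anchor_year,
                                          dc$anchor_generation,
                                          dc$sampling_year)
    traj <- map_generations_to_years(traj, gen_time, dc$sampling_year)
    # robustness of each generational estimate: pairwise SNP comparisons
    # shrink for older generation bins in LD-based estimation
    theta_bins <- round(2e5 / (1 + traj$generation))
    gstat <- g_statistic(dc$n_ld_samples, theta_bins, traj$ne_mean,
                         threshold = dc$g_threshold)
    traj$g <- gstat$g
    traj$low_confidence <- gstat$low_confidence
    catches <- generate_catch_series(
      rev(traj$nc_mean), years = rev(traj$year),
      reporting_noise = dc$catch_noise_sd,
      seed = derive_seed(seed, salt = 14))
    corr <- catch_correlation(traj, catches, gen_time, dc$sampling_year,
                              value = "nc_mean")
    out$demography <- list(trajectory = traj, gen_time = gen_time,
                           catches = catches, correlation = corr)
    tsv(traj, "trajectory.tsv")
    tsv(catches, "catches.tsv")
  }

  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package_version = as.character(
                     utils::packageVersion("popgenerode")),
                   stages = config$stages)
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  out$manifest <- manifest
  class(out) <- "pipeline_result"
  make_report(out, file.path(config$outdir, "report.txt"))
  invisible(out)
}

#' Consolidated text report of a pipeline run
#'
#' Joins the stage outputs into one human-readable report with
#' cross-stage consistency checks (e.g. samples in the load tables must be
#' a subset of the cohort table). Numbers are taken from the stage outputs
#' verbatim, never recomputed.
#'
#' @param result a `pipeline_result`
#' @param path optional output path; when `NULL` the lines are returned
#' @return character vector of report lines, invisibly when written
#' @export
make_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  stages <- setdiff(names(result), c("config", "manifest"))
  if (length(stages) == 0) stop("no stage outputs to report")
  lines <- c("popgenerode pipeline report",
             paste0("config hash: ", result$manifest$config_hash),
             paste0("seed: ", result$manifest$seed), "")
  if (!is.null(result$simulate)) {
    s <- result$simulate$replicate$summaries
    lines <- c(lines, "[simulate]",
               sprintf("  heterozygosity: %s",
                       paste(sprintf("%s=%.4g", names(s$het), s$het),
                             collapse = ", ")),
               sprintf("  het loss: %.2f%%", s$het_loss_pct), "")
  }
  if (!is.null(result$filter)) {
    r <- result$filter$report
    lines <- c(lines, "[filter]",
               sprintf("  %s: removed %d sites, recoded %d, missing %d",
                       r$rule, r$sites_removed, r$genotypes_recoded,
                       r$genotypes_missing), "")
  }
  cohort_samples <- if (!is.null(result$simulate)) {
    result$simulate$merged$samples$sample_id
  } else {
    NULL
  }
  if (!is.null(result$diversity)) {
    h <- result$diversity$het
    if (!is.null(cohort_samples) &&
        !all(h$sample_id %in% cohort_samples)) {
      stop("diversity output contains unknown sample: ",
           setdiff(h$sample_id, cohort_samples)[1])
    }
    agg <- stats::aggregate(het ~ cohort, data = h, FUN = mean)
    lines <- c(lines, "[diversity]",
               sprintf("  mean het %s: %.4g", agg$cohort, agg$het),
               sprintf("  ROH segments: %d", nrow(result$diversity$segments)),
               sprintf("  mean F_ROH: %.4g", mean(result$diversity$froh$froh)),
               "")
  } else if (!is.null(result$simulate)) {
    lines <- c(lines, "[diversity] not run", "")
  }
  if (!is.null(result$load)) {
    lp <- result$load$per_sample
    if (!is.null(cohort_samples) && !all(lp$sample_id %in% cohort_samples)) {
      stop("load output contains unknown sample: ",
           setdiff(lp$sample_id, cohort_samples)[1])
    }
    lines <- c(lines, "[load]",
               sprintf("  polarized sites: %d (dropped %d)",
                       nrow(result$load$polarized$sites),
                       result$load$polarized$dropped))
    if (!is.null(result$load$rxy)) {
      lines <- c(lines, sprintf("  R_his/con (%s): %.3f [%.3f, %.3f]",
                                result$load$rxy$category,
                                result$load$rxy$estimate,
                                result$load$rxy$ci_low,
                                result$load$rxy$ci_high))
    }
    lines <- c(lines, "")
  }
  if (!is.null(result$demography)) {
    d <- result$demography
    lines <- c(lines, "[demography]",
               sprintf("  generation time: %.2f years", d$gen_time),
               sprintf("  catch correlation: r^2 = %.3f (p = %.3g, n = %d)",
                       d$correlation$r_squared, d$correlation$p_value,
                       d$correlation$n), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
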