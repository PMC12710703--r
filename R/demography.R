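#' Read per-run output tables of an LD-based Ne estimator
#'
#' Each run file is a whitespace-delimited table whose first two numeric
#' columns are generation and Ne (header and comment lines are skipped
#' automatically).
#'
#' @param paths character vector of file paths (one per independent run)
#' @return long data.frame with `run`, `generation`, `ne`
#' @export
read_ne_runs <- function(paths) {
  stopifnot(length(paths) >= 1)
  out <- lapply(seq_along(paths), function(k) {
    lines <- readLines(paths[k])
    fields <- strsplit(trimws(lines), "[ \t]+")
    numeric_row <- vapply(fields, function(f) {
      length(f) >= 2 && !anyNA(suppressWarnings(as.numeric(f[1:2])))
    }, logical(1))
    if (!any(numeric_row)) stop("no numeric rows in ", paths[k])
    m <- do.call(rbind, lapply(fields[numeric_row],
                               function(f) as.numeric(f[1:2])))
    data.frame(run = k, generation = m[, 1], ne = m[, 2])
  })
  do.call(rbind, out)
}

#' Summarize an Ne trajectory across independent estimator runs
#'
#' Per generation: mean, median and percentile 95% CI (2.5th/97.5th) of Ne
#' across runs.
#'
#' @param runs long data.frame with `run`, `generation`, `ne` (as returned
#'   by [read_ne_runs()]); an optional `theta` column (pairwise SNP
#'   comparisons per generation bin) is averaged across runs
#' @return data.frame of class `ne_trajectory` with `generation`,
#'   `ne_mean`, `ne_median`, `ci_low`, `ci_high`, `n_runs` (and `theta`
#'   when supplied)
#' @export
summarize_trajectory <- function(runs) {
  stopifnot(is.data.frame(runs),
            all(c("run", "generation", "ne") %in% names(runs)))
  if (length(unique(runs$run)) < 2) stop("at least 2 runs are required")
  if (any(runs$ne <= 0)) stop("Ne values must be positive")
  gens <- sort(unique(runs$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    x <- runs$ne[runs$generation == g]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(generation = g, ne_mean = mean(x), ne_median = stats::median(x),
               ci_low = q[1], ci_high = q[2], n_runs = length(x))
  }))
  if (!is.null(runs$theta)) {
    out$theta <- vapply(gens, function(g) {
      mean(runs$theta[runs$generation == g], na.rm = TRUE)
    }, numeric(1))
  }
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Convert an Ne trajectory to census size
#'
#' Multiplies all Ne summary columns by the Ne:Nc ratio (1:4 by default,
#' as used for baleen whales).
#'
#' @param traj a trajectory from [summarize_trajectory()]
#' @param ratio census individuals per effective individual (> 0)
#' @return the trajectory with added `nc_mean`, `nc_median`, `nc_ci_low`,
#'   `nc_ci_high`
#' @export
ne_to_nc <- function(traj, ratio = 4) {
  stopifnot(ratio > 0)
  traj$nc_mean <- traj$ne_mean * ratio
  traj$nc_median <- traj$ne_median * ratio
  traj$nc_ci_low <- traj$ci_low * ratio
  traj$nc_ci_high <- traj$ci_high * ratio
  traj
}

#' Calibrate generation time from a dated demographic event
#'
#' Anchors a known calendar-year event (e.g. the onset of mechanized
#' whaling) to its estimated generation offset in the trajectory:
#' `gen_time = (sampling_year - anchor_year) / anchor_generation`.
#'
#' @param anchor_year calendar year of the anchoring event
#' @param anchor_generation generations before sampling at which the event
#'   appears in the trajectory (> 0)
#' @param sampling_year calendar year of the contemporary sampling
#' @return years per generation
#' @export
calibrate_generation_time <- function(anchor_year, anchor_generation,
                                      sampling_year) {
  stopifnot(sampling_year > anchor_year, anchor_generation > 0)
  (sampling_year - anchor_year) / anchor_generation
}

#' Date a generation-indexed trajectory in calendar years
#'
#' `year(g) = sampling_year - g * gen_time`; the anchor round-trips
#' exactly: `year(anchor_generation) == anchor_year`.
#'
#' @param traj a trajectory with a `generation` column
#' @param gen_time years per generation
#' @param sampling_year calendar year of generation 0
#' @return the trajectory with an added `year` column
#' @export
map_generations_to_years <- function(traj, gen_time, sampling_year) {
  stopifnot(gen_time > 0)
  traj$year <- sampling_year - traj$generation * gen_time
  traj
}

#' G robustness statistic for LD-based Ne estimates
#'
#' `G = n * theta / Ne`, where `n` is the sample size used in the LD
#' estimation and `theta` the number of pairwise SNP comparisons. Low
#' values (around 50) indicate unreliable estimates; estimates at or below
#' `threshold` are flagged.
#'
#' @param n sample size (diploids in the LD estimation)
#' @param theta pairwise SNP comparisons (total, or per generation bin)
#' @param ne effective population size estimate(s)
#' @param threshold flag estimates with `G <= threshold` (default 100)
#' @return data.frame with `g` and `low_confidence`
#' @export
g_statistic <- function(n, theta, ne, threshold = 100) {
  stopifnot(all(n > 0), all(theta > 0), all(ne > 0))
  g <- n * theta / ne
  data.frame(g = g, low_confidence = g <= threshold)
}

#' Correlation between an Ne trajectory and cumulative catches
#'
#' Dates the trajectory (years per generation from the calibration), sums
#' the catch record cumulatively up to each generation's calendar year, and
#' reports the Pearson correlation between the generational Ne means and the
#' cumulative catches, with the t-based two-sided p-value.
#'
#' @param traj trajectory with `generation` and `ne_mean` (or `nc_mean`)
#' @param catches data.frame with `year` and `catches`
#' @param gen_time years per generation
#' @param sampling_year calendar year of generation 0
#' @param value which trajectory column to correlate (default `ne_mean`)
#' @return list with `r`, `r_squared`, `p_value`, `n` and the dated,
#'   binned data in `data`
#' @export
catch_correlation <- function(traj, catches, gen_time, sampling_year,
                              value = "ne_mean") {
  stopifnot(value %in% names(traj),
            all(c("year", "catches") %in% names(catches)))
  dated <- map_generations_to_years(traj, gen_time, sampling_year)
  inside <- dated$year >= min(catches$year) & dated$year <= max(catches$year)
  dated <- dated[inside, , drop = FALSE]
  if (nrow(dated) < 3) {
    stop("fewer than 3 generations overlap the catch record")
  }
  cum <- vapply(dated$year, function(y) {
    sum(catches$catches[catches$year <= y])
  }, numeric(1))
  v <- dated[[value]]
  if (stats::sd(v) == 0 || stats::sd(cum) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  ct <- stats::cor.test(v, cum, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = nrow(dated),
       data = data.frame(generation = dated$generation, year = dated$year,
                         value = v, cumulative_catches = cum))
}
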