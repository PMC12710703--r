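# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive quantities from first principles (enumeration, closed forms,
# textbook formulas) without calling the implementation under test.

# joint log-probability of a given ROH state path (1 = non-autozygous,
# 2 = autozygous) under the two-state model definition
roh_path_logprob <- function(path, obs, pos, p, config) {
  n <- length(obs)
  phet <- pmin(pmax(2 * p * (1 - p), config$error_rate),
               1 - config$error_rate)
  lp <- log(0.5)
  for (i in seq_len(n)) {
    ph <- if (path[i] == 2) config$error_rate else phet[i]
    lp <- lp + (if (obs[i] == 1) log(ph) else log(1 - ph))
    if (i > 1) {
      d <- pos[i] - pos[i - 1]
      p_in <- 1 - exp(-config$az_entry * d)
      p_out <- 1 - exp(-config$az_exit * d)
      m <- matrix(c(1 - p_in, p_in, p_out, 1 - p_out), 2, byrow = TRUE)
      lp <- lp + log(m[path[i - 1], path[i]])
    }
  }
  lp
}

# exhaustive search over all 2^n state paths
enumerate_best_path <- function(obs, pos, p, config) {
  n <- length(obs)
  best <- -Inf
  best_path <- NULL
  for (mask in 0:(2^n - 1)) {
    path <- as.integer(intToBits(mask))[1:n] + 1L
    lp <- roh_path_logprob(path, obs, pos, p, config)
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- path
    }
  }
  list(path = best_path, logp = best)
}

# exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments of the pooled sample
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  m <- length(pooled) - n
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  dev <- abs(us - n * m / 2)
  mean(dev >= abs(u_obs - n * m / 2) - 1e-9)
}

# textbook Pearson correlation via the covariance formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
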