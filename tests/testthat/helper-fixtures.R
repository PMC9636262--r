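# Fixture builders shared across the suite.

# long visit table with exact linear trajectories (optionally noisy)
make_linear_visits <- function(slopes, intercepts = rep(1.2, length(slopes)),
                               times = 0:2, region_id = 1L, sd_noise = 0) {
  ns <- length(slopes)
  ids <- sprintf("S%03d", seq_len(ns))
  do.call(rbind, lapply(seq_len(ns), function(i)
    data.frame(subject_id = ids[i], time_years = times, region_id = region_id,
               suvr = intercepts[i] + slopes[i] * times +
                 rnorm(length(times), 0, sd_noise))))
}

# small, well-separated two-component mixture sample
make_gmm_fixture <- function(n = 2000, seed = 42) {
  set.seed(seed)
  comp <- rbinom(n, 1, 0.5)
  x <- ifelse(comp == 1, rnorm(n, 2.5, 0.2), rnorm(n, 1.2, 0.1))
  list(x = x, means = c(1.2, 2.5), sds = c(0.1, 0.2), weights = c(0.5, 0.5))
}

# closed-form posterior of the high component for known parameters
oracle_posterior <- function(x, means, sds, weights) {
  d1 <- weights[1] * dnorm(x, means[1], sds[1])
  d2 <- weights[2] * dnorm(x, means[2], sds[2])
  d2 / (d1 + d2)
}

# brute-force Floyd-Warshall all-pairs shortest paths on edge lengths
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- ifelse(len > 0, len, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

# brute-force Benjamini-Hochberg step-up adjusted p-values
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

small_config <- function(..., seed = 11) {
  cohort_config(n_per_group = c(cn_neg = 16, cu_pos = 12, mci_pos = 12, ad = 10),
                n_regions = 80, n_modules = 4, seed = seed, ...)
}
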