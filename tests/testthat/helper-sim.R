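# Shared fixtures: a compact genome keeps unit tests fast; the default
# 20 Mb geometry is reserved for the pipeline-level acceptance checks.

tiny_lengths <- c(X = 1e6, `2L` = 1.2e6, `2R` = 1.2e6, `3R` = 1.4e6,
                  Y = 1e5)

tiny_cfg <- function(seed = 42, ...) {
  sim_config(seed = seed, chrom_lengths = tiny_lengths, ...)
}

# memoised default tiny model so multiple tests can share it
.tiny_env <- new.env()
tiny_model <- function() {
  if (is.null(.tiny_env$model)) {
    .tiny_env$model <- simulate_genome(tiny_cfg())
  }
  .tiny_env$model
}

# Brute-force CBS arc maximization: the independent O(n^2) oracle.
brute_max_arc <- function(x) {
  n <- length(x)
  S <- c(0, cumsum(x))
  best <- -1; bi <- 0; bj <- 1
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      d <- (S[j + 1] - S[i + 1]) / k - (S[n + 1] - S[j + 1] + S[i + 1]) / (n - k)
      t <- abs(d) / sqrt(1 / k + 1 / (n - k))
      if (t > best) { best <- t; bi <- i; bj <- j }
    }
  }
  list(stat = best, i = bi, j = bj)
}

# Enumeration oracle for the two-sided rank-sum p-value.
brute_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  Us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  lo <- min(U_obs, n1 * n2 - U_obs)
  if (abs(U_obs - n1 * n2 / 2) < 1e-9) return(1)
  min(1, mean(Us <= lo + 1e-9) + mean(Us >= n1 * n2 - lo - 1e-9))
}
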