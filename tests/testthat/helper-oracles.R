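# Independent brute-force oracles the implementation is checked against.

# Exhaustive Viterbi: score every possible state path and return the best.
# Shares nothing with the package's dynamic program. Path matrices are
# cached per (n, k) because enumeration is the expensive part.
.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(n, k) {
  key <- paste(n, k, sep = "_")
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n),
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(paths) <- NULL
  .path_cache[[key]] <- paths
  paths
}

brute_force_viterbi <- function(values, means, sd, p_self, log_prior) {
  n <- length(values)
  k <- length(means)
  paths <- enumerate_paths(n, k)
  lp <- log(p_self)
  lq <- log((1 - p_self) / (k - 1))
  em <- -0.5 * ((matrix(values, n, k) -
                   matrix(means, n, k, byrow = TRUE)) / sd)^2
  score <- log_prior[paths[, 1]] + em[cbind(1L, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      score <- score + em[cbind(t, paths[, t])] +
        ifelse(paths[, t] == paths[, t - 1], lp, lq)
    }
  }
  paths[which.max(score), ]
}

# Mean of a normal truncated to [a, b].
truncnorm_mean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  mean + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

# Probability mass of a truncated normal inside [lo, hi].
truncnorm_mass <- function(mean, sd, a, b, lo, hi) {
  (pnorm(hi, mean, sd) - pnorm(lo, mean, sd)) /
    (pnorm(b, mean, sd) - pnorm(a, mean, sd))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (small n only).
enumerate_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  obs <- u_of(seq_len(m))
  combos <- utils::combn(n, m)
  us <- apply(combos, 2, u_of)
  mu <- m * (n - m) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}
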