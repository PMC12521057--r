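# Independent statistical oracles, implemented from first principles so the
# package's routines are checked against a different route.

# Textbook Friedman chi-square for untied data:
# Q = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1), Rj = column rank sums.
friedman_oracle <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign patterns.
wilcoxon_exact_oracle <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(grid %*% rk)
  min(1, 2 * min(mean(w_null >= w_obs), mean(w_null <= w_obs)))
}

# Two-sided normal-approximation signed-rank p with continuity correction
# (untied differences).
wilcoxon_normal_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  z <- W - n * (n + 1) / 4
  z <- (z - sign(z) * 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
}
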