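# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package code they check.

toy_clock <- function(name = "toy", intercept = 10,
                      w = c(cg1 = 2, cg2 = -1), transform = "identity",
                      ...) {
  clock_model(name, intercept, w, transform = transform, ...)
}

# a small default cohort shared by several tests (simulated once per run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_samples = 200, seed = 42))
    }
    cache
  }
})

# Independent OLS oracle: normal equations, explicit (X'X)^-1
ols_t_oracle <- function(y, x, covars) {
  X <- cbind(covars, x)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * xtx_inv[ncol(X), ncol(X)])
  tt <- b[ncol(X)] / se
  c(t = tt, p = 2 * pt(-abs(tt), df))
}

# Independent ICC(2,k) oracle through aov() mean squares
icc2k_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  long <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  bms <- ms[1]; jms <- ms[2]; ems <- ms[3]
  (bms - ems) / (bms + (jms - ems) / n)
}

# Brute-force point-in-interval annotation (1-based CpG points against
# 1-based closed intervals)
annotate_oracle <- function(pos, chrom, iv_chrom, iv_start, iv_end) {
  vapply(seq_along(pos), function(i) {
    any(chrom[i] == iv_chrom & pos[i] >= iv_start & pos[i] <= iv_end)
  }, logical(1))
}

# Two-sided Fisher p by hypergeometric enumeration
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
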