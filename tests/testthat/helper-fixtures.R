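# Shared fixtures and brute-force oracles.

# Reference constants used throughout: f = 1e4 fragments/genome, 5500-genome
# fully converted reference.
default_consts <- sim_constants()

# A small reproducible two-group dataset on the quantity scale.
make_dataset <- function(seed = 42, scenario = "a.i", n1 = 100, n2 = 100) {
  set.seed(seed)
  simulate_dataset(get_scenario(scenario, n1, n2))
}

# Brute-force window variances: literal translation of the centred-window
# rule with edge pooling, using var() per window.
brute_window_variances <- function(pmr, surrogate, w) {
  n <- length(pmr)
  ord <- order(surrogate)
  y <- pmr[ord]
  m <- (w - 1) / 2
  v <- sapply(seq_len(n), function(r) {
    lo <- min(max(r - m, 1), n - w + 1)
    stats::var(y[lo:(lo + w - 1)])
  })
  out <- numeric(n)
  out[ord] <- v
  out
}

# Brute-force quantile-bin variances, nearly equal contiguous bins.
brute_quantile_variances <- function(pmr, surrogate, k) {
  n <- length(pmr)
  ord <- order(surrogate)
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  blocks <- rep(seq_len(k), sizes)
  v <- tapply(pmr[ord], blocks, stats::var)
  out <- numeric(n)
  out[ord] <- v[blocks]
  out
}

# Closed-form pooled two-sample t-test (equal variances), independent of the
# package's regression code path.
pooled_t_test <- function(y, g2) {
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- mean(y[!g2]); m2 <- mean(y[g2])
  sp2 <- ((n1 - 1) * stats::var(y[!g2]) + (n2 - 1) * stats::var(y[g2])) /
    (n1 + n2 - 2)
  tval <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(estimate = m2 - m1,
       p_value = 2 * stats::pt(-abs(tval), n1 + n2 - 2))
}
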