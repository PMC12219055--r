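# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Exhaustive two-sample permutation p-value (two-sided, |difference of
# means|) by enumerating all C(n, na) label assignments.
perm_two_exhaustive <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(n, na)
  stats <- apply(splits, 2, function(idx) {
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Exhaustive one-sample sign-flip p-value (two-sided) over all 2^n patterns.
perm_one_exhaustive <- function(diffs) {
  n <- length(diffs)
  obs <- abs(mean(diffs))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- abs(signs %*% diffs) / n
  mean(stats >= obs - 1e-12)
}

# Naive Benjamini-Hochberg step-up, written from the definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1):1) {
    if (n == 1) break
    ranked[i] <- min(ranked[i], ranked[i + 1])
  }
  out <- numeric(n)
  out[ord] <- pmin(ranked, 1)
  out
}

# Independent equal-variance SDT computation (liberal-negative criterion).
sdt_oracle <- function(n_hit, n_miss, n_fa, n_cr) {
  hr <- n_hit / (n_hit + n_miss)
  fa <- n_fa / (n_fa + n_cr)
  if (hr %in% c(0, 1)) hr <- (n_hit + 0.5) / (n_hit + n_miss + 1)
  if (fa %in% c(0, 1)) fa <- (n_fa + 0.5) / (n_fa + n_cr + 1)
  c(d_prime = qnorm(hr) - qnorm(fa),
    criterion = -(qnorm(hr) + qnorm(fa)) / 2)
}

# Two-sided minimum-likelihood binomial p-value from the definition.
binom_oracle <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}
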