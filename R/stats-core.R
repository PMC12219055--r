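#' Two-sample permutation test for a difference in means
#'
#' Pools both samples, redraws group labels `n_iterations` times, and compares
#' the permuted difference of means to the observed difference. The p-value
#' uses the add-one convention `p = (1 + n_extreme) / (1 + n_iterations)`, so
#' it is never exactly zero and is valid at any iteration count.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param n_iterations Number of label permutations (default 10,000).
#' @param seed Integer seed; the test is bit-reproducible given the seed.
#' @param sided `"two"` (statistic `|mean(a) - mean(b)|`), `"greater"` or
#'   `"less"` (signed statistic).
#' @return One-row tibble with `statistic` (observed `mean(a) - mean(b)`),
#'   `p_value`, `n_iterations`, `seed`, `sided`.
#' @examples
#' permutation_test_two_sample(rnorm(20), rnorm(20, 1), n_iterations = 999,
#'                             seed = 1)
#' @export
permutation_test_two_sample <- function(a, b, n_iterations = 10000, seed = 1,
                                        sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  check_numeric_vector(a, "a")
  check_numeric_vector(b, "b")
  check_number(n_iterations, "n_iterations", min = 1)
  pool <- c(a, b)
  na <- length(a)
  n <- length(pool)
  total <- sum(pool)
  obs <- mean(a) - mean(b)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      sa <- sum(pool[sample.int(n, na)])
      sa / na - (total - sa) / (n - na)
    }, numeric(1))
  })
  tol <- 1e-12 * max(1, abs(obs))
  n_extreme <- switch(sided,
    two = sum(abs(perm) >= abs(obs) - tol),
    greater = sum(perm >= obs - tol),
    less = sum(perm <= obs + tol)
  )
  tibble::tibble(
    statistic = obs,
    p_value = (1 + n_extreme) / (1 + n_iterations),
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed),
    sided = sided
  )
}

#' One-sample (sign-flip) permutation test for paired differences
#'
#' Tests whether the mean of paired differences departs from zero by randomly
#' flipping the sign of each element.
#'
#' @param diffs Numeric vector of paired differences (non-empty).
#' @inheritParams permutation_test_two_sample
#' @return One-row tibble as in [permutation_test_two_sample()], with
#'   `statistic = mean(diffs)`.
#' @export
permutation_test_one_sample <- function(diffs, n_iterations = 10000, seed = 1,
                                        sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  check_numeric_vector(diffs, "diffs")
  check_number(n_iterations, "n_iterations", min = 1)
  n <- length(diffs)
  obs <- mean(diffs)
  perm <- withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_iterations, replace = TRUE),
                    nrow = n_iterations)
    as.numeric(signs %*% diffs) / n
  })
  tol <- 1e-12 * max(1, abs(obs))
  n_extreme <- switch(sided,
    two = sum(abs(perm) >= abs(obs) - tol),
    greater = sum(perm >= obs - tol),
    less = sum(perm <= obs + tol)
  )
  tibble::tibble(
    statistic = obs,
    p_value = (1 + n_extreme) / (1 + n_iterations),
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed),
    sided = sided
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment preserving input order; each adjusted value is at
#' least the raw value and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same order and length.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must all lie in [0, 1].", class = "wa_invalid_input")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided binomial exact test
#'
#' Exact test for a deviation of `k` successes out of `n` from success
#' probability `p0`, using the minimum-likelihood two-sided method (the
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one).
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return One-row tibble with `statistic` (`k - n * p0`, the signed deviation
#'   from expectation) and `p_value`.
#' @examples
#' binomial_exact_test(107, 173, 0.5)
#' @export
binomial_exact_test <- function(k, n, p0 = 0.5) {
  check_number(n, "n", min = 0)
  check_number(k, "k", min = 0)
  check_number(p0, "p0")
  if (k > n) abort("`k` must not exceed `n`.", class = "wa_invalid_input")
  if (p0 <= 0 || p0 >= 1) {
    abort("`p0` must lie strictly in (0, 1).", class = "wa_invalid_input")
  }
  res <- stats::binom.test(k, n, p = p0, alternative = "two.sided")
  tibble::tibble(statistic = k - n * p0, p_value = unname(res$p.value))
}
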