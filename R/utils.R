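# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage counter.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, counter) {
  master <- as.numeric(master)
  counter <- as.numeric(counter)
  as.integer((master * 69069 + counter * 10007 + 1) %% 2147483647)
}

check_number <- function(x, arg, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", arg, min, max),
      class = "wa_invalid_input"
    )
  }
  invisible(x)
}

check_numeric_vector <- function(x, arg, allow_empty = FALSE) {
  if (!is.numeric(x) || (!allow_empty && length(x) == 0L) || anyNA(x)) {
    abort(
      sprintf("`%s` must be a non-empty numeric vector without NA.", arg),
      class = "wa_invalid_input"
    )
  }
  invisible(x)
}

# Log-linear correction for extreme rates: (k + 0.5) / (n + 1), applied only
# when the raw rate is exactly 0 or 1.
loglinear_rate <- function(k, n) {
  rate <- k / n
  extreme <- rate == 0 | rate == 1
  rate[extreme] <- (k[extreme] + 0.5) / (n[extreme] + 1)
  list(rate = rate, corrected = extreme)
}
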