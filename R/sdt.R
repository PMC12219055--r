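#' Signal-detection metrics from a 2x2 outcome table
#'
#' Computes sensitivity and criterion from hit and false-alarm counts under
#' the equal-variance Gaussian model: `d' = Z(HR) - Z(FA)` with `Z` the
#' standard-normal quantile function. The criterion is reported with the
#' liberal-negative sign convention, `c = -(Z(HR) + Z(FA)) / 2`, so that
#' liberal responding (high hit and false-alarm rates) yields negative values.
#'
#' Rates of exactly 0 or 1 make `Z` infinite; with
#' `correction = "log-linear"` such rates are replaced by
#' `(k + 0.5) / (n + 1)` (only when extreme). With `correction = "none"` an
#' extreme rate is an error.
#'
#' @param n_hit,n_miss,n_fa,n_cr Outcome counts (vectorised).
#' @param correction `"log-linear"` (default) or `"none"`.
#' @return Tibble with `hit_rate`, `fa_rate`, `d_prime`, `criterion`, `n_go`,
#'   `n_nogo`, `correction_applied`.
#' @examples
#' compute_sdt(84, 16, 50, 50)
#' @export
compute_sdt <- function(n_hit, n_miss, n_fa, n_cr,
                        correction = c("log-linear", "none")) {
  correction <- match.arg(correction)
  n_go <- n_hit + n_miss
  n_nogo <- n_fa + n_cr
  if (any(n_go == 0) || any(n_nogo == 0)) {
    abort("Go and NoGo trial counts must both be positive.",
          class = "wa_undefined_metric")
  }
  hr <- n_hit / n_go
  fa <- n_fa / n_nogo
  corrected <- rep(FALSE, length(hr))
  if (correction == "log-linear") {
    h <- loglinear_rate(n_hit, n_go)
    f <- loglinear_rate(n_fa, n_nogo)
    hr <- h$rate
    fa <- f$rate
    corrected <- h$corrected | f$corrected
  } else if (any(hr %in% c(0, 1)) || any(fa %in% c(0, 1))) {
    abort("Extreme rate (0 or 1) with `correction = \"none\"`.",
          class = "wa_undefined_metric")
  }
  zh <- qnorm(hr)
  zf <- qnorm(fa)
  tibble::tibble(
    hit_rate = hr,
    fa_rate = fa,
    d_prime = zh - zf,
    criterion = -(zh + zf) / 2,
    n_go = as.integer(n_go),
    n_nogo = as.integer(n_nogo),
    correction_applied = corrected
  )
}

# Sliding-window d' for each non-aborted trial; the window is centred,
# sliding to a trailing/leading alignment at the session edges so it always
# spans exactly `window` trials.
sliding_dprime <- function(trials, window = 50) {
  active <- trials[!trials$aborted, ]
  n <- nrow(active)
  if (n < window) {
    abort(sprintf("Need at least %d non-aborted trials.", window),
          class = "wa_invalid_input")
  }
  half <- window %/% 2
  chit <- c(0, cumsum(active$outcome == "Hit"))
  cgo <- c(0, cumsum(active$kind == "Go"))
  cfa <- c(0, cumsum(active$outcome == "FA"))
  start <- pmin(pmax(1L, seq_len(n) - half), n - window + 1L)
  end <- start + window - 1L
  n_go <- cgo[end + 1L] - cgo[start]
  n_nogo <- window - n_go
  n_hit <- chit[end + 1L] - chit[start]
  n_fa <- cfa[end + 1L] - cfa[start]
  hr <- loglinear_rate(n_hit, n_go)$rate
  fa <- loglinear_rate(n_fa, n_nogo)$rate
  d <- qnorm(hr) - qnorm(fa)
  d[n_go == 0 | n_nogo == 0] <- NA_real_
  tibble::tibble(trial_index = active$trial_index, sliding_d = d)
}

#' Task-engagement window of a session
#'
#' Applies a sliding-window d' cutoff to the start and end of a session to
#' exclude low-motivation epochs: the analysis window runs from the first to
#' the last trial whose sliding d' (over `window` non-aborted trials, centred
#' with edge clamping) meets `cutoff`.
#'
#' @param session A session tibble (see [simulate_session()] /
#'   [read_session()]).
#' @param window Sliding-window width in non-aborted trials (default 50).
#' @param cutoff Minimum sliding d' (default 0.5; extracellular-recording
#'   analyses conventionally use 1.2).
#' @return One-row tibble with `first_index` and `last_index` (trial indices).
#'   Errors with class `wa_empty_window` if no trial qualifies.
#' @seealso [trim_to_engagement()]
#' @export
engagement_window <- function(session, window = 50, cutoff = 0.5) {
  sd_tbl <- sliding_dprime(session, window = window)
  ok <- which(!is.na(sd_tbl$sliding_d) & sd_tbl$sliding_d >= cutoff)
  if (length(ok) == 0L) {
    abort(
      sprintf(
        "No %d-trial window reaches d' >= %.2f (max sliding d' = %.2f).",
        window, cutoff, max(sd_tbl$sliding_d, na.rm = TRUE)
      ),
      class = "wa_empty_window"
    )
  }
  tibble::tibble(
    first_index = sd_tbl$trial_index[min(ok)],
    last_index = sd_tbl$trial_index[max(ok)]
  )
}

#' @rdname engagement_window
#' @return `trim_to_engagement()` returns the session restricted to the
#'   engagement window (all trials between the two indices, aborted included
#'   as time markers).
#' @export
trim_to_engagement <- function(session, window = 50, cutoff = 0.5) {
  w <- engagement_window(session, window = window, cutoff = cutoff)
  dplyr::filter(session, .data$trial_index >= w$first_index,
                .data$trial_index <= w$last_index)
}
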