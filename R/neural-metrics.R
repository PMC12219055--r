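#' Fractional fluorescence change (dF/F)
#'
#' Converts a raw fluorescence series to dF/F, optionally after neuropil
#' subtraction (`corrected = raw - scale * neuropil`, used for pyramidal
#' cells; VIP cells skip subtraction). The baseline `F0` is the 20th
#' percentile of the (corrected) series over the whole recording.
#'
#' @param raw Raw somatic fluorescence series.
#' @param neuropil Optional neuropil series of the same length.
#' @param neuropil_scale Neuropil subtraction factor (default 0.3).
#' @param f0_quantile Baseline percentile (default 0.2).
#' @return Tibble with `frame`, `f_corrected` and `dff`; baseline in
#'   attribute `f0`.
#' @export
dff_from_fluorescence <- function(raw, neuropil = NULL, neuropil_scale = 0.3,
                                  f0_quantile = 0.2) {
  check_numeric_vector(raw, "raw")
  corrected <- raw
  if (!is.null(neuropil)) {
    check_numeric_vector(neuropil, "neuropil")
    if (length(neuropil) != length(raw)) {
      abort("`neuropil` must match `raw` in length.",
            class = "wa_invalid_input")
    }
    corrected <- raw - neuropil_scale * neuropil
  }
  f0 <- unname(quantile(corrected, f0_quantile))
  if (f0 <= 0) {
    abort(sprintf("Degenerate baseline: F0 = %.3g <= 0.", f0),
          class = "wa_degenerate_baseline")
  }
  out <- tibble::tibble(
    frame = seq_along(raw),
    f_corrected = corrected,
    dff = (corrected - f0) / f0
  )
  attr(out, "f0") <- f0
  out
}

#' Evoked response from peri-stimulus traces
#'
#' Evoked magnitude per trial: mean of the post-stimulus window minus mean of
#' the pre-stimulus baseline window (by default 7 frames post vs 2 frames
#' baseline at 7.5 Hz). With `normalize = "zscore-baseline"` responses are
#' divided by the baseline-epoch standard deviation pooled across trials.
#'
#' @param traces Trials x frames matrix (or a single trace vector).
#' @param onset_frame Frame index of stimulus onset (first post-stimulus
#'   frame).
#' @param post_frames,baseline_frames Window lengths in frames.
#' @param normalize `"raw"` or `"zscore-baseline"`.
#' @return Numeric vector of evoked magnitudes, one per trial.
#' @export
evoked_response <- function(traces, onset_frame, post_frames = 7,
                            baseline_frames = 2,
                            normalize = c("raw", "zscore-baseline")) {
  normalize <- match.arg(normalize)
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  nf <- ncol(traces)
  post_idx <- onset_frame:(onset_frame + post_frames - 1)
  base_idx <- (onset_frame - baseline_frames):(onset_frame - 1)
  if (min(base_idx) < 1 || max(post_idx) > nf) {
    abort("Analysis windows fall outside the trace.",
          class = "wa_invalid_window")
  }
  ev <- rowMeans(traces[, post_idx, drop = FALSE]) -
    rowMeans(traces[, base_idx, drop = FALSE])
  if (normalize == "zscore-baseline") {
    s <- sd(as.vector(traces[, base_idx, drop = FALSE]))
    if (!is.finite(s) || s == 0) {
      abort("Zero pooled baseline SD; cannot z-score.",
            class = "wa_degenerate_baseline")
    }
    ev <- ev / s
  }
  ev
}

#' Evoked firing rate from spike times
#'
#' Rate in a post-stimulus window minus the baseline-window rate, per trial.
#'
#' @param spike_times List of per-trial spike-time vectors (s, relative to
#'   stimulus onset).
#' @param post_window Post-stimulus window `c(lo, hi)` in seconds (default
#'   0-0.5 s).
#' @param baseline_window Baseline window in seconds.
#' @return Numeric vector of evoked rates (Hz), one per trial.
#' @export
evoked_rate <- function(spike_times, post_window = c(0, 0.5),
                        baseline_window = c(-0.5, 0)) {
  vapply(spike_times, function(st) {
    sum(st >= post_window[1] & st < post_window[2]) / diff(post_window) -
      sum(st >= baseline_window[1] & st < baseline_window[2]) /
        diff(baseline_window)
  }, numeric(1))
}

#' Whisker-responsiveness permutation test
#'
#' Tests, per whisker, whether Go-trial evoked responses exceed NoGo-trial
#' responses by a two-sample permutation test on the difference of means
#' (one-sided), corrects the per-whisker p-values by FDR, and calls the cell
#' responsive if at least one whisker has adjusted p below `alpha` with a
#' positive mean difference (cells without any positive response are
#' non-responsive).
#'
#' @param go_responses Named list (or long tibble with columns `whisker`,
#'   `evoked`) of Go evoked responses per whisker.
#' @param nogo_responses NoGo evoked responses.
#' @param n_iterations Permutation iterations (default 10,000).
#' @param seed Integer seed (whisker `w` uses a seed derived from it).
#' @param alpha Significance level (default 0.05).
#' @param min_trials Minimum Go trials per whisker to test that whisker.
#' @return Tibble with one row per tested whisker (`whisker`, `mean_diff`,
#'   `p_value`, `p_adjusted`, `significant`); overall call in attribute
#'   `responsive`.
#' @export
responsiveness_test <- function(go_responses, nogo_responses,
                                n_iterations = 10000, seed = 1,
                                alpha = 0.05, min_trials = 3) {
  if (is.data.frame(go_responses)) {
    go_responses <- split(go_responses$evoked, go_responses$whisker)
  }
  check_numeric_vector(nogo_responses, "nogo_responses")
  keep <- vapply(go_responses, length, integer(1)) >= min_trials
  if (!any(keep)) {
    abort("No whisker has enough Go trials to test.",
          class = "wa_insufficient_data")
  }
  go_responses <- go_responses[keep]
  rows <- purrr::imap(go_responses, function(vals, w) {
    res <- permutation_test_two_sample(
      vals, nogo_responses, n_iterations = n_iterations,
      seed = derive_seed(seed, match(w, names(go_responses))),
      sided = "greater"
    )
    tibble::tibble(whisker = w, mean_diff = res$statistic,
                   p_value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- fdr_adjust(out$p_value)
  out$significant <- out$p_adjusted < alpha & out$mean_diff > 0
  attr(out, "responsive") <- any(out$significant)
  out
}

#' Per-condition linear baseline detrending
#'
#' Removes slow pre-stimulus baseline trends (e.g. declining post-reward VIP
#' activity): the median trace over trials is taken in a pre-stimulus window,
#' a line is fit to it, and the line - extrapolated over the full
#' peri-stimulus extent - is subtracted from every individual trial. When a
#' grouping is supplied the procedure runs separately per history condition,
#' since pre-stimulus slopes differ between conditions.
#'
#' @param traces Trials x frames matrix.
#' @param times Frame times in seconds relative to stimulus onset.
#' @param condition Optional per-trial condition labels.
#' @param baseline_window Length of the pre-stimulus fitting window
#'   (seconds; default 1.07 s, i.e. `times` in `[-1.07, 0)`).
#' @param min_trials Conditions with fewer trials are skipped (returned
#'   untouched) with a message.
#' @return Detrended matrix of the same shape.
#' @export
detrend_baseline <- function(traces, times, condition = NULL,
                             baseline_window = 1.07, min_trials = 2) {
  stopifnot(is.matrix(traces), length(times) == ncol(traces))
  base_idx <- which(times >= -baseline_window & times < 0)
  if (length(base_idx) < 2) {
    abort("Baseline window must cover at least 2 frames.",
          class = "wa_invalid_window")
  }
  detrend_group <- function(m) {
    med <- apply(m[, base_idx, drop = FALSE], 2, median)
    fit <- lm(med ~ t, data = data.frame(med = med, t = times[base_idx]))
    line <- coef(fit)[[1]] + coef(fit)[[2]] * times
    sweep(m, 2, line, "-")
  }
  if (is.null(condition)) {
    if (nrow(traces) < min_trials) {
      abort("Too few trials to detrend.", class = "wa_insufficient_data")
    }
    return(detrend_group(traces))
  }
  stopifnot(length(condition) == nrow(traces))
  out <- traces
  for (g in unique(condition)) {
    idx <- which(condition == g)
    if (length(idx) < min_trials) {
      inform(sprintf("detrend_baseline: skipping '%s' (%d trials).",
                     g, length(idx)))
      next
    }
    out[idx, ] <- detrend_group(traces[idx, , drop = FALSE])
  }
  out
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in fixed bins aligned to stimulus onset.
#'
#' @param spike_times List of per-trial spike-time vectors (s, relative to
#'   onset).
#' @param bin_s Bin width in seconds (default 10 ms).
#' @param window Histogram window `c(lo, hi)` in seconds.
#' @return Tibble with `time` (bin centre) and `rate` (Hz).
#' @export
psth <- function(spike_times, bin_s = 0.01, window = c(-0.1, 0.6)) {
  breaks <- seq(window[1], window[2], by = bin_s)
  counts <- rep(0, length(breaks) - 1)
  for (st in spike_times) {
    st <- st[st >= window[1] & st < breaks[length(breaks)]]
    if (length(st)) {
      counts <- counts + tabulate(findInterval(st, breaks),
                                  nbins = length(counts))
    }
  }
  tibble::tibble(
    time = breaks[-length(breaks)] + bin_s / 2,
    rate = counts / (length(spike_times) * bin_s)
  )
}
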