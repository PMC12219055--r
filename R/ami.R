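#' Normalized modulation index
#'
#' `(a - b) / |a + b|`, the normalized difference used by all attention and
#' response modulation indices. Undefined (NA) when `|a + b|` is below `eps`.
#'
#' @param a,b Condition means (vectorised).
#' @param eps Denominator tolerance (response units).
#' @return Numeric vector in \[-1, 1\] (for same-signed inputs), NA where
#'   undefined.
#' @export
modulation_index <- function(a, b, eps = 1e-6) {
  den <- abs(a + b)
  ifelse(den < eps, NA_real_, (a - b) / den)
}

#' Attention modulation indices for one cell
#'
#' Computes the three AMIs from mean evoked responses on current Go trials
#' (any whisker) grouped by trial history:
#' `AMI_same_vs_nogo = (Go_>1HitSame - Go_NoGo) / |Go_>1HitSame + Go_NoGo|`,
#' the analogous index for prior >1 hits to a different whisker, and the
#' same-vs-different contrast. A record is valid only when every condition
#' has at least `min_trials` trials and no denominator underflows.
#'
#' @param evoked Evoked responses on Go trials.
#' @param category Matching history categories (uses `priorGT1HitSame`,
#'   `priorGT1HitDiff`, `priorNoGo`).
#' @param min_trials Minimum trials per condition (default 3).
#' @param eps Denominator tolerance.
#' @return One-row tibble: the three indices, per-condition counts, `valid`.
#' @export
compute_ami <- function(evoked, category, min_trials = 3, eps = 1e-6) {
  stopifnot(length(evoked) == length(category))
  m <- function(cat) mean(evoked[category == cat])
  n <- function(cat) sum(category == cat, na.rm = TRUE)
  n_same <- n("priorGT1HitSame")
  n_diff <- n("priorGT1HitDiff")
  n_nogo <- n("priorNoGo")
  enough <- min(n_same, n_diff, n_nogo) >= min_trials
  out <- tibble::tibble(
    ami_same_vs_nogo = if (n_same >= min_trials && n_nogo >= min_trials)
      modulation_index(m("priorGT1HitSame"), m("priorNoGo"), eps)
      else NA_real_,
    ami_diff_vs_nogo = if (n_diff >= min_trials && n_nogo >= min_trials)
      modulation_index(m("priorGT1HitDiff"), m("priorNoGo"), eps)
      else NA_real_,
    ami_same_vs_diff = if (n_same >= min_trials && n_diff >= min_trials)
      modulation_index(m("priorGT1HitSame"), m("priorGT1HitDiff"), eps)
      else NA_real_,
    n_same = n_same, n_diff = n_diff, n_nogo = n_nogo
  )
  out$valid <- enough & !anyNA(out[1, 1:3])
  out
}

#' Attention modulation indices per cell
#'
#' Joins a long response table with history labels and computes
#' [compute_ami()] for every cell, over current Go trials.
#'
#' @param responses Long response tibble (`trial_index`, `cell_id`,
#'   `evoked`).
#' @param labels Labelled session from [classify_history()].
#' @param min_trials,eps Passed to [compute_ami()].
#' @return Tibble with one row per cell.
#' @export
ami_by_cell <- function(responses, labels, min_trials = 3, eps = 1e-6) {
  go <- dplyr::filter(labels, .data$kind == "Go", !.data$aborted,
                      !is.na(.data$category))
  joined <- dplyr::inner_join(
    responses,
    dplyr::select(go, "trial_index", "category"),
    by = "trial_index"
  )
  out <- dplyr::reframe(
    dplyr::group_by(joined, .data$cell_id),
    compute_ami(.data$evoked, .data$category, min_trials = min_trials,
                eps = eps)
  )
  dplyr::ungroup(out)
}
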