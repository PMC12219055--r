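#' Classify each trial by its recent stimulus-reward history
#'
#' Assigns every non-aborted trial to a trial-history category based on the
#' outcome, stimulus whisker and reward of the immediately preceding trials.
#' Current Go trials take the categories in [history_categories_go()]
#' (distinguishing prior hit(s) to the same vs a different whisker); current
#' NoGo trials take the collapsed categories in [history_categories_nogo()].
#' A hit streak is the maximal run of immediately preceding hits to one
#' consistent whisker.
#'
#' @param session Session tibble (one row per trial, ordered by onset).
#' @param grid The [whisker_grid()] of the session; defaults to the grid
#'   attached to the session.
#' @param mode `"consecutive"` classifies over all preceding trials (a NoGo
#'   breaks a hit streak and yields the `priorNoGo` category).
#'   `"ignore-nogo"` skips NoGo trials when looking back, so history reflects
#'   Go trials only (used for the temporal profile of cueing).
#' @param reward_threshold_fraction Hits whose reward is below this fraction
#'   of the session's maximum reward are flagged via `low_reward_prior`.
#' @param low_reward_as With `"hit"` (default) low-reward hits still count as
#'   hits for classification; with `"miss"` they are treated as misses
#'   (non-boosting), mirroring the observation that unrewarded or very small
#'   rewards do not cue attention.
#' @param abort_breaks Whether an aborted trial terminates the look-back
#'   (default `FALSE`: aborted trials are skipped as history sources but kept
#'   as time markers).
#'
#' @return The session tibble with added columns `category`, `run_length`,
#'   `prior_whisker`, `offset_class`, `inter_go_interval`,
#'   `prior_reward_fraction`, `low_reward_prior`. First trials (no usable
#'   history) and aborted trials get `NA` category.
#' @export
classify_history <- function(session, grid = attr(session, "grid"),
                             mode = c("consecutive", "ignore-nogo"),
                             reward_threshold_fraction = 0,
                             low_reward_as = c("hit", "miss"),
                             abort_breaks = FALSE) {
  mode <- match.arg(mode)
  low_reward_as <- match.arg(low_reward_as)
  if (is.null(grid)) {
    abort("No `grid` supplied and none attached to the session.",
          class = "wa_invalid_input")
  }
  n <- nrow(session)
  kind <- session$kind
  whisker <- session$whisker
  outcome <- session$outcome
  onset <- session$onset_time_s
  aborted <- session$aborted
  reward <- session$reward_ul
  max_reward <- suppressWarnings(max(reward[outcome == "Hit" & !aborted],
                                     na.rm = TRUE))
  if (!is.finite(max_reward) || max_reward <= 0) max_reward <- NA_real_

  reward_frac <- ifelse(outcome == "Hit" & !is.na(max_reward),
                        reward / max_reward, NA_real_)
  low_reward <- !is.na(reward_frac) & reward_frac < reward_threshold_fraction
  # a hit that counts towards cueing streaks
  effective_hit <- outcome == "Hit" &
    !(low_reward & low_reward_as == "miss")

  is_source <- !aborted
  if (mode == "ignore-nogo") is_source <- is_source & kind == "Go"

  category <- rep(NA_character_, n)
  run_length <- integer(n)
  prior_whisker <- rep(NA_character_, n)
  inter_go <- rep(NA_real_, n)
  prior_rf <- rep(NA_real_, n)
  low_reward_prior <- rep(FALSE, n)

  last_go_onset <- NA_real_
  source_idx <- integer(0)  # indices of source trials seen so far

  for (i in seq_len(n)) {
    if (!is.na(last_go_onset)) inter_go[i] <- onset[i] - last_go_onset
    if (!aborted[i]) {
      prev <- NA_integer_
      if (length(source_idx) > 0L) {
        prev <- source_idx[length(source_idx)]
        if (abort_breaks && i > 1L && aborted[i - 1L]) prev <- NA_integer_
      }
      if (!is.na(prev)) {
        if (kind[prev] == "Go") {
          prior_whisker[i] <- whisker[prev]
          if (outcome[prev] == "Hit") {
            prior_rf[i] <- reward_frac[prev]
            low_reward_prior[i] <- low_reward[prev]
          }
        }
        if (kind[prev] == "NoGo") {
          category[i] <- "priorNoGo"
        } else if (!effective_hit[prev]) {
          category[i] <- if (kind[i] == "Go") {
            if (identical(whisker[prev], whisker[i])) "priorMissSame"
            else "priorMissDiff"
          } else "priorMiss"
        } else {
          # maximal streak of effective hits to the one consistent whisker
          run <- 0L
          pos <- length(source_idx)
          while (pos >= 1L) {
            j <- source_idx[pos]
            if (kind[j] == "Go" && effective_hit[j] &&
                identical(whisker[j], whisker[prev])) {
              run <- run + 1L
              pos <- pos - 1L
            } else break
          }
          run_length[i] <- run
          if (kind[i] == "Go") {
            same <- identical(whisker[prev], whisker[i])
            category[i] <- if (run >= 2L) {
              if (same) "priorGT1HitSame" else "priorGT1HitDiff"
            } else {
              if (same) "prior1HitSame" else "prior1HitDiff"
            }
          } else {
            category[i] <- if (run >= 2L) "priorGT1Hit" else "prior1Hit"
          }
        }
      }
    }
    if (is_source[i]) source_idx <- c(source_idx, i)
    if (kind[i] == "Go" && !aborted[i]) last_go_onset <- onset[i]
  }

  off <- offset_class(grid, prior_whisker, whisker)
  off[kind != "Go"] <- NA
  out <- dplyr::mutate(
    session,
    category = category,
    run_length = run_length,
    prior_whisker = prior_whisker,
    offset_class = off,
    inter_go_interval = inter_go,
    prior_reward_fraction = prior_rf,
    low_reward_prior = low_reward_prior
  )
  attr(out, "grid") <- grid
  attr(out, "history_mode") <- mode
  out
}
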