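# Hand-labelled 40-trial fixture covering every history category, streak
# breaking by whisker change, interleaved NoGo trials, an aborted trial, and
# low-reward hits. Expected labels assume mode = "consecutive",
# reward_threshold_fraction = 0.05, low_reward_as = "miss".
history_fixture <- function() {
  mk <- function(i, kind, whisker, outcome, reward = 0, aborted = FALSE) {
    tibble::tibble(
      trial_index = i, onset_time_s = i * 4, kind = kind,
      whisker = whisker, amplitude_um = ifelse(kind == "Go", 150, NA_real_),
      outcome = outcome, reward_ul = reward,
      first_lick_latency_s = ifelse(outcome %in% c("Hit", "FA"), 0.3,
                                    NA_real_),
      aborted = aborted
    )
  }
  rows <- list(
    mk(1,  "Go",   "D2", "Hit",  8),
    mk(2,  "Go",   "D2", "Hit",  8),
    mk(3,  "Go",   "D2", "Hit",  8),
    mk(4,  "Go",   "C1", "Hit",  8),
    mk(5,  "NoGo", NA,   "CR"),
    mk(6,  "Go",   "C1", "Hit",  8),
    mk(7,  "Go",   "C1", "Miss"),
    mk(8,  "Go",   "D1", "Miss"),
    mk(9,  "Go",   "D1", "Hit",  8),
    mk(10, "Go",   "D1", "Hit",  8),
    mk(11, "Go",   "E3", "Hit",  8),
    mk(12, "Go",   "E3", "Hit",  0.2),  # low reward: below 5% of max
    mk(13, "Go",   "E3", "Hit",  8),
    mk(14, "NoGo", NA,   "FA"),
    mk(15, "NoGo", NA,   "CR"),
    mk(16, "Go",   "C3", "Hit",  8),
    mk(17, "Go",   "C3", "Hit",  8, aborted = TRUE),
    mk(18, "Go",   "C3", "Hit",  8),
    mk(19, "Go",   "D3", "Hit",  8),
    mk(20, "Go",   "D3", "Hit",  8),
    mk(21, "NoGo", NA,   "CR"),
    mk(22, "Go",   "D3", "Hit",  8),
    mk(23, "NoGo", NA,   "FA"),
    mk(24, "NoGo", NA,   "CR"),
    mk(25, "Go",   "C2", "Miss"),
    mk(26, "NoGo", NA,   "CR"),
    mk(27, "Go",   "C2", "Hit",  8),
    mk(28, "Go",   "D2", "Hit",  8),
    mk(29, "Go",   "D2", "Hit",  8),
    mk(30, "Go",   "D2", "Hit",  8),
    mk(31, "Go",   "C1", "Miss"),
    mk(32, "Go",   "C1", "Hit",  8),
    mk(33, "NoGo", NA,   "CR"),
    mk(34, "Go",   "C1", "Hit",  8),
    mk(35, "Go",   "C1", "Hit",  8),
    mk(36, "Go",   "C2", "Hit",  8),
    mk(37, "NoGo", NA,   "FA"),
    mk(38, "Go",   "E1", "Hit",  8),
    mk(39, "Go",   "E1", "Hit",  0.1),  # low reward
    mk(40, "NoGo", NA,   "CR")
  )
  trials <- dplyr::bind_rows(rows)
  expected <- c(
    NA, "prior1HitSame", "priorGT1HitSame", "priorGT1HitDiff", "prior1Hit",
    "priorNoGo", "prior1HitSame", "priorMissDiff", "priorMissSame",
    "prior1HitSame", "priorGT1HitDiff", "prior1HitSame", "priorMissSame",
    "prior1Hit", "priorNoGo", "priorNoGo", NA, "prior1HitSame",
    "priorGT1HitDiff", "prior1HitSame", "priorGT1Hit", "priorNoGo",
    "prior1Hit", "priorNoGo", "priorNoGo", "priorMiss", "priorNoGo",
    "prior1HitDiff", "prior1HitSame", "priorGT1HitSame", "priorGT1HitDiff",
    "priorMissSame", "prior1Hit", "priorNoGo", "prior1HitSame",
    "priorGT1HitDiff", "prior1Hit", "priorNoGo", "prior1HitSame",
    "priorMiss"
  )
  list(trials = trials, expected = expected)
}

# Small receptive-field tibble builder: values given row-major over the 3x3
# offsets (dy = 1 row first), NA = unsampled.
rf_fixture <- function(values) {
  offs <- expand.grid(dx = -1:1, dy = 1:-1)[, c("dx", "dy")]
  tibble::tibble(
    dx = offs$dx, dy = offs$dy,
    value = as.numeric(values),
    sampled = !is.na(values)
  )
}
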