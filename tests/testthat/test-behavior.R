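test_that("SDT metrics agree with the inverse-normal oracle", {
  r <- compute_sdt(50, 50, 50, 50)
  expect_equal(r$d_prime, 0)
  expect_equal(r$criterion, 0)

  r <- compute_sdt(84, 16, 50, 50)
  expect_equal(r$d_prime, qnorm(0.84) - qnorm(0.5), tolerance = 1e-12)
  expect_equal(r$criterion, -(qnorm(0.84) + qnorm(0.5)) / 2,
               tolerance = 1e-12)

  # log-linear handling of a perfect hit rate
  r <- compute_sdt(100, 0, 30, 70)
  expect_true(r$correction_applied)
  expect_equal(r$hit_rate, 100.5 / 101, tolerance = 1e-12)
  expect_equal(r$d_prime, qnorm(100.5 / 101) - qnorm(0.3), tolerance = 1e-12)

  set.seed(99)
  for (i in 1:50) {
    cnt <- sample(0:40, 4, replace = TRUE) + c(1, 1, 1, 1)
    r <- compute_sdt(cnt[1], cnt[2], cnt[3], cnt[4])
    o <- sdt_oracle(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(r$d_prime, unname(o["d_prime"]), tolerance = 1e-9)
    expect_equal(r$criterion, unname(o["criterion"]), tolerance = 1e-9)
  }

  expect_error(compute_sdt(0, 0, 5, 5), class = "wa_undefined_metric")
  expect_error(compute_sdt(10, 0, 5, 5, correction = "none"),
               class = "wa_undefined_metric")
})

test_that("engagement window trims low-performance epochs", {
  g <- whisker_grid()
  mk_block <- function(idx, hit_rate, fa_rate, seed) {
    withr::with_seed(seed, {
      kind <- ifelse(runif(length(idx)) < 0.5, "Go", "NoGo")
      outcome <- ifelse(
        kind == "Go",
        ifelse(runif(length(idx)) < hit_rate, "Hit", "Miss"),
        ifelse(runif(length(idx)) < fa_rate, "FA", "CR")
      )
      tibble::tibble(
        trial_index = idx, onset_time_s = idx * 3, kind = kind,
        whisker = ifelse(kind == "Go", "D2", NA), amplitude_um = 150,
        outcome = outcome, reward_ul = ifelse(outcome == "Hit", 8, 0),
        first_lick_latency_s = NA_real_, aborted = FALSE
      )
    })
  }
  good <- mk_block(1:200, 0.9, 0.1, 1)
  w <- engagement_window(good, window = 50, cutoff = 0.5)
  expect_equal(w$first_index, 1)
  expect_equal(w$last_index, 200)

  # 80 chance-level trials then strong performance: window starts later
  sess <- dplyr::bind_rows(mk_block(1:80, 0.3, 0.3, 2),
                           mk_block(81:260, 0.9, 0.1, 3))
  w <- engagement_window(sess, window = 50, cutoff = 0.5)
  expect_gt(w$first_index, 40)
  expect_equal(w$last_index, 260)
  # independent scan: every retained sliding window can reach the cutoff
  trimmed <- trim_to_engagement(sess, window = 50, cutoff = 0.5)
  expect_gt(mean(trimmed$outcome %in% c("Hit", "CR")), 0.6)

  # stringent spike-recording cutoff on a mediocre session: no window
  mediocre <- mk_block(1:150, 0.75, 0.4, 4)  # d' around 1
  expect_error(engagement_window(mediocre, window = 50, cutoff = 1.2),
               class = "wa_empty_window")
})

test_that("history classifier matches the hand-labelled fixture", {
  fx <- history_fixture()
  lab <- classify_history(fx$trials, whisker_grid(),
                          mode = "consecutive",
                          reward_threshold_fraction = 0.05,
                          low_reward_as = "miss")
  expect_equal(lab$category, fx$expected)
  # run lengths on key trials
  expect_equal(lab$run_length[3], 2)   # two prior hits to D2
  expect_equal(lab$run_length[4], 3)
  expect_equal(lab$run_length[29], 1)  # streak broken by whisker change
  expect_equal(lab$run_length[31], 3)
  # offset class of the cueing whisker
  expect_equal(as.character(lab$offset_class[28]), "same-arc adjacent")
  expect_equal(as.character(lab$offset_class[36]), "same-row adjacent")
  expect_equal(as.character(lab$offset_class[2]), "same")
  # inter-Go interval skips the NoGo trial at index 5
  expect_equal(lab$inter_go_interval[6], 8)
  # low-reward prior hits are flagged
  expect_true(lab$low_reward_prior[13])
  expect_false(lab$low_reward_prior[11])
})

test_that("history categories partition the classified trials", {
  fx <- history_fixture()
  lab <- classify_history(fx$trials, whisker_grid(),
                          reward_threshold_fraction = 0.05,
                          low_reward_as = "miss")
  n_labelled <- sum(!is.na(lab$category))
  n_first <- 1
  n_aborted <- sum(lab$aborted)
  expect_equal(n_labelled + n_first + n_aborted, nrow(fx$trials))
  counts <- table(lab$category)
  expect_equal(sum(counts), n_labelled)
  # Go and NoGo vocabularies stay disjoint by construction
  go_cats <- unique(lab$category[lab$kind == "Go" & !is.na(lab$category)])
  expect_true(all(go_cats %in% history_categories_go()))
  nogo_cats <- unique(lab$category[lab$kind == "NoGo" &
                                     !is.na(lab$category)])
  expect_true(all(nogo_cats %in% history_categories_nogo()))
})

test_that("consecutive and ignore-nogo modes agree without NoGo trials", {
  s <- simulate_session(behavior_config(n_trials = 300, p_go = 1), seed = 12)
  a <- classify_history(s, mode = "consecutive")
  b <- classify_history(s, mode = "ignore-nogo")
  expect_equal(a$category, b$category)
  expect_equal(a$run_length, b$run_length)
})

test_that("history-conditioned SDT uses matched NoGo pools", {
  s <- simulate_session(behavior_config_calibrated(n_trials = 2000),
                        seed = 13)
  lab <- classify_history(trim_to_engagement(s),
                          reward_threshold_fraction = 0.04)
  h <- suppressMessages(history_sdt(lab))
  expect_equal(h$delta_d[h$category == "priorNoGo"], 0)
  expect_equal(h$nogo_pool[h$category == "prior1HitSame"], "prior1Hit")
  expect_equal(h$nogo_pool[h$category == "prior1HitDiff"], "prior1Hit")
  # shared pool: both prior-1-hit categories carry identical FA rates
  fa <- h$fa_rate[h$category %in% c("prior1HitSame", "prior1HitDiff")]
  if (length(fa) == 2) expect_equal(fa[1], fa[2])
  expect_true(all(h$n_go >= 5))
})

test_that("temporal profile drops empty bins and recovers a flat limit", {
  s <- simulate_session(behavior_config_calibrated(n_trials = 3000),
                        seed = 14)
  lab <- classify_history(s, mode = "ignore-nogo",
                          reward_threshold_fraction = 0.04)
  tp <- temporal_profile(lab, breaks = c(0, 4, 8, 12, 100, 200))
  expect_true(all(tp$n_same >= 5 & tp$n_diff >= 5))
  expect_false(any(tp$bin_lo == 100))  # no inter-Go intervals that long
  # no temporal decay in the calibrated preset: profile is flat in
  # expectation, so early and late bins should not differ wildly
  expect_gt(nrow(tp), 1)
})
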