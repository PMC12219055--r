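test_that("dF/F conversion matches the percentile oracle", {
  flat <- dff_from_fluorescence(rep(10, 20))
  expect_equal(flat$dff, rep(0, 20))

  raw <- c(10, 10, 10, 20)
  tr <- dff_from_fluorescence(raw)
  f0 <- unname(quantile(raw, 0.2))  # independent percentile oracle
  expect_equal(attr(tr, "f0"), f0)
  expect_equal(max(tr$dff), (20 - f0) / f0)

  # neuropil subtraction is scale * neuropil before conversion
  tr2 <- dff_from_fluorescence(raw, neuropil = rep(2, 4),
                               neuropil_scale = 0.3)
  expect_equal(tr2$f_corrected, raw - 0.6)

  expect_error(dff_from_fluorescence(c(-5, -5, -5, 1)),
               class = "wa_degenerate_baseline")
  expect_error(dff_from_fluorescence(rep(1, 4), neuropil = rep(1, 3)),
               class = "wa_invalid_input")
})

test_that("evoked response is post-window minus baseline-window mean", {
  flat <- matrix(0.5, nrow = 3, ncol = 12)
  expect_equal(evoked_response(flat, onset_frame = 4), rep(0, 3))

  tr <- matrix(0, nrow = 2, ncol = 12)
  tr[, 4:10] <- 1
  expect_equal(evoked_response(tr, onset_frame = 4), rep(1, 2))

  expect_error(evoked_response(tr, onset_frame = 2),
               class = "wa_invalid_window")
  expect_error(evoked_response(tr, onset_frame = 7),
               class = "wa_invalid_window")

  # z-score mode divides by the pooled baseline SD
  set.seed(1)
  noisy <- matrix(rnorm(50 * 12, sd = 2), nrow = 50)
  noisy[, 4:10] <- noisy[, 4:10] + 4
  ev <- evoked_response(noisy, 4, normalize = "zscore-baseline")
  s <- sd(as.vector(noisy[, 2:3]))
  expect_equal(ev, evoked_response(noisy, 4) / s)
})

test_that("evoked spike rate recovers the generating rate difference", {
  st <- simulate_spike_trains(400, baseline_hz = 5, evoked_hz = 15,
                              deflection_times = 0, evoked_dur = 0.5,
                              window = c(-0.5, 0.5), seed = 31)
  ev <- evoked_rate(st, post_window = c(0, 0.5),
                    baseline_window = c(-0.5, 0))
  expect_lt(abs(mean(ev) - 15), 1.5)
})

test_that("responsiveness test controls type I error and detects signals", {
  # identical Go and NoGo distributions: rarely called responsive
  calls <- vapply(1:100, function(s) {
    go <- withr::with_seed(500 + s, {
      stats::setNames(
        lapply(1:9, function(i) rnorm(10)), paste0("w", 1:9)
      )
    })
    nogo <- withr::with_seed(600 + s, rnorm(30))
    res <- responsiveness_test(go, nogo, n_iterations = 300, seed = s)
    attr(res, "responsive")
  }, logical(1))
  # FDR-level false-call rate of ~0.05, with binomial slack over 100 seeds
  expect_lte(mean(calls), 0.09)

  # one whisker shifted +5 SD: always detected
  hits <- vapply(1:20, function(s) {
    go <- withr::with_seed(700 + s, {
      g <- lapply(1:9, function(i) rnorm(10))
      g[[3]] <- g[[3]] + 5
      stats::setNames(g, paste0("w", 1:9))
    })
    nogo <- withr::with_seed(800 + s, rnorm(30))
    res <- responsiveness_test(go, nogo, n_iterations = 400, seed = s)
    attr(res, "responsive")
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # purely negative-going responses are never responsive
  go_neg <- stats::setNames(lapply(1:9, function(i) {
    withr::with_seed(i, rnorm(10, mean = -3))
  }), paste0("w", 1:9))
  nogo <- withr::with_seed(900, rnorm(30))
  res <- responsiveness_test(go_neg, nogo, n_iterations = 400, seed = 1)
  expect_false(attr(res, "responsive"))
})

test_that("responsiveness test reduces to the two-sample permutation test", {
  go <- list(w1 = withr::with_seed(1, rnorm(12, 1)))
  nogo <- withr::with_seed(2, rnorm(20))
  res <- responsiveness_test(go, nogo, n_iterations = 1000, seed = 5)
  direct <- permutation_test_two_sample(
    go$w1, nogo, n_iterations = 1000,
    seed = whiskattn:::derive_seed(5, 1), sided = "greater"
  )
  expect_equal(res$p_value, direct$p_value)
  expect_equal(res$mean_diff, direct$statistic)
})

test_that("AMI identities hold for direct substitution", {
  r <- compute_ami(
    c(0.3, 0.3, 0.3, 0.2, 0.2, 0.2, 0.1, 0.1, 0.1),
    rep(c("priorGT1HitSame", "priorGT1HitDiff", "priorNoGo"), each = 3)
  )
  expect_equal(r$ami_same_vs_nogo, 0.2 / 0.4)
  expect_equal(r$ami_diff_vs_nogo, 0.1 / 0.3)
  expect_equal(r$ami_same_vs_diff, 0.1 / 0.5)
  expect_true(r$valid)

  same <- compute_ami(rep(0.2, 9),
                      rep(c("priorGT1HitSame", "priorGT1HitDiff",
                            "priorNoGo"), each = 3))
  expect_equal(same$ami_same_vs_nogo, 0)

  # modulation index is scale invariant and antisymmetric
  expect_equal(modulation_index(0.6, 0.2), modulation_index(6, 2))
  expect_equal(modulation_index(0.2, 0.6), -modulation_index(0.6, 0.2))
  expect_true(is.na(modulation_index(1e-9, -1e-9)))

  # below the per-condition minimum the record is invalid
  few <- compute_ami(c(0.3, 0.1, 0.1, 0.1),
                     c("priorGT1HitSame", rep("priorNoGo", 3)))
  expect_false(few$valid)
})

test_that("linear baseline detrending is exact and preserves the response", {
  times <- seq(-1.2, 1.06, by = 1 / 7.5)
  zero <- matrix(0, nrow = 4, ncol = length(times))
  expect_equal(detrend_baseline(zero, times), zero)

  slope <- 0.8
  step <- as.numeric(times >= 0) * 2
  traces <- t(vapply(1:6, function(i) slope * times + step,
                     numeric(length(times))))
  det <- detrend_baseline(traces, times)
  base_idx <- times >= -1.07 & times < 0
  fit <- lm(det[1, base_idx] ~ times[base_idx])
  expect_lt(abs(coef(fit)[2]), 1e-9)
  post <- times >= 0
  expect_equal(mean(det[1, post]) - mean(det[1, base_idx]), 2,
               tolerance = 1e-9)

  # per-condition fits recover steeper decline after rewarded trials
  s <- simulate_session(behavior_config(n_trials = 300), seed = 41)
  tr <- simulate_trial_traces(s, seed = 42, noise_sd = 0)
  cond <- ifelse(
    c(FALSE, head(tr$labels$outcome == "Hit" & tr$labels$reward_ul > 0, -1)),
    "prior_rewarded", "prior_unrewarded"
  )
  slope_of <- function(m) {
    bi <- tr$times >= -1.07 & tr$times < 0
    med <- apply(m[, bi, drop = FALSE], 2, median)
    unname(coef(lm(med ~ tr$times[bi]))[2])
  }
  s_rew <- slope_of(tr$traces[cond == "prior_rewarded", ])
  s_un <- slope_of(tr$traces[cond == "prior_unrewarded", ])
  expect_lt(s_rew, s_un - 0.01)  # declining baseline only after reward
  det2 <- detrend_baseline(tr$traces, tr$times, condition = cond)
  expect_lt(abs(slope_of(det2[cond == "prior_rewarded", ])), 1e-9)
})

test_that("PSTH recovers homogeneous rates and stimulus-train structure", {
  expect_equal(sum(psth(list(numeric(0), numeric(0)))$rate), 0)

  st <- simulate_spike_trains(300, baseline_hz = 10, evoked_hz = 0,
                              deflection_times = numeric(0),
                              window = c(-0.5, 1), seed = 51)
  p <- psth(st, bin_s = 0.01, window = c(-0.4, 0.9))
  expect_lt(abs(mean(p$rate) - 10), 1)

  st5 <- simulate_spike_trains(300, baseline_hz = 2, evoked_hz = 60,
                               deflection_times = seq(0, 0.4, by = 0.1),
                               evoked_dur = 0.02, window = c(-0.2, 0.7),
                               seed = 52)
  p5 <- psth(st5, bin_s = 0.01, window = c(-0.1, 0.6))
  peaks <- vapply(seq(0, 0.4, by = 0.1), function(d) {
    mean(p5$rate[p5$time > d & p5$time < d + 0.02])
  }, numeric(1))
  expect_true(all(peaks > 5 * mean(p5$rate[p5$time < 0])))
})

test_that("somatotopic profile is exact for point populations", {
  g <- whisker_grid()
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:9),
    x_um = g$cx_um, y_um = g$cy_um
  )
  trials <- tibble::tibble(
    trial_index = 1:9, kind = "Go", whisker = g$whisker,
    aborted = FALSE, category = "priorNoGo"
  )
  responses <- tidyr::expand_grid(trial_index = 1:9,
                                  cell_id = paste0("c", 1:9))
  responses$evoked <- 1
  prof <- somatotopic_profile(responses, trials, cells, g,
                              conditions = "priorNoGo", bin_width = 0.25)
  expect_equal(prof$mean_response, rep(1, nrow(prof)))
  expect_equal(min(prof$bin_mid), 0.125)
})

test_that("laminar grouping confines the whisker-specific effect", {
  s <- simulate_session(
    behavior_config_calibrated(n_trials = 2500, p_repeat_whisker = 0.45),
    seed = 61
  )
  cfg <- neural_config(n_cells = 90, noise_sd = 0.1, attentional_gain = 3,
                       tuning_width = 1e6, gain_space_halfwidth = 1e6,
                       layers_with_gain = c("L2/3", "L5"),
                       layer_probs = c(0.4, 0.3, 0.3))
  pop <- simulate_population(s, cfg, seed = 62)
  ami <- ami_by_cell(pop$responses, pop$labels)
  ami <- dplyr::inner_join(ami, pop$cells[, c("cell_id", "layer")],
                           by = "cell_id")
  ami <- ami[ami$valid, ]
  by_layer <- tapply(ami$ami_same_vs_diff, ami$layer, median)
  expect_gt(by_layer[["L2/3"]], 0.2)
  expect_gt(by_layer[["L5"]], 0.2)
  expect_lt(abs(by_layer[["L4"]]), 0.05)
})
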