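# Separable synthetic field: Go trials carry signal, NoGo trials do not.
make_separable <- function(n_go = 120, n_nogo = 120, n_cells = 25,
                           signal = 1, noise = 0.4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_go * n_cells, mean = signal, sd = noise),
             nrow = n_go),
      matrix(rnorm(n_nogo * n_cells, mean = 0, sd = noise), nrow = n_nogo)
    )
    colnames(x) <- paste0("c", seq_len(n_cells))
    outcome <- c(
      sample(rep(c("Hit", "Miss"), length.out = n_go)),
      sample(rep(c("CR", "FA"), length.out = n_nogo))
    )
    list(x = x, outcome = outcome)
  })
}

test_that("decoder separates well-separated response distributions", {
  d <- make_separable(seed = 81)
  m <- fit_decoder(d$x, d$outcome, seed = 82)
  expect_gte(m$accuracy, 0.9)
  expect_equal(length(m$weights), 25)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$accuracy, m$accuracy)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  d <- make_separable(seed = 83)
  accs <- vapply(1:8, function(i) {
    shuffled <- withr::with_seed(90 + i, sample(d$outcome))
    fit_decoder(d$x, shuffled, seed = i)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("decoder fitting is deterministic and enforces balance", {
  d <- make_separable(n_go = 100, n_nogo = 60, seed = 84)
  m1 <- fit_decoder(d$x, d$outcome, seed = 85)
  m2 <- fit_decoder(d$x, d$outcome, seed = 85)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$ridge_strength, m2$ridge_strength)

  # balanced resample: equal counts per outcome class
  counts <- table(d$outcome[m1$balanced_idx])
  expect_equal(length(unique(counts)), 1L)
  # every balanced trial has a fold in 1..10
  expect_true(all(m1$fold_assignment %in% 1:10))
  expect_equal(length(m1$fold_assignment), length(m1$balanced_idx))

  few <- d$outcome
  few[few == "FA"][-(1:2)] <- "CR"
  expect_error(fit_decoder(d$x, few, seed = 1),
               class = "wa_insufficient_data")
})

test_that("decoder performance degrades monotonically with noise", {
  accs <- vapply(c(0.3, 1, 2.5), function(ns) {
    d <- make_separable(noise = ns, seed = 86)
    fit_decoder(d$x, d$outcome, seed = 87)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.02))  # non-increasing up to CV noise
})

test_that("field best whisker is the population argmax with tie flagging", {
  g <- whisker_grid()
  trials <- tibble::tibble(trial_index = 1:9, kind = "Go",
                           whisker = g$whisker, aborted = FALSE)
  responses <- tidyr::expand_grid(trial_index = 1:9, cell_id = c("a", "b"))
  responses$evoked <- 0.1
  responses$evoked[responses$trial_index == 5] <- 0.3  # D2 trials
  f <- field_best_whisker(responses, trials, g)
  expect_equal(f$whisker, "D2")
  expect_false(f$tie)

  responses$evoked[responses$trial_index == 1] <- 0.3  # C1 ties with D2
  f2 <- field_best_whisker(responses, trials, g)
  expect_equal(f2$whisker, "C1")  # row-major: C1 precedes D2
  expect_true(f2$tie)
})

test_that("decoder evaluation scores every trial out of fold", {
  s <- simulate_session(
    behavior_config_calibrated(n_trials = 350, p_repeat_whisker = 0.4),
    seed = 88
  )
  pop <- simulate_population(
    s, neural_config(n_cells = 30, noise_sd = 0.3, attentional_gain = 1,
                     field_center = "D2"),
    seed = 89
  )
  lab <- dplyr::filter(pop$labels, !aborted)
  x <- response_matrix(pop$responses)
  x <- x[match(lab$trial_index, rownames(x)), ]
  fbw <- field_best_whisker(pop$responses, lab, whisker_grid())
  ev <- evaluate_decoder(x, lab, fbw$whisker, n_iterations = 3, seed = 90)
  expect_true(all(ev$fraction_called >= 0 & ev$fraction_called <= 1))
  expect_true(all(c("any", "fBW", "non-fBW", "NoGo") %in% ev$filter))
  # without attentional gain the NoGo false-call rate is history-flat
  nogo <- ev[ev$filter == "NoGo", ]
  if (nrow(nogo) >= 2) {
    expect_lt(max(nogo$fraction_called) - min(nogo$fraction_called), 0.35)
  }
})
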