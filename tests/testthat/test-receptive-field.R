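test_that("best whisker takes the argmax with row-major tie breaking", {
  rf <- rf_fixture(c(NA, NA, NA, NA, 0.4, NA, NA, NA, NA))
  b <- best_whisker(rf)
  expect_equal(c(b$dx, b$dy), c(0, 0))

  # rostral neighbour beats the CW
  rf <- rf_fixture(c(0, 0, 0, 0, 0.5, 0.9, 0, 0, 0))
  b <- best_whisker(rf)
  expect_equal(c(b$dx, b$dy), c(1, 0))
  expect_false(b$tie)

  # exact CW / rostral tie resolves row-major (the earlier offset) and flags
  rf <- rf_fixture(c(0, 0, 0, 0, 0.9, 0.9, 0, 0, 0))
  b <- best_whisker(rf)
  expect_equal(c(b$dx, b$dy), c(0, 0))
  expect_true(b$tie)

  expect_error(best_whisker(rf_fixture(rep(NA, 9))),
               class = "wa_insufficient_data")
})

test_that("centre of mass is the response-weighted mean offset", {
  uniform <- rf_fixture(rep(1, 9))
  expect_equal(unlist(rf_com(uniform)[, c("x", "y")]),
               c(x = 0, y = 0))

  point <- rf_fixture(c(0, 0, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(unlist(rf_com(point)[, c("x", "y")]), c(x = 1, y = 0))

  two <- rf_fixture(c(0, 0, 0, 0, 2, 1, 0, 0, 0))
  expect_equal(rf_com(two)$x, 1 / 3)
  expect_equal(rf_com(two)$y, 0)

  # mirroring the field mirrors the CoM (reflection equivariance)
  set.seed(71)
  vals <- runif(9)
  rf <- rf_fixture(vals)
  mirrored <- rf
  mirrored$dx <- -mirrored$dx
  expect_equal(rf_com(mirrored)$x, -rf_com(rf)$x)
  expect_equal(rf_com(mirrored)$y, rf_com(rf)$y)

  # negative values are clipped, all-nonpositive is undefined
  neg <- rf_fixture(c(-1, 0, 0, 0, 2, 1, 0, 0, 0))
  expect_equal(rf_com(neg)$x, 1 / 3)
  expect_equal(rf_com(neg)$clipped, 1)
  expect_error(rf_com(rf_fixture(rep(-1, 9))), class = "wa_undefined_com")
})

test_that("RF shift implements the normalized attention-axis projection", {
  # CoM moves from (0,0) to (0.3, 0) with target (1, 0): shift = +0.3
  rf_n <- rf_fixture(c(1, 1, 1, 1, 1, 1, 1, 1, 1))
  # value x at (1,0) with ones elsewhere puts the CoM at (x-1)/(8+x)
  vals_a <- c(1, 1, 1, 1, 1, (1 + 8 * 0.3) / (1 - 0.3), 1, 1, 1)
  rf_a <- rf_fixture(vals_a)
  com_a <- rf_com(rf_a)
  expect_equal(com_a$x, 0.3, tolerance = 1e-6)
  res <- rf_shift(rf_n, rf_a, c(1, 0))
  expect_equal(res$shift, 0.3, tolerance = 1e-6)
  expect_false(res$excluded)

  # shifts away from the target are negative
  res_away <- rf_shift(rf_n, rf_a, c(-1, 0))
  expect_equal(res_away$shift, -0.3, tolerance = 1e-6)

  # diagonal target: normalization by the CW-target distance
  res_diag <- rf_shift(rf_n, rf_a, c(1, 1))
  expect_equal(res_diag$shift, (0.3 / sqrt(2)) / sqrt(2), tolerance = 1e-6)

  # scale invariance: multiplying both fields by a positive constant
  rf_n5 <- rf_n; rf_n5$value <- rf_n5$value * 5
  rf_a5 <- rf_a; rf_a5$value <- rf_a5$value * 5
  expect_equal(rf_shift(rf_n5, rf_a5, c(1, 0))$shift, res$shift)
})

test_that("coverage rule and intersection mask are enforced", {
  rf_n <- rf_fixture(c(1, 1, 1, 1, 1, NA, NA, NA, NA))  # 5 sampled
  rf_a <- rf_fixture(rep(1, 9))
  res <- rf_shift(rf_n, rf_a, c(1, 0))
  expect_true(res$excluded)
  expect_equal(res$reason, "coverage")

  # values at positions not shared by both conditions cannot affect the
  # result (perturbation test)
  rf_n2 <- rf_fixture(c(1, 2, 1, 0.8, 1.5, 1, 1, NA, 1))
  rf_a2 <- rf_fixture(c(1.2, 1, 1, 1, 2.5, 1.4, NA, 1, 1))
  base <- rf_shift(rf_n2, rf_a2, c(0, 1))
  rf_a3 <- rf_a2
  rf_a3$value[rf_a3$dx == 0 & rf_a3$dy == -1] <- 99  # nogo-unsampled there
  expect_equal(rf_shift(rf_n2, rf_a3, c(0, 1))$shift, base$shift)
  rf_n3 <- rf_n2
  rf_n3$value[rf_n3$dx == -1 & rf_n3$dy == -1] <- -50  # attend-unsampled
  expect_equal(rf_shift(rf_n3, rf_a2, c(0, 1))$shift, base$shift)
})

test_that("per-cell shifts average equally over attended targets", {
  rf_nogo <- rf_fixture(rep(1, 9))
  rf_nogo$cell_id <- "c1"
  # put mass x at the target offset so the CoM sits at s toward the target
  mk_attend <- function(tdx, tdy, s) {
    rf <- rf_fixture(rep(1, 9))
    x <- (1 + 8 * s) / (1 - s)
    rf$value[rf$dx == tdx & rf$dy == tdy] <- x
    rf$cell_id <- "c1"
    rf$target_dx <- tdx
    rf$target_dy <- tdy
    rf
  }
  rfa <- dplyr::bind_rows(mk_attend(1, 0, 0.14), mk_attend(0, 1, 0.2))
  out <- rf_shift_by_cell(rf_nogo, rfa)
  expect_equal(out$shift, (0.14 + 0.2) / 2, tolerance = 1e-9)
  expect_equal(out$n_targets, 2)
})

test_that("RF modulation indices follow the printed formulas", {
  r <- rf_modulation(0.4, 0.2, 0.1, 0.2)
  expect_equal(r$rmi_cw, 0.2 / 0.6)
  expect_equal(r$rmi_sw, -0.1 / 0.3)
  expect_equal(r$cw_preference_attend, 0.3 / 0.5)
  expect_equal(r$cw_preference_nogo, 0)
  expect_true(r$valid)

  # attend = nogo: RMIs are zero, preferences match
  r0 <- rf_modulation(0.4, 0.4, 0.2, 0.2)
  expect_equal(r0$rmi_cw, 0)
  expect_equal(r0$rmi_sw, 0)
  expect_equal(r0$cw_preference_attend, r0$cw_preference_nogo)

  rz <- rf_modulation(1e-9, -1e-9, 0.1, 0.1)
  expect_false(rz$valid)
})

test_that("surround whiskers are the three strongest in the baseline field", {
  rf_n <- rf_fixture(c(0.9, 0.1, 0.8, 0.1, 1.0, 0.7, 0.1, 0.1, 0.1))
  rf_a <- rf_fixture(c(0.9, 0.1, 0.8, 0.1, 2.0, 0.7, 0.1, 0.1, 0.1))
  r <- rf_modulation_from_rfs(rf_a, rf_n)
  sw <- attr(r, "sw_offsets")
  expect_equal(nrow(sw), 3)
  # top-3 SWs by baseline value: (-1,1)=0.9, (1,1)=0.8, (1,0)=0.7
  expect_setequal(paste(sw$dx, sw$dy), c("-1 1", "1 1", "1 0"))
  expect_equal(r$rmi_cw, 1 / 3)
  expect_equal(r$rmi_sw, 0)
  expect_gt(r$cw_preference_attend, r$cw_preference_nogo)
})
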