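#' Build history-conditioned receptive fields per cell
#'
#' Constructs each cell's 9-whisker receptive field on a Cartesian grid
#' centred on its columnar whisker (CW): for every stimulus offset
#' `(dx, dy)` in `{-1,0,1}^2` (arc axis = x, rostral positive; row axis = y,
#' upper rows positive) the mean evoked response over current Go trials of
#' each history condition. Offsets beyond the 3x3 neighbourhood are dropped;
#' an offset is `sampled` when it has at least `min_trials` trials.
#'
#' @param responses Long response tibble (`trial_index`, `cell_id`,
#'   `evoked`).
#' @param labels Labelled session from [classify_history()].
#' @param cells Cell table with `cell_id` and `cw` (columnar whisker).
#' @param grid The session [whisker_grid()].
#' @param conditions History categories to keep.
#' @param min_trials Minimum trials per offset for `sampled = TRUE`.
#' @return Long tibble (`cell_id`, `category`, `dx`, `dy`, `value`, `n`,
#'   `sampled`).
#' @export
cell_receptive_fields <- function(responses, labels, cells, grid,
                                  conditions = c("priorNoGo",
                                                 "priorGT1HitSame",
                                                 "priorGT1HitDiff"),
                                  min_trials = 1) {
  go <- dplyr::filter(labels, .data$kind == "Go", !.data$aborted,
                      .data$category %in% conditions)
  joined <- dplyr::inner_join(
    responses,
    dplyr::select(go, "trial_index", "category", "whisker"),
    by = "trial_index"
  )
  joined <- dplyr::inner_join(joined,
                              dplyr::select(cells, "cell_id", "cw"),
                              by = "cell_id")
  wi <- match(joined$whisker, grid$whisker)
  ci <- match(joined$cw, grid$whisker)
  joined$dx <- grid$x[wi] - grid$x[ci]
  joined$dy <- grid$y[wi] - grid$y[ci]
  joined <- dplyr::filter(joined, abs(.data$dx) <= 1, abs(.data$dy) <= 1)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$cell_id, .data$category, .data$dx,
                    .data$dy),
    value = mean(.data$evoked),
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, sampled = .data$n >= min_trials)
}

#' Receptive fields conditioned on the attended whisker
#'
#' Like [cell_receptive_fields()] but restricted to Go trials following
#' prior-hit streaks, grouped by the attended (prior-hit) whisker expressed
#' as a target offset from each cell's CW. Only targets within the 3x3
#' neighbourhood (excluding the CW itself) are kept.
#'
#' @inheritParams cell_receptive_fields
#' @param min_run Minimum prior-hit streak length (default 2, i.e. >1 hits).
#' @return Long tibble (`cell_id`, `target_dx`, `target_dy`, `dx`, `dy`,
#'   `value`, `n`, `sampled`).
#' @export
attended_receptive_fields <- function(responses, labels, cells, grid,
                                      min_run = 2, min_trials = 1) {
  go <- dplyr::filter(labels, .data$kind == "Go", !.data$aborted,
                      .data$run_length >= min_run,
                      !is.na(.data$prior_whisker))
  joined <- dplyr::inner_join(
    responses,
    dplyr::select(go, "trial_index", "whisker", "prior_whisker"),
    by = "trial_index"
  )
  joined <- dplyr::inner_join(joined,
                              dplyr::select(cells, "cell_id", "cw"),
                              by = "cell_id")
  wi <- match(joined$whisker, grid$whisker)
  ai <- match(joined$prior_whisker, grid$whisker)
  ci <- match(joined$cw, grid$whisker)
  joined$dx <- grid$x[wi] - grid$x[ci]
  joined$dy <- grid$y[wi] - grid$y[ci]
  joined$target_dx <- grid$x[ai] - grid$x[ci]
  joined$target_dy <- grid$y[ai] - grid$y[ci]
  joined <- dplyr::filter(
    joined,
    abs(.data$dx) <= 1, abs(.data$dy) <= 1,
    abs(.data$target_dx) <= 1, abs(.data$target_dy) <= 1,
    !(.data$target_dx == 0 & .data$target_dy == 0)
  )
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$cell_id, .data$target_dx, .data$target_dy,
                    .data$dx, .data$dy),
    value = mean(.data$evoked),
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, sampled = .data$n >= min_trials)
}

#' Best whisker of a receptive field
#'
#' The sampled offset with the numerically highest response. Exact ties are
#' broken row-major (upper rows first, then caudal to rostral) and flagged.
#'
#' @param rf Receptive-field tibble (`dx`, `dy`, `value`, `sampled`).
#' @return One-row tibble (`dx`, `dy`, `value`, `tie`).
#' @export
best_whisker <- function(rf) {
  rf <- dplyr::filter(rf, .data$sampled)
  if (nrow(rf) == 0) {
    abort("No sampled positions.", class = "wa_insufficient_data")
  }
  rf <- dplyr::arrange(rf, dplyr::desc(.data$value), dplyr::desc(.data$dy),
                       .data$dx)
  tie <- nrow(rf) > 1 && rf$value[2] == rf$value[1]
  tibble::tibble(dx = rf$dx[1], dy = rf$dy[1], value = rf$value[1],
                 tie = tie)
}

#' Receptive-field centre of mass
#'
#' Response-weighted mean offset over sampled positions. Negative responses
#' are clipped at zero for weighting (the centre of mass of a signed field
#' is ill-defined); if everything clips to zero the CoM is undefined.
#'
#' @param rf Receptive-field tibble (`dx`, `dy`, `value`, `sampled`).
#' @return One-row tibble (`x`, `y`, `clipped` = number of clipped
#'   positions).
#' @export
rf_com <- function(rf) {
  rf <- dplyr::filter(rf, .data$sampled)
  w <- pmax(rf$value, 0)
  if (nrow(rf) == 0 || sum(w) <= 0) {
    abort("Nonpositive total weight; centre of mass undefined.",
          class = "wa_undefined_com")
  }
  tibble::tibble(
    x = sum(w * rf$dx) / sum(w),
    y = sum(w * rf$dy) / sum(w),
    clipped = sum(rf$value < 0)
  )
}

#' Receptive-field shift along the attention axis
#'
#' Projects the displacement of the receptive-field centre of mass between
#' the baseline (prior NoGo) and attended (prior >1 hit) conditions onto the
#' attention axis - the line from the CW position (origin) to the attended
#' whisker's offset - and normalizes by the CW-to-target distance. Positive
#' shifts are toward the attended whisker. Only offsets sampled in both
#' conditions contribute to either CoM, and at least `min_shared` of the 9
#' positions must be shared.
#'
#' @param rf_nogo,rf_attend Receptive-field tibbles for the two conditions.
#' @param target_offset Numeric `c(dx, dy)` of the attended whisker.
#' @param min_shared Minimum shared sampled positions (default 6).
#' @return One-row tibble (`shift`, `com_nogo_x/y`, `com_attend_x/y`,
#'   `n_shared`, `excluded`, `reason`). When the coverage rule fails the row
#'   is returned with `excluded = TRUE` and NA shift.
#' @export
rf_shift <- function(rf_nogo, rf_attend, target_offset, min_shared = 6) {
  stopifnot(length(target_offset) == 2)
  # match sampled offsets of both conditions on a compact integer key
  kn <- rf_nogo$dx * 3L + rf_nogo$dy
  ka <- rf_attend$dx * 3L + rf_attend$dy
  ns <- which(rf_nogo$sampled)
  as <- which(rf_attend$sampled)[match(kn[rf_nogo$sampled], ka[rf_attend$sampled])]
  keep <- !is.na(as)
  ns <- ns[keep]
  as <- as[keep]
  empty <- tibble::tibble(
    shift = NA_real_, com_nogo_x = NA_real_, com_nogo_y = NA_real_,
    com_attend_x = NA_real_, com_attend_y = NA_real_,
    n_shared = length(ns), excluded = TRUE, reason = NA_character_
  )
  if (length(ns) < min_shared) {
    empty$reason <- "coverage"
    return(empty)
  }
  dx <- rf_nogo$dx[ns]
  dy <- rf_nogo$dy[ns]
  wn <- pmax(rf_nogo$value[ns], 0)
  wa <- pmax(rf_attend$value[as], 0)
  if (sum(wn) <= 0 || sum(wa) <= 0) {
    empty$reason <- "nonpositive_weight"
    return(empty)
  }
  com_n <- c(sum(wn * dx), sum(wn * dy)) / sum(wn)
  com_a <- c(sum(wa * dx), sum(wa * dy)) / sum(wa)
  norm <- sqrt(sum(target_offset^2))
  u <- target_offset / norm
  tibble::tibble(
    shift = sum((com_a - com_n) * u) / norm,
    com_nogo_x = com_n[1], com_nogo_y = com_n[2],
    com_attend_x = com_a[1], com_attend_y = com_a[2],
    n_shared = length(ns), excluded = FALSE, reason = NA_character_
  )
}

#' Per-cell receptive-field shift averaged over attended targets
#'
#' Computes [rf_shift()] for every attended-whisker target available for a
#' cell and averages the shifts (each target weighted equally) into a single
#' per-cell metric.
#'
#' @param rf_nogo Long tibble of baseline receptive fields
#'   ([cell_receptive_fields()] restricted to `priorNoGo`).
#' @param rf_attended Long tibble from [attended_receptive_fields()].
#' @param min_shared Coverage rule passed to [rf_shift()].
#' @return Tibble with one row per cell (`cell_id`, `shift`,
#'   `n_targets`, `n_excluded`); cells with no usable target have NA shift.
#' @export
rf_shift_by_cell <- function(rf_nogo, rf_attended, min_shared = 6) {
  nogo_by_cell <- split(rf_nogo, rf_nogo$cell_id)
  attended_by_cell <- split(rf_attended, rf_attended$cell_id)
  rows <- purrr::map(names(nogo_by_cell), function(cid) {
    rfa_cell <- attended_by_cell[[cid]]
    if (is.null(rfa_cell)) return(NULL)
    by_target <- split(rfa_cell,
                       paste(rfa_cell$target_dx, rfa_cell$target_dy))
    shifts <- purrr::map(by_target, function(rfa) {
      rf_shift(nogo_by_cell[[cid]], rfa,
               c(rfa$target_dx[1], rfa$target_dy[1]),
               min_shared = min_shared)
    })
    shifts <- dplyr::bind_rows(shifts)
    ok <- !shifts$excluded
    tibble::tibble(
      cell_id = cid,
      shift = if (any(ok)) mean(shifts$shift[ok]) else NA_real_,
      n_targets = sum(ok),
      n_excluded = sum(!ok)
    )
  })
  dplyr::bind_rows(rows)
}

#' Response modulation indices for CW and surround whiskers
#'
#' Normalized change of the columnar-whisker (CW) and surround-whisker (SW)
#' responses when attention is directed to the CW, plus the CW-preference
#' index in each condition:
#' `RMI = (X_attend - X_nogo) / |X_attend + X_nogo|` for X = CW, SW and
#' `CW preference = (CW - SW) / |CW + SW|` within each condition.
#'
#' @param cw_attend,cw_nogo Mean CW response under prior >1 hit to the CW
#'   and under prior NoGo.
#' @param sw_attend,sw_nogo Mean response of the selected surround whiskers
#'   in the two conditions.
#' @param eps Denominator tolerance.
#' @return One-row tibble (`rmi_cw`, `rmi_sw`, `cw_preference_attend`,
#'   `cw_preference_nogo`, `valid`).
#' @export
rf_modulation <- function(cw_attend, cw_nogo, sw_attend, sw_nogo,
                          eps = 1e-6) {
  out <- tibble::tibble(
    rmi_cw = modulation_index(cw_attend, cw_nogo, eps),
    rmi_sw = modulation_index(sw_attend, sw_nogo, eps),
    cw_preference_attend = modulation_index(cw_attend, sw_attend, eps),
    cw_preference_nogo = modulation_index(cw_nogo, sw_nogo, eps)
  )
  out$valid <- !anyNA(out[1, ])
  out
}

#' Response modulation indices from a pair of receptive fields
#'
#' Derives the CW response (offset (0,0)) and the mean of the three
#' strongest surround whiskers - selected from the baseline (prior NoGo)
#' receptive field among offsets sampled in both conditions, ties broken
#' row-major - then computes [rf_modulation()].
#'
#' @param rf_attend,rf_nogo Receptive-field tibbles (`dx`, `dy`, `value`,
#'   `sampled`) for prior >1 hit to the CW and prior NoGo.
#' @param n_sw Number of surround whiskers (default 3).
#' @param eps Denominator tolerance.
#' @return As [rf_modulation()], with the selected SW offsets in attribute
#'   `sw_offsets`.
#' @export
rf_modulation_from_rfs <- function(rf_attend, rf_nogo, n_sw = 3,
                                   eps = 1e-6) {
  shared <- dplyr::inner_join(
    dplyr::filter(rf_nogo, .data$sampled),
    dplyr::filter(rf_attend, .data$sampled),
    by = c("dx", "dy"), suffix = c("_nogo", "_attend")
  )
  cw <- dplyr::filter(shared, .data$dx == 0, .data$dy == 0)
  sws <- dplyr::filter(shared, !(.data$dx == 0 & .data$dy == 0))
  if (nrow(cw) == 0 || nrow(sws) < n_sw) {
    abort("CW and at least `n_sw` shared surround whiskers are required.",
          class = "wa_insufficient_data")
  }
  sws <- dplyr::arrange(sws, dplyr::desc(.data$value_nogo),
                        dplyr::desc(.data$dy), .data$dx)
  top <- sws[seq_len(n_sw), ]
  out <- rf_modulation(cw$value_attend, cw$value_nogo,
                       mean(top$value_attend), mean(top$value_nogo),
                       eps = eps)
  attr(out, "sw_offsets") <- dplyr::select(top, "dx", "dy")
  out
}
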