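#' Neural generator configuration
#'
#' Parameters of the synthetic population generator. Cells are scattered
#' uniformly over the imaged map, tuned to whiskers by a Gaussian of the
#' distance between the cell and each whisker's column centroid, and respond
#' on each trial with `gain * tuning + noise`. Attentional gain after prior
#' hit(s) to whisker `a` is multiplicative and either whisker-specific
#' (`gain_whisker_specific = TRUE`, PYR-like: responses to `a` itself are
#' boosted, for cells within `gain_space_halfwidth` column widths of `a`'s
#' centroid and in the layers in `layers_with_gain` - a somatotopic
#' spotlight that also pulls receptive fields toward the attended whisker)
#' or non-specific (VIP-like: every cell is boosted after any prior hit,
#' whatever the stimulus).
#'
#' @param n_cells Number of cells.
#' @param cell_class `"PYR"` or `"VIP"` (bookkeeping; VIP defaults pair with
#'   `gain_whisker_specific = FALSE`).
#' @param tuning_width Gaussian tuning width in column widths.
#' @param peak_response Peak evoked response (dF/F units).
#' @param noise_sd Trial-to-trial Gaussian noise SD (same units).
#' @param attentional_gain Multiplicative gain (>= 0) after >1 prior hits.
#' @param gain_run1_scale Fraction of the full gain applied after a single
#'   prior hit (gain = `1 + (attentional_gain - 1) * gain_run1_scale`).
#' @param gain_space_halfwidth Spotlight half-width in column widths.
#' @param gain_whisker_specific Spatially targeted (PYR-like) vs non-specific
#'   (VIP-like) gain.
#' @param field_center Whisker label at the centre of the imaged field, or
#'   `NULL` (default) to scatter cells over the whole grid. Real imaging
#'   fields span roughly 1-1.5 columns, which concentrates the population on
#'   one whisker's representation.
#' @param field_halfwidth Half-width of the imaged field in column widths
#'   (used only with `field_center`).
#' @param layers,layer_probs Layer labels and sampling probabilities.
#' @param layers_with_gain Layers receiving the whisker-specific gain.
#' @param vip_baseline_amp,vip_baseline_tau Amplitude (dF/F) and decay time
#'   constant (s) of the declining post-reward baseline added to VIP traces.
#' @param frame_rate Imaging frame rate (Hz).
#' @return A list of class `wa_neural_config`.
#' @export
neural_config <- function(n_cells = 150,
                          cell_class = c("PYR", "VIP"),
                          tuning_width = 0.6,
                          peak_response = 1,
                          noise_sd = 0.3,
                          attentional_gain = 2,
                          gain_run1_scale = 0.5,
                          gain_space_halfwidth = 0.75,
                          gain_whisker_specific = cell_class[1] == "PYR",
                          field_center = NULL,
                          field_halfwidth = 0.75,
                          layers = c("L2/3", "L4", "L5"),
                          layer_probs = c(0.6, 0.2, 0.2),
                          layers_with_gain = c("L2/3", "L5"),
                          vip_baseline_amp = 0.3,
                          vip_baseline_tau = 3,
                          frame_rate = 7.5) {
  cell_class <- match.arg(cell_class)
  check_number(n_cells, "n_cells", min = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(attentional_gain, "attentional_gain", min = 0)
  check_number(gain_space_halfwidth, "gain_space_halfwidth", min = 1e-9)
  structure(
    list(
      n_cells = as.integer(n_cells), cell_class = cell_class,
      tuning_width = tuning_width, peak_response = peak_response,
      noise_sd = noise_sd, attentional_gain = attentional_gain,
      gain_run1_scale = gain_run1_scale,
      gain_space_halfwidth = gain_space_halfwidth,
      gain_whisker_specific = gain_whisker_specific,
      field_center = field_center, field_halfwidth = field_halfwidth,
      layers = layers, layer_probs = layer_probs,
      layers_with_gain = layers_with_gain,
      vip_baseline_amp = vip_baseline_amp,
      vip_baseline_tau = vip_baseline_tau,
      frame_rate = frame_rate
    ),
    class = "wa_neural_config"
  )
}

#' Simulate a neural population responding to a session
#'
#' Places cells over the cortical map, assigns columns (centroid containment;
#' cells outside every barrel are septal with the nearest column as their
#' columnar whisker), and generates per-trial evoked responses with
#' history-dependent multiplicative gain per [neural_config()]. NoGo trials
#' carry noise only. Ground-truth per-trial, per-cell gains are emitted so
#' recovery tests compare estimates against stored truth.
#'
#' @param session A session tibble (with its grid attached).
#' @param config A [neural_config()].
#' @param seed Integer seed.
#' @param reward_threshold_fraction Passed to [classify_history()] (with
#'   `low_reward_as = "miss"`) to determine which hits cue gain; defaults to
#'   the session generator's threshold when available.
#' @return List of class `wa_population`: `cells` (one row per cell),
#'   `responses` (long tibble `trial_index`, `cell_id`, `evoked`, `gain`),
#'   `labels` (the labelled session), plus the config and grid.
#' @export
simulate_population <- function(session, config = neural_config(), seed = 1,
                                reward_threshold_fraction = NULL) {
  grid <- attr(session, "grid")
  stopifnot(inherits(config, "wa_neural_config"), inherits(grid, "wa_grid"))
  if (is.null(reward_threshold_fraction)) {
    scfg <- attr(session, "config")
    reward_threshold_fraction <-
      if (!is.null(scfg)) scfg$reward_threshold_fraction else 0
  }
  labels <- classify_history(
    session, grid,
    mode = "consecutive",
    reward_threshold_fraction = reward_threshold_fraction,
    low_reward_as = "miss"
  )
  width <- attr(grid, "barrel_width_um")
  sigma <- config$tuning_width * width

  withr::with_seed(seed, {
    nc <- config$n_cells
    if (!is.null(config$field_center)) {
      fi <- match(config$field_center, grid$whisker)
      if (is.na(fi)) {
        abort("`field_center` is not a whisker of the grid.",
              class = "wa_config")
      }
      half <- config$field_halfwidth * width
      cx_range <- grid$cx_um[fi] + c(-half, half)
      cy_range <- grid$cy_um[fi] + c(-half, half)
    } else {
      pad <- width / 2
      cx_range <- range(grid$cx_um) + c(-pad, pad)
      cy_range <- range(grid$cy_um) + c(-pad, pad)
    }
    cells <- tibble::tibble(
      cell_id = sprintf("c%04d", seq_len(nc)),
      x_um = runif(nc, cx_range[1], cx_range[2]),
      y_um = runif(nc, cy_range[1], cy_range[2]),
      depth_um = runif(nc, 110, 250),
      cell_class = config$cell_class,
      layer = sample(config$layers, nc, replace = TRUE,
                     prob = config$layer_probs)
    )
    # distance of each cell to each whisker centroid (cells x whiskers)
    dmat <- outer(cells$x_um, grid$cx_um, "-")^2 +
      outer(cells$y_um, grid$cy_um, "-")^2
    dmat <- sqrt(dmat)
    colnames(dmat) <- grid$whisker
    nearest <- max.col(-dmat, ties.method = "first")
    cells$cw <- grid$whisker[nearest]
    in_barrel <- dmat[cbind(seq_len(nc), nearest)] <= width / 2
    cells$column <- ifelse(in_barrel, cells$cw, "septal")
    tuning <- config$peak_response * exp(-dmat^2 / (2 * sigma^2))

    nt <- nrow(labels)
    attended <- ifelse(labels$run_length >= 1, labels$prior_whisker,
                       NA_character_)
    gain_level <- ifelse(
      is.na(attended), 1,
      1 + (config$attentional_gain - 1) *
        ifelse(labels$run_length >= 2, 1, config$gain_run1_scale)
    )
    eligible <- matrix(FALSE, nrow = nt, ncol = nc)
    if (config$gain_whisker_specific) {
      # spotlight: boost responses to the attended whisker, for cells within
      # the spotlight around its column, in the gain-bearing layers
      in_spot <- dmat <= config$gain_space_halfwidth * width  # cells x whiskers
      a_idx <- match(attended, grid$whisker)
      layer_ok <- cells$layer %in% config$layers_with_gain
      hit_stim <- which(!is.na(a_idx) & labels$whisker == attended)
      for (t in hit_stim) {
        eligible[t, ] <- in_spot[, a_idx[t]] & layer_ok
      }
    } else {
      # VIP-like: any prior hit boosts every cell, whatever the stimulus
      eligible[!is.na(attended), ] <- TRUE
    }
    gain <- 1 + (gain_level - 1) * eligible  # trials x cells

    w_idx <- match(labels$whisker, grid$whisker)
    base <- matrix(0, nrow = nt, ncol = nc)
    go <- !is.na(w_idx)
    base[go, ] <- t(tuning[, w_idx[go], drop = FALSE])
    evoked <- gain * base +
      matrix(rnorm(nt * nc, sd = config$noise_sd), nrow = nt)

    responses <- tibble::tibble(
      trial_index = rep(labels$trial_index, times = nc),
      cell_id = rep(cells$cell_id, each = nt),
      evoked = as.vector(evoked),
      gain = as.vector(gain)
    )
    structure(
      list(cells = cells, responses = responses, labels = labels,
           config = config, grid = grid, seed = as.integer(seed)),
      class = "wa_population"
    )
  })
}

#' Reshape long responses to a trial x cell matrix
#'
#' @param responses Long response tibble (`trial_index`, `cell_id`,
#'   `evoked`).
#' @return Numeric matrix, rows named by trial index, columns by cell id.
#' @export
response_matrix <- function(responses) {
  wide <- tidyr::pivot_wider(
    dplyr::select(responses, "trial_index", "cell_id", "evoked"),
    names_from = "cell_id", values_from = "evoked"
  )
  m <- as.matrix(dplyr::select(wide, -"trial_index"))
  rownames(m) <- wide$trial_index
  m
}

#' Simulate peri-stimulus fluorescence traces with history-dependent baseline
#'
#' Emits frame-resolved dF/F traces around each trial's stimulus onset:
#' a declining post-reward baseline (amplitude `vip_baseline_amp`, time
#' constant `vip_baseline_tau`, present only when the previous trial was
#' rewarded), an evoked transient on Go trials, and Gaussian noise. Used to
#' exercise per-condition linear baseline detrending.
#'
#' @param session Session tibble.
#' @param config A [neural_config()].
#' @param seed Integer seed.
#' @param evoked_amp Evoked transient amplitude (dF/F).
#' @param noise_sd Frame noise SD.
#' @param window Trace window relative to onset (seconds).
#' @return List with `times` (frame times, s) and `traces` (trials x frames
#'   matrix), plus the labelled session as `labels`.
#' @export
simulate_trial_traces <- function(session, config = neural_config(cell_class = "VIP"),
                                  seed = 1, evoked_amp = 0.5,
                                  noise_sd = 0.02, window = c(-1.2, 1.1)) {
  grid <- attr(session, "grid")
  labels <- classify_history(session, grid, mode = "consecutive")
  dt <- 1 / config$frame_rate
  times <- seq(window[1], window[2], by = dt)
  nt <- nrow(labels)
  prev_rewarded <- c(FALSE, head(labels$outcome == "Hit" &
                                   labels$reward_ul > 0, -1))
  prev_onset <- c(NA_real_, head(labels$onset_time_s, -1))
  withr::with_seed(seed, {
    traces <- matrix(rnorm(nt * length(times), sd = noise_sd), nrow = nt)
    for (t in seq_len(nt)) {
      if (prev_rewarded[t]) {
        elapsed <- labels$onset_time_s[t] + times - prev_onset[t]
        traces[t, ] <- traces[t, ] + config$vip_baseline_amp *
          exp(-pmax(elapsed, 0) / config$vip_baseline_tau)
      }
      if (labels$kind[t] == "Go") {
        ev <- times >= 0 & times < 0.799
        traces[t, ev] <- traces[t, ev] + evoked_amp
      }
    }
    list(times = times, traces = traces, labels = labels)
  })
}

#' Simulate spike trains for one stimulus condition
#'
#' Inhomogeneous Poisson spike trains: a constant baseline rate plus brief
#' rate elevations after each deflection of the stimulus train (five
#' deflections at 100 ms spacing by default).
#'
#' @param n_trials Number of trials.
#' @param baseline_hz Baseline rate.
#' @param evoked_hz Added rate during the `evoked_dur` after each deflection.
#' @param deflection_times Deflection onset times (s); `numeric(0)` for a
#'   stimulus-free condition.
#' @param evoked_dur Duration of each evoked elevation (s).
#' @param window Spike window (s, relative to stimulus onset).
#' @param seed Integer seed.
#' @return List of per-trial spike-time vectors (seconds).
#' @export
simulate_spike_trains <- function(n_trials, baseline_hz = 5, evoked_hz = 40,
                                  deflection_times = seq(0, 0.4, by = 0.1),
                                  evoked_dur = 0.03,
                                  window = c(-0.5, 1), seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n_trials), function(i) {
      n_base <- rpois(1, baseline_hz * diff(window))
      spikes <- runif(n_base, window[1], window[2])
      for (d in deflection_times) {
        n_ev <- rpois(1, evoked_hz * evoked_dur)
        spikes <- c(spikes, runif(n_ev, d, d + evoked_dur))
      }
      sort(spikes)
    })
  })
}
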