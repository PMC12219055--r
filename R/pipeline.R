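session_columns <- c(
  "trial_index", "onset_time_s", "kind", "whisker", "amplitude_um",
  "outcome", "reward_ul", "first_lick_latency_s", "aborted"
)

validate_session <- function(trials) {
  missing <- setdiff(session_columns, names(trials))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "wa_validation")
  }
  bad <- which(diff(trials$onset_time_s) <= 0)
  if (length(bad)) {
    abort(sprintf("Onset times not strictly increasing at row %d.",
                  bad[1] + 1L),
          class = "wa_validation")
  }
  bad <- which(trials$kind == "Go" & is.na(trials$whisker) |
                 trials$kind == "NoGo" & !is.na(trials$whisker))
  if (length(bad)) {
    abort(sprintf("Row %d: `whisker` must be set iff `kind` is Go.", bad[1]),
          class = "wa_validation")
  }
  bad <- which(trials$kind == "Go" & !trials$outcome %in% c("Hit", "Miss") |
                 trials$kind == "NoGo" & !trials$outcome %in% c("FA", "CR"))
  if (length(bad)) {
    abort(sprintf("Row %d: outcome '%s' invalid for kind '%s'.",
                  bad[1], trials$outcome[bad[1]], trials$kind[bad[1]]),
          class = "wa_validation")
  }
  invisible(trials)
}

#' Read and write session trial tables
#'
#' Sessions are stored as plain delimited text with the fixed column set
#' `trial_index, onset_time_s, kind, whisker, amplitude_um, outcome,
#' reward_ul, first_lick_latency_s, aborted` (missing values empty; ground
#' truth columns `gt_*` are preserved when present). Reading validates the
#' schema - monotone onsets, Go trials iff a whisker is set, outcome domain
#' per kind - and reports the offending row on failure.
#'
#' @param session Session tibble.
#' @param path CSV file path.
#' @param grid Grid to attach on read (default [whisker_grid()]).
#' @return `read_session()` returns a `wa_session` tibble; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  readr::write_csv(session, path, na = "")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, grid = whisker_grid()) {
  trials <- readr::read_csv(path, show_col_types = FALSE, na = "",
                            progress = FALSE)
  trials$whisker <- as.character(trials$whisker)
  validate_session(trials)
  out <- tibble::new_tibble(trials, class = "wa_session")
  attr(out, "grid") <- grid
  out
}

#' Read and write long response tables
#'
#' The response container is a delimited long table
#' (`trial_index, cell_id, evoked`, plus extra columns such as ground-truth
#' `gain`). Reading checks referential integrity against a cell table when
#' one is supplied.
#'
#' @param responses Long response tibble.
#' @param path CSV file path.
#' @param cells Optional cell table for referential-integrity checking.
#' @return `read_responses()` returns a tibble; `write_responses()` returns
#'   `path` invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, cells = NULL) {
  responses <- readr::read_csv(path, show_col_types = FALSE, na = "",
                               progress = FALSE)
  if (!is.null(cells)) {
    unknown <- setdiff(unique(responses$cell_id), cells$cell_id)
    if (length(unknown)) {
      abort(paste0("Unknown cell_id(s) in responses: ",
                   paste(head(unknown, 3), collapse = ", ")),
            class = "wa_validation")
    }
  }
  responses
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings with a single master seed; each stochastic
#' stage receives a seed derived from it through a fixed counter scheme, so
#' the manifest's seeds reproduce every output exactly.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param behavior A [behavior_config()].
#' @param neural A [neural_config()].
#' @param grid A [whisker_grid()].
#' @param engagement List with `window` and `cutoff` for
#'   [trim_to_engagement()].
#' @param reward_threshold_fraction Passed to [classify_history()].
#' @param stats List with `n_iterations` (permutation iterations) and
#'   `alpha`.
#' @param decoder List with `enabled`, `n_iterations` (balancing
#'   iterations) and `min_per_class`.
#' @return List of class `wa_run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("wa_run_"),
                            behavior = behavior_config(),
                            neural = neural_config(),
                            grid = whisker_grid(),
                            engagement = list(window = 50, cutoff = 0.5),
                            reward_threshold_fraction = 0.04,
                            stats = list(n_iterations = 1000, alpha = 0.05),
                            decoder = list(enabled = TRUE, n_iterations = 5,
                                           min_per_class = 5)) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, behavior = behavior,
         neural = neural, grid = grid, engagement = engagement,
         reward_threshold_fraction = reward_threshold_fraction,
         stats = stats, decoder = decoder),
    class = "wa_run_config"
  )
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes simulate, behaviour, neural, receptive-field, decoding and
#' reporting stages in order, writing every metric table as delimited text
#' plus a JSON manifest (config hash, derived seeds, per-stage record
#' counts, package version) to `config$out_dir`. Identical (config, seed)
#' runs produce byte-identical outputs. A stage failure halts the run with
#' the stage name; tables already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's tables and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "wa_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(
    package = "whiskattn",
    version = as.character(utils::packageVersion("whiskattn")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages = list(),
    counts = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "wa_stage_failure", parent = e)
    })
  }
  seeds <- list(simulate = derive_seed(config$seed, 11),
                neural = derive_seed(config$seed, 12),
                decoder = derive_seed(config$seed, 13))
  manifest$seeds <- seeds

  # simulate
  session <- stage("simulate", {
    s <- simulate_session(config$behavior, config$grid,
                          seed = seeds$simulate)
    write_session(s, file.path(config$out_dir, "session.csv"))
    s
  })
  out$session <- session
  manifest$stages$simulate <- "complete"
  manifest$counts$n_trials <- nrow(session)

  # behaviour
  beh <- stage("behavior", {
    trimmed <- trim_to_engagement(session,
                                  window = config$engagement$window,
                                  cutoff = config$engagement$cutoff)
    labels <- classify_history(
      trimmed, config$grid,
      reward_threshold_fraction = config$reward_threshold_fraction
    )
    hsdt <- history_sdt(labels)
    readr::write_csv(hsdt, file.path(config$out_dir, "history_sdt.csv"))
    sg <- tryCatch(spatial_gradient(labels),
                   wa_insufficient_data = function(e) NULL)
    if (!is.null(sg)) {
      readr::write_csv(sg, file.path(config$out_dir,
                                     "spatial_gradient.csv"))
    }
    labels_ig <- classify_history(
      trimmed, config$grid, mode = "ignore-nogo",
      reward_threshold_fraction = config$reward_threshold_fraction
    )
    tp <- tryCatch(temporal_profile(labels_ig),
                   wa_insufficient_data = function(e) NULL)
    if (!is.null(tp) && nrow(tp)) {
      readr::write_csv(tp, file.path(config$out_dir,
                                     "temporal_profile.csv"))
    }
    list(trimmed = trimmed, labels = labels, history_sdt = hsdt,
         spatial_gradient = sg, temporal_profile = tp)
  })
  out <- c(out, beh)
  manifest$stages$behavior <- "complete"
  manifest$counts$n_engaged_trials <- nrow(beh$trimmed)

  # neural
  pop <- stage("neural", {
    p <- simulate_population(beh$trimmed, config$neural,
                             seed = seeds$neural)
    readr::write_csv(p$cells, file.path(config$out_dir, "cells.csv"))
    write_responses(p$responses,
                    file.path(config$out_dir, "responses.csv"))
    p
  })
  ami <- stage("neural", {
    a <- ami_by_cell(pop$responses, pop$labels)
    readr::write_csv(a, file.path(config$out_dir, "ami.csv"))
    a
  })
  out$population <- pop
  out$ami <- ami
  manifest$stages$neural <- "complete"
  manifest$counts$n_cells <- nrow(pop$cells)
  manifest$counts$n_cells_ami_valid <- sum(ami$valid)

  # receptive fields
  rf <- stage("rf", {
    rfn <- cell_receptive_fields(pop$responses, pop$labels, pop$cells,
                                 config$grid, conditions = "priorNoGo")
    rfa <- attended_receptive_fields(pop$responses, pop$labels, pop$cells,
                                     config$grid)
    shifts <- rf_shift_by_cell(rfn, rfa)
    readr::write_csv(shifts, file.path(config$out_dir, "rf_shift.csv"))
    list(rf_nogo = rfn, rf_attended = rfa, shifts = shifts)
  })
  out$rf <- rf
  manifest$stages$rf <- "complete"
  manifest$counts$n_rf_cells <- sum(!is.na(rf$shifts$shift))

  # decoding
  if (isTRUE(config$decoder$enabled)) {
    dec <- stage("decode", {
      labels <- dplyr::filter(pop$labels, !.data$aborted)
      xmat <- response_matrix(
        dplyr::semi_join(pop$responses, labels, by = "trial_index")
      )
      xmat <- xmat[match(labels$trial_index, rownames(xmat)), ,
                   drop = FALSE]
      fbw <- field_best_whisker(pop$responses, labels, config$grid)
      model <- fit_decoder(xmat, labels$outcome, seed = seeds$decoder,
                           min_per_class = config$decoder$min_per_class)
      eval <- evaluate_decoder(
        xmat, labels, fbw$whisker,
        n_iterations = config$decoder$n_iterations, seed = seeds$decoder,
        min_per_class = config$decoder$min_per_class
      )
      readr::write_csv(eval, file.path(config$out_dir,
                                       "decoder_eval.csv"))
      readr::write_csv(tidy(model), file.path(config$out_dir,
                                              "decoder_weights.csv"))
      list(model = model, eval = eval, fbw = fbw)
    })
    out$decoder <- dec
    manifest$stages$decode <- "complete"
    manifest$counts$decoder_accuracy <- dec$model$accuracy
  }

  manifest$stages$report <- "complete"
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
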