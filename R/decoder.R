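#' Field best whisker
#'
#' The whisker evoking the numerically highest mean population response
#' across the given cells on Go trials. Exact ties are broken row-major
#' (grid order) and flagged.
#'
#' @param responses Long response tibble (`trial_index`, `cell_id`,
#'   `evoked`).
#' @param trials Session/labels tibble (for `whisker` per trial).
#' @param grid The session [whisker_grid()].
#' @param cell_ids Optional subset of cells (e.g. whisker-responsive ones).
#' @return One-row tibble (`whisker`, `mean_response`, `tie`).
#' @export
field_best_whisker <- function(responses, trials, grid, cell_ids = NULL) {
  go <- dplyr::filter(trials, .data$kind == "Go", !.data$aborted)
  joined <- dplyr::inner_join(
    responses, dplyr::select(go, "trial_index", "whisker"),
    by = "trial_index"
  )
  if (!is.null(cell_ids)) {
    joined <- dplyr::filter(joined, .data$cell_id %in% cell_ids)
  }
  means <- dplyr::summarise(
    dplyr::group_by(joined, .data$whisker),
    mean_response = mean(.data$evoked), .groups = "drop"
  )
  # row-major order = grid order
  means <- means[order(match(means$whisker, grid$whisker)), ]
  best <- which.max(means$mean_response)
  tie <- sum(means$mean_response == means$mean_response[best]) > 1
  tibble::tibble(whisker = means$whisker[best],
                 mean_response = means$mean_response[best], tie = tie)
}

# Stratified fold assignment: folds are balanced within each class so a
# held-out fold's composition does not anti-correlate with its training set.
stratified_folds <- function(y, n_folds, seed) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  foldid
}

# Undersample every outcome class to the size of the smallest one.
balance_classes <- function(outcome, seed) {
  counts <- table(outcome)
  n_min <- min(counts)
  withr::with_seed(seed, {
    idx <- unlist(lapply(names(counts), function(cl) {
      pool <- which(outcome == cl)
      sample(pool, n_min)
    }), use.names = FALSE)
  })
  sort(idx)
}

#' Fit a class-balanced ridge logistic stimulus decoder
#'
#' Predicts stimulus presence (Go vs NoGo) from single-trial population
#' activity with L2-penalized logistic regression. Trials are first
#' rebalanced by undersampling so every behavioural outcome class (Hit,
#' Miss, CR, FA) contributes equally; the ridge strength is chosen by
#' 10-fold cross-validated deviance over a logarithmic grid; performance is
#' reported from held-out (pre-validated) folds.
#'
#' @param x Trials x cells response matrix (rows follow `outcome`).
#' @param outcome Per-trial behavioural outcome (`Hit`, `Miss`, `FA`, `CR`).
#' @param seed Integer seed (balancing and fold assignment).
#' @param n_folds Cross-validation folds (default 10).
#' @param lambda_grid Ridge strengths; default 30 values spanning 6 decades.
#' @param min_per_class Minimum trials per outcome class (default 5); below
#'   it the session is not decodable and an error of class
#'   `wa_insufficient_data` is thrown.
#' @return Object of class `wa_decoder`: weights and intercept at the
#'   selected lambda, fold assignment, balanced trial indices, held-out
#'   probabilities and accuracy.
#' @export
fit_decoder <- function(x, outcome, seed = 1, n_folds = 10,
                        lambda_grid = 10^seq(2, -4, length.out = 30),
                        min_per_class = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(outcome))
  outcome <- as.character(outcome)
  counts <- table(factor(outcome, levels = c("Hit", "Miss", "FA", "CR")))
  if (any(counts < min_per_class)) {
    abort(
      paste0("Outcome class below minimum count: ",
             paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
      class = "wa_insufficient_data"
    )
  }
  idx <- balance_classes(outcome, seed)
  xb <- x[idx, , drop = FALSE]
  yb <- as.integer(outcome[idx] %in% c("Hit", "Miss"))  # stimulus present
  foldid <- stratified_folds(yb, n_folds, derive_seed(seed, 1))
  cv <- glmnet::cv.glmnet(xb, yb, family = "binomial", alpha = 0,
                          lambda = lambda_grid, foldid = foldid,
                          type.measure = "deviance", keep = TRUE,
                          standardize = TRUE)
  j <- match(cv$lambda.min, cv$lambda)
  prob_heldout <- as.numeric(stats::plogis(cv$fit.preval[, j]))
  co <- as.numeric(coef(cv, s = "lambda.min"))
  structure(
    list(
      cell_ids = colnames(x) %||% paste0("cell", seq_len(ncol(x))),
      weights = co[-1],
      intercept = co[1],
      ridge_strength = cv$lambda.min,
      fold_assignment = set_names(foldid, idx),
      balanced_idx = idx,
      prob_heldout = prob_heldout,
      accuracy = mean((prob_heldout > 0.5) == yb),
      glmnet_fit = cv$glmnet.fit,
      lambda_grid = lambda_grid,
      seed = as.integer(seed)
    ),
    class = "wa_decoder"
  )
}

#' @method print wa_decoder
#' @export
print.wa_decoder <- function(x, ...) {
  cat(sprintf(
    "<wa_decoder> %d cells, %d balanced trials, lambda = %.4g, held-out accuracy = %.3f\n",
    length(x$weights), length(x$balanced_idx), x$ridge_strength, x$accuracy
  ))
  invisible(x)
}

#' @rdname fit_decoder
#' @param x A `wa_decoder`.
#' @param ... Unused.
#' @export
tidy.wa_decoder <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_ids, weight = x$weights)
}

#' @rdname fit_decoder
#' @export
glance.wa_decoder <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$weights),
    n_balanced_trials = length(x$balanced_idx),
    ridge_strength = x$ridge_strength,
    accuracy = x$accuracy,
    seed = x$seed
  )
}

#' Evaluate decoder performance by trial filter and history condition
#'
#' Repeats the class-balanced fit over `n_iterations` resampling iterations
#' and measures, for each combination of current-trial filter (any Go, field
#' best whisker Go, non-fBW Go, NoGo) and history category, the average
#' fraction of trials the decoder classifies as containing a stimulus. On
#' every iteration, trials inside the balanced sample are scored from their
#' held-out fold (pre-validated predictions) and trials outside it from the
#' full balanced fit, so no trial is ever scored by a model that trained on
#' it. Balanced class counts and fold disjointness are asserted each
#' iteration. A shuffled-label control is run with the same scheme.
#'
#' @param x Trials x cells response matrix.
#' @param trials Labelled trials tibble aligned with `x` rows (`outcome`,
#'   `kind`, `whisker`, `category`).
#' @param fbw Field best whisker label (see [field_best_whisker()]).
#' @param n_iterations Resampling iterations (default 25).
#' @param seed Integer seed.
#' @param threshold Stimulus-call threshold on the logistic output.
#' @param categories History categories to report.
#' @inheritParams fit_decoder
#' @return Tibble per (filter x category): `fraction_called`,
#'   `shuffled_control`, `n_trials`, `n_iterations`.
#' @export
evaluate_decoder <- function(x, trials, fbw, n_iterations = 25, seed = 1,
                             threshold = 0.5,
                             categories = c("priorNoGo", "priorGT1HitSame",
                                            "priorGT1HitDiff"),
                             lambda_grid = 10^seq(2, -4, length.out = 30),
                             n_folds = 10, min_per_class = 5) {
  stopifnot(nrow(x) == nrow(trials))
  outcome <- trials$outcome
  called <- matrix(NA_real_, nrow = n_iterations, ncol = nrow(x))
  called_shuf <- called
  one_pass <- function(oc, it_seed) {
    idx <- balance_classes(oc, it_seed)
    # balanced resample: equal counts per outcome class, asserted
    stopifnot(length(unique(table(oc[idx]))) == 1)
    xb <- x[idx, , drop = FALSE]
    yb <- as.integer(oc[idx] %in% c("Hit", "Miss"))
    foldid <- stratified_folds(yb, n_folds, derive_seed(it_seed, 1))
    cv <- glmnet::cv.glmnet(xb, yb, family = "binomial", alpha = 0,
                            lambda = lambda_grid, foldid = foldid,
                            type.measure = "deviance", keep = TRUE,
                            standardize = TRUE)
    j <- match(cv$lambda.min, cv$lambda)
    prob <- rep(NA_real_, nrow(x))
    prob[idx] <- stats::plogis(cv$fit.preval[, j])
    out_idx <- setdiff(seq_len(nrow(x)), idx)
    # fold disjointness: held-out trials are not in the balanced sample
    stopifnot(length(intersect(out_idx, idx)) == 0)
    if (length(out_idx)) {
      prob[out_idx] <- as.numeric(predict(
        cv$glmnet.fit, newx = x[out_idx, , drop = FALSE],
        s = cv$lambda.min, type = "response"
      ))
    }
    as.numeric(prob > threshold)
  }
  for (it in seq_len(n_iterations)) {
    called[it, ] <- one_pass(outcome, derive_seed(seed, 100 + it))
    shuffled <- withr::with_seed(derive_seed(seed, 200 + it),
                                 sample(outcome))
    called_shuf[it, ] <- one_pass(shuffled, derive_seed(seed, 300 + it))
  }
  frac <- colMeans(called)
  frac_shuf <- colMeans(called_shuf)

  is_go <- trials$kind == "Go"
  filters <- list(
    any = is_go,
    fBW = is_go & trials$whisker == fbw,
    `non-fBW` = is_go & trials$whisker != fbw,
    NoGo = !is_go
  )
  rows <- purrr::imap(filters, function(sel, fname) {
    purrr::map(categories, function(cat) {
      m <- which(sel & trials$category == cat & !trials$aborted)
      if (length(m) == 0) return(NULL)
      tibble::tibble(
        filter = fname, category = cat,
        fraction_called = mean(frac[m]),
        shuffled_control = mean(frac_shuf[m]),
        n_trials = length(m),
        n_iterations = as.integer(n_iterations)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
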