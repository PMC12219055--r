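#' History-conditioned signal detection metrics
#'
#' For each Go trial-history category, computes the hit rate from Go trials
#' with that history and the false-alarm rate from the matched NoGo-history
#' pool (same/different collapsed for NoGo trials), then d' and criterion,
#' plus the change relative to the `priorNoGo` baseline.
#'
#' @param labeled A session labelled by [classify_history()] (typically after
#'   [trim_to_engagement()]).
#' @param min_go,min_nogo Minimum trial counts per condition; categories below
#'   threshold are omitted with a message.
#' @param correction Extreme-rate correction passed to [compute_sdt()].
#' @return Tibble with one row per reportable Go category: counts, rates,
#'   `d_prime`, `criterion`, `delta_d`, `delta_c` (relative to `priorNoGo`)
#'   and `median_lick_latency_s` over hits in the category.
#' @export
history_sdt <- function(labeled, min_go = 5, min_nogo = 5,
                        correction = "log-linear") {
  active <- dplyr::filter(labeled, !.data$aborted, !is.na(.data$category))
  go <- dplyr::filter(active, .data$kind == "Go")
  nogo <- dplyr::filter(active, .data$kind == "NoGo")
  nogo_counts <- dplyr::summarise(
    dplyr::group_by(nogo, nogo_category = .data$category),
    n_fa = sum(.data$outcome == "FA"),
    n_cr = sum(.data$outcome == "CR"),
    .groups = "drop"
  )
  rows <- purrr::map(history_categories_go(), function(cat) {
    g <- dplyr::filter(go, .data$category == cat)
    pool <- matched_nogo_category(cat)
    ng <- dplyr::filter(nogo_counts, .data$nogo_category == pool)
    n_go_cat <- nrow(g)
    n_nogo_cat <- if (nrow(ng)) ng$n_fa + ng$n_cr else 0L
    if (n_go_cat < min_go || n_nogo_cat < min_nogo) {
      inform(sprintf(
        "history_sdt: omitting '%s' (%d Go, %d NoGo trials).",
        cat, n_go_cat, n_nogo_cat
      ))
      return(NULL)
    }
    sdt <- compute_sdt(sum(g$outcome == "Hit"), sum(g$outcome == "Miss"),
                       ng$n_fa, ng$n_cr, correction = correction)
    dplyr::mutate(
      sdt,
      category = cat,
      nogo_pool = pool,
      median_lick_latency_s = stats::median(
        g$first_lick_latency_s[g$outcome == "Hit"], na.rm = TRUE
      ),
      .before = 1
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) && "priorNoGo" %in% out$category) {
    base <- dplyr::filter(out, .data$category == "priorNoGo")
    out <- dplyr::mutate(out,
      delta_d = .data$d_prime - base$d_prime,
      delta_c = .data$criterion - base$criterion
    )
  } else {
    out$delta_d <- NA_real_
    out$delta_c <- NA_real_
  }
  out
}

#' Somatotopic gradient of the attentional boost
#'
#' Groups Go trials that follow prior hit(s) by the facial offset between the
#' prior-hit whisker and the current whisker, and computes d' per offset
#' class against the shared prior-hit NoGo pool. The change relative to the
#' `priorNoGo` baseline gives the spatial profile of cueing.
#'
#' @inheritParams history_sdt
#' @param min_go Minimum Go trials per offset class.
#' @return Tibble with one row per offset class: counts, `d_prime`, `delta_d`.
#' @export
spatial_gradient <- function(labeled, min_go = 5, correction = "log-linear") {
  hit_cats_go <- c("prior1HitSame", "priorGT1HitSame",
                   "prior1HitDiff", "priorGT1HitDiff")
  active <- dplyr::filter(labeled, !.data$aborted, !is.na(.data$category))
  go <- dplyr::filter(active, .data$kind == "Go",
                      .data$category %in% hit_cats_go)
  nogo <- dplyr::filter(active, .data$kind == "NoGo",
                        .data$category %in% c("prior1Hit", "priorGT1Hit"))
  base_go <- dplyr::filter(active, .data$kind == "Go",
                           .data$category == "priorNoGo")
  base_nogo <- dplyr::filter(active, .data$kind == "NoGo",
                             .data$category == "priorNoGo")
  if (nrow(nogo) == 0 || nrow(base_go) < min_go || nrow(base_nogo) == 0) {
    abort("Insufficient trials for the spatial gradient.",
          class = "wa_insufficient_data")
  }
  base_d <- compute_sdt(
    sum(base_go$outcome == "Hit"), sum(base_go$outcome == "Miss"),
    sum(base_nogo$outcome == "FA"), sum(base_nogo$outcome == "CR"),
    correction = correction
  )$d_prime
  n_fa <- sum(nogo$outcome == "FA")
  n_cr <- sum(nogo$outcome == "CR")
  rows <- purrr::map(offset_classes(), function(cls) {
    g <- dplyr::filter(go, .data$offset_class == cls)
    if (nrow(g) < min_go) {
      inform(sprintf("spatial_gradient: omitting '%s' (%d Go trials).",
                     cls, nrow(g)))
      return(NULL)
    }
    sdt <- compute_sdt(sum(g$outcome == "Hit"), sum(g$outcome == "Miss"),
                       n_fa, n_cr, correction = correction)
    dplyr::mutate(sdt, offset_class = cls, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::mutate(out, delta_d = .data$d_prime - base_d)
  out
}

#' Temporal profile of the attentional boost
#'
#' Bins Go trials that follow a prior Go hit by the interval since that Go
#' trial and computes, per bin, d' for prior-same vs prior-different hits
#' (both against the shared prior-hit NoGo pool), whose difference traces the
#' temporal decay of whisker-specific cueing. Labels should come from
#' [classify_history()] with `mode = "ignore-nogo"`, since intervening NoGo
#' trials are ignored here.
#'
#' @inheritParams history_sdt
#' @param breaks Interval bin edges in seconds.
#' @param min_go Minimum Go trials per (bin, same/different) cell; bins
#'   lacking either side are omitted.
#' @return Tibble with one row per interval bin: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `t_mean` (mean interval of the contributing Go trials -
#'   intervals are not centred within bins, so decay fits use this), counts,
#'   `d_same`, `d_diff`, `delta_d = d_same - d_diff`.
#' @export
temporal_profile <- function(labeled, breaks = c(0, 2, 4, 6, 8, 12, 20),
                             min_go = 5, correction = "log-linear") {
  hit_cats_go <- c("prior1HitSame", "priorGT1HitSame",
                   "prior1HitDiff", "priorGT1HitDiff")
  active <- dplyr::filter(labeled, !.data$aborted, !is.na(.data$category))
  go <- dplyr::filter(active, .data$kind == "Go",
                      .data$category %in% hit_cats_go,
                      !is.na(.data$inter_go_interval))
  nogo <- dplyr::filter(active, .data$kind == "NoGo",
                        .data$category %in% c("prior1Hit", "priorGT1Hit"))
  if (nrow(go) == 0 || nrow(nogo) == 0) {
    abort("Insufficient trials for the temporal profile.",
          class = "wa_insufficient_data")
  }
  n_fa <- sum(nogo$outcome == "FA")
  n_cr <- sum(nogo$outcome == "CR")
  go <- dplyr::mutate(
    go,
    same = .data$category %in% c("prior1HitSame", "priorGT1HitSame"),
    bin = cut(.data$inter_go_interval, breaks = breaks, right = FALSE)
  )
  rows <- purrr::map(levels(go$bin), function(b) {
    gb <- dplyr::filter(go, !is.na(.data$bin), .data$bin == b)
    gs <- dplyr::filter(gb, .data$same)
    gd <- dplyr::filter(gb, !.data$same)
    if (nrow(gs) < min_go || nrow(gd) < min_go) return(NULL)
    d_same <- compute_sdt(sum(gs$outcome == "Hit"), sum(gs$outcome == "Miss"),
                          n_fa, n_cr, correction = correction)$d_prime
    d_diff <- compute_sdt(sum(gd$outcome == "Hit"), sum(gd$outcome == "Miss"),
                          n_fa, n_cr, correction = correction)$d_prime
    i <- match(b, levels(go$bin))
    tibble::tibble(
      bin_lo = breaks[i], bin_hi = breaks[i + 1],
      bin_mid = (breaks[i] + breaks[i + 1]) / 2,
      t_mean = mean(gb$inter_go_interval),
      n_same = nrow(gs), n_diff = nrow(gd),
      d_same = d_same, d_diff = d_diff,
      delta_d = d_same - d_diff
    )
  })
  dplyr::bind_rows(rows)
}

#' Fit an exponential decay to a temporal profile
#'
#' Fits `delta_d = A * exp(-t / tau)` to the per-bin same-vs-different d'
#' difference by weighted nonlinear least squares (weights = trials per
#' bin), with `t` the mean inter-Go interval of each bin (intervals are not
#' centred within bins, so bin midpoints would bias tau upward).
#' Initialised from a log-linear fit over the positive bins.
#'
#' @param profile Output of [temporal_profile()] (bins may be pooled across
#'   sessions first).
#' @return One-row tibble with `amplitude` and `tau_s`.
#' @export
fit_temporal_decay <- function(profile) {
  if (nrow(profile) < 3) {
    abort("Need at least 3 bins to fit a decay.",
          class = "wa_insufficient_data")
  }
  w <- profile$n_same + profile$n_diff
  pos <- profile$delta_d > 0
  if (sum(pos) < 2) {
    abort("Too few positive bins to initialise the decay fit.",
          class = "wa_insufficient_data")
  }
  profile$t_fit <- profile$t_mean %||% profile$bin_mid
  init <- stats::lm(log(delta_d) ~ t_fit, data = profile[pos, ],
                    weights = w[pos])
  start <- list(A = exp(coef(init)[[1]]),
                tau = max(0.5, -1 / coef(init)[[2]]))
  fit <- tryCatch(
    stats::nls(delta_d ~ A * exp(-t_fit / tau), data = profile,
               start = start, weights = w,
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(amplitude = start$A, tau_s = start$tau))
  }
  cf <- coef(fit)
  tibble::tibble(amplitude = unname(cf["A"]), tau_s = unname(cf["tau"]))
}
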