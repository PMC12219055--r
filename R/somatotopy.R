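#' Somatotopic profile of evoked responses by trial history
#'
#' For each of the nine whiskers in turn (the reference whisker), every cell
#' is placed in a spatial bin by its distance to the reference whisker's
#' column centre (normalized by the mean barrel width), and the mean evoked
#' response to that whisker is computed per bin and history condition. The
#' profiles are then averaged over all reference whiskers (each weighted
#' equally). The `priorNoGo` trace reflects normal somatotopy; the
#' attentional spotlight appears as the difference of other conditions from
#' it.
#'
#' @param responses Long response tibble (`trial_index`, `cell_id`,
#'   `evoked`).
#' @param labels Labelled session from [classify_history()].
#' @param cells Cell table with `cell_id`, `x_um`, `y_um`.
#' @param grid The session [whisker_grid()].
#' @param conditions History categories to profile.
#' @param bin_width Bin width in column widths (default 0.25).
#' @param max_dist Largest distance retained (column widths).
#' @return Tibble `bin_mid` x `category` with `mean_response` (average over
#'   reference whiskers of the per-reference bin means), `n_obs` and
#'   `n_refs`.
#' @export
somatotopic_profile <- function(responses, labels, cells, grid,
                                conditions = c("priorGT1HitSame",
                                               "priorNoGo"),
                                bin_width = 0.25, max_dist = 2.5) {
  width <- attr(grid, "barrel_width_um")
  go <- dplyr::filter(labels, .data$kind == "Go", !.data$aborted,
                      .data$category %in% conditions)
  per_ref <- purrr::map(seq_len(nrow(grid)), function(i) {
    w <- grid$whisker[i]
    trials_w <- dplyr::filter(go, .data$whisker == w)
    if (nrow(trials_w) == 0) return(NULL)
    joined <- dplyr::inner_join(
      responses,
      dplyr::select(trials_w, "trial_index", "category"),
      by = "trial_index"
    )
    joined <- dplyr::inner_join(joined, cells, by = "cell_id")
    joined <- dplyr::mutate(
      joined,
      dist = sqrt((.data$x_um - grid$cx_um[i])^2 +
                    (.data$y_um - grid$cy_um[i])^2) / width,
      bin_mid = (floor(.data$dist / bin_width) + 0.5) * bin_width
    )
    joined <- dplyr::filter(joined, .data$dist <= max_dist)
    dplyr::summarise(
      dplyr::group_by(joined, .data$bin_mid, .data$category),
      mean_response = mean(.data$evoked),
      n_obs = dplyr::n(),
      .groups = "drop"
    )
  })
  binned <- dplyr::bind_rows(per_ref)
  if (nrow(binned) == 0) {
    abort("No trials available for the somatotopic profile.",
          class = "wa_insufficient_data")
  }
  dplyr::summarise(
    dplyr::group_by(binned, .data$bin_mid, .data$category),
    mean_response = mean(.data$mean_response),
    n_obs = sum(.data$n_obs),
    n_refs = dplyr::n(),
    .groups = "drop"
  )
}

#' Attentional profile: condition minus baseline, per spatial bin
#'
#' @param profile Output of [somatotopic_profile()].
#' @param condition Attention condition (default `priorGT1HitSame`).
#' @param baseline Baseline condition (default `priorNoGo`).
#' @param relative Also compute the modulation relative to the baseline
#'   somatotopy (`difference / baseline`), which normalizes out tuning
#'   falloff with distance.
#' @return Tibble per bin with `difference` and (optionally) `relative`.
#' @export
attentional_profile <- function(profile, condition = "priorGT1HitSame",
                                baseline = "priorNoGo", relative = TRUE) {
  cond <- dplyr::filter(profile, .data$category == condition)
  base <- dplyr::filter(profile, .data$category == baseline)
  joined <- dplyr::inner_join(
    dplyr::select(cond, "bin_mid", cond_mean = "mean_response",
                  cond_n = "n_obs"),
    dplyr::select(base, "bin_mid", base_mean = "mean_response"),
    by = "bin_mid"
  )
  out <- dplyr::mutate(joined, difference = .data$cond_mean - .data$base_mean)
  if (relative) {
    out <- dplyr::mutate(
      out,
      relative = ifelse(abs(.data$base_mean) > 1e-9,
                        .data$difference / .data$base_mean, NA_real_)
    )
  }
  dplyr::arrange(out, .data$bin_mid)
}

#' Half-maximum distance of an attentional profile
#'
#' Distance at which the attentional modulation falls to half its value in
#' the innermost bin, by linear interpolation between bin centres. Operates
#' on the relative modulation by default (robust to tuning falloff).
#'
#' @param att Output of [attentional_profile()].
#' @param value Column to use (`"relative"` or `"difference"`).
#' @return Half-max distance in column widths (NA if the profile never drops
#'   below half).
#' @export
profile_half_max <- function(att, value = c("relative", "difference")) {
  value <- match.arg(value)
  v <- att[[value]]
  x <- att$bin_mid
  keep <- !is.na(v)
  v <- v[keep]
  x <- x[keep]
  if (length(v) < 2) {
    abort("Need at least 2 bins.", class = "wa_insufficient_data")
  }
  half <- v[1] / 2
  below <- which(v <= half)
  below <- below[below > 1]
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  # interpolate between the last bin above half and the first at/below it
  x[j - 1] + (v[j - 1] - half) / (v[j - 1] - v[j]) * (x[j] - x[j - 1])
}
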