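#' Build a whisker / barrel-column grid
#'
#' Constructs the 3x3 (by default) whisker array used throughout the package,
#' together with the corresponding lattice of barrel-column centroids in
#' cortical map coordinates. Grid coordinates follow the convention that the
#' arc axis is x (rostral positive, i.e. increasing arc number) and the row
#' axis is y (upper rows positive), with the central whisker at the origin.
#'
#' @param rows Character vector of row labels, ordered top to bottom.
#' @param arcs Vector of arc labels, ordered caudal to rostral.
#' @param pitch_um Centroid-to-centroid spacing of barrel columns (micrometres).
#' @param barrel_width_um Mean barrel width (micrometres); defaults to the
#'   pitch, i.e. abutting columns of equal major and minor axes.
#'
#' @return A tibble of class `wa_grid` with one row per whisker and columns
#'   `whisker`, `row`, `arc`, `x`, `y` (grid units) and `cx_um`, `cy_um`
#'   (centroid position). Attributes `pitch_um` and `barrel_width_um` carry
#'   the spatial scale.
#' @examples
#' grid <- whisker_grid()
#' grid
#' @export
whisker_grid <- function(rows = c("C", "D", "E"), arcs = 1:3, pitch_um = 300,
                         barrel_width_um = pitch_um) {
  if (length(rows) == 0L || length(arcs) == 0L) {
    abort("`rows` and `arcs` must be non-empty.", class = "wa_invalid_input")
  }
  check_number(pitch_um, "pitch_um", min = 1e-9)
  check_number(barrel_width_um, "barrel_width_um", min = 1e-9)
  row_idx <- seq_along(rows)
  arc_idx <- seq_along(arcs)
  g <- tidyr::expand_grid(row_i = row_idx, arc_i = arc_idx)
  # centre of the grid is the origin; y grows upward (towards earlier rows)
  cy <- stats::median(row_idx)
  cx <- stats::median(arc_idx)
  g <- dplyr::mutate(
    g,
    row = rows[.data$row_i],
    arc = arcs[.data$arc_i],
    whisker = paste0(.data$row, .data$arc),
    x = .data$arc_i - cx,
    y = cy - .data$row_i,
    cx_um = .data$x * pitch_um,
    cy_um = .data$y * pitch_um
  )
  g <- dplyr::select(g, "whisker", "row", "arc", "x", "y", "cx_um", "cy_um")
  out <- tibble::new_tibble(g, class = "wa_grid")
  attr(out, "pitch_um") <- pitch_um
  attr(out, "barrel_width_um") <- barrel_width_um
  out
}

#' Somatotopic offset classes
#'
#' Ordered vocabulary for the facial offset between a prior (cueing) whisker
#' and the current trial whisker.
#'
#' @return Character vector of the five offset classes, nearest first.
#' @export
offset_classes <- function() {
  c("same", "same-row adjacent", "same-arc adjacent", "diagonal adjacent",
    "further")
}

#' Classify the spatial offset between two whiskers
#'
#' @param grid A [whisker_grid()].
#' @param from,to Whisker labels (vectorised, recycled to common length).
#'   `from` is the prior / cueing whisker, `to` the current whisker.
#' @return Factor with levels [offset_classes()]; `NA` where either label is
#'   missing or unknown.
#' @examples
#' g <- whisker_grid()
#' offset_class(g, "D2", c("D2", "D1", "C2", "C1", "E3"))
#' @export
offset_class <- function(grid, from, to) {
  stopifnot(inherits(grid, "wa_grid"))
  n <- max(length(from), length(to))
  from <- rep_len(as.character(from), n)
  to <- rep_len(as.character(to), n)
  ix <- match(from, grid$whisker)
  iy <- match(to, grid$whisker)
  dx <- abs(grid$x[ix] - grid$x[iy])
  dy <- abs(grid$y[ix] - grid$y[iy])
  cls <- dplyr::case_when(
    dx == 0 & dy == 0 ~ "same",
    dy == 0 & dx == 1 ~ "same-row adjacent",
    dx == 0 & dy == 1 ~ "same-arc adjacent",
    dx == 1 & dy == 1 ~ "diagonal adjacent",
    !is.na(dx) ~ "further"
  )
  factor(cls, levels = offset_classes())
}

#' History-condition vocabularies
#'
#' Trial-history categories assigned to current Go and current NoGo trials.
#' Go categories distinguish whether the cueing hit(s) were to the same or a
#' different whisker than the current stimulus; NoGo trials have no current
#' whisker, so their categories collapse over whisker identity and serve as
#' the matched false-alarm pools.
#'
#' @return Character vector of category labels.
#' @export
history_categories_go <- function() {
  c("priorNoGo", "prior1HitSame", "priorGT1HitSame", "prior1HitDiff",
    "priorGT1HitDiff", "priorMissSame", "priorMissDiff")
}

#' @rdname history_categories_go
#' @export
history_categories_nogo <- function() {
  c("priorNoGo", "prior1Hit", "priorGT1Hit", "priorMiss")
}

# Matched NoGo pool for each Go category (false-alarm rates are computed from
# the NoGo trials whose history matches the Go category, with same/different
# collapsed because NoGo trials carry no current whisker).
matched_nogo_category <- function(go_category) {
  map <- c(
    priorNoGo = "priorNoGo",
    prior1HitSame = "prior1Hit", prior1HitDiff = "prior1Hit",
    priorGT1HitSame = "priorGT1Hit", priorGT1HitDiff = "priorGT1Hit",
    priorMissSame = "priorMiss", priorMissDiff = "priorMiss"
  )
  unname(map[as.character(go_category)])
}
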