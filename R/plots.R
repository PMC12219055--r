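#' Plot history-conditioned sensitivity
#'
#' Point-range style summary of d' per trial-history category.
#'
#' @param hsdt Output of [history_sdt()].
#' @return A ggplot object.
#' @export
plot_history_sdt <- function(hsdt) {
  hsdt$category <- factor(hsdt$category, levels = history_categories_go())
  ggplot2::ggplot(hsdt, ggplot2::aes(x = .data$category, y = .data$d_prime)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(
      yintercept = hsdt$d_prime[hsdt$category == "priorNoGo"],
      linetype = "dashed"
    ) +
    ggplot2::labs(x = NULL, y = "d'") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the somatotopic gradient of the attentional boost
#'
#' @param sg Output of [spatial_gradient()].
#' @return A ggplot object.
#' @export
plot_spatial_gradient <- function(sg) {
  sg$offset_class <- factor(sg$offset_class, levels = offset_classes())
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$offset_class,
                                   y = .data$delta_d)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "offset of prior-hit whisker", y = "Δ d'") +
    ggplot2::theme_minimal()
}

#' Plot the temporal profile of the attentional boost
#'
#' @param tp Output of [temporal_profile()].
#' @param fit Optional [fit_temporal_decay()] result to overlay.
#' @return A ggplot object.
#' @export
plot_temporal_profile <- function(tp, fit = NULL) {
  p <- ggplot2::ggplot(tp, ggplot2::aes(x = .data$bin_mid,
                                        y = .data$delta_d)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time since prior Go trial (s)",
                  y = "Δ d' (same - different)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid_t <- seq(min(tp$bin_mid), max(tp$bin_mid), length.out = 100)
    curve <- tibble::tibble(
      bin_mid = grid_t,
      delta_d = fit$amplitude * exp(-grid_t / fit$tau_s)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Plot a somatotopic response profile by history condition
#'
#' @param profile Output of [somatotopic_profile()].
#' @return A ggplot object.
#' @export
plot_somatotopic_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_mid,
                                        y = .data$mean_response,
                                        colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance to reference column (column widths)",
                  y = "mean evoked response", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot decoder weights
#'
#' @param object A [fit_decoder()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wa_decoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "white") +
    ggplot2::labs(x = "ridge logistic weight", y = "cells") +
    ggplot2::theme_minimal()
}
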