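# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes autoplot geom_bin2d geom_line geom_point
#'   geom_ribbon geom_step labs scale_x_log10 theme_minimal
NULL

#' Density plot of AmFRET versus concentration
#'
#' The standard two-dimensional view of a sample: AmFRET against the
#' log-scaled per-cell concentration proxy, with bin counts as fill.
#'
#' @param events Gated, AmFRET-derived event tibble.
#' @param bins Number of bins per axis (default 120).
#' @return A ggplot object.
#' @export
plot_damfret <- function(events, bins = 120) {
  check_channels(events, c("concentration", "amfret"))
  ggplot(events, aes(x = .data$concentration, y = .data$amfret)) +
    geom_bin2d(bins = bins) +
    scale_x_log10() +
    labs(
      x = "concentration (acceptor / SSC, AU)", y = "AmFRET",
      fill = "cells"
    ) +
    theme_minimal()
}

#' @export
autoplot.gate_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$acceptor_center, y = .data$upper_gate)) +
    geom_step() +
    geom_line(aes(y = .data$lower_gate), linetype = 2) +
    geom_point(aes(shape = .data$valid), size = 1) +
    scale_x_log10() +
    labs(
      x = "acceptor intensity (AU)", y = "AmFRET gate",
      shape = "valid bin"
    ) +
    theme_minimal()
}

#' @export
autoplot.plateau_scan <- function(object, ...) {
  d <- object$slopes
  ggplot(d, aes(x = .data$acceptor_center)) +
    geom_point(aes(y = .data$fraction), alpha = 0.6) +
    geom_line(aes(y = .data$fit)) +
    geom_line(aes(y = .data$isotonic), linetype = 3) +
    scale_x_log10() +
    labs(
      x = "acceptor intensity (AU)", y = "fraction positive",
      title = if (object$plateau) "plateau flagged" else "no plateau"
    ) +
    theme_minimal()
}

#' Overlay plot of normalized lane profiles
#'
#' @param profiles Named list of lane profiles (see [line_profile()]); each
#'   is normalized before plotting.
#' @return A ggplot object.
#' @export
plot_lane_profiles <- function(profiles) {
  d <- purrr::imap_dfr(profiles, function(p, nm) {
    p <- normalize_profile(p)
    tibble(lane = nm, position = p$position, intensity = p$intensity)
  })
  ggplot(d, aes(x = .data$position, y = .data$intensity, colour = .data$lane)) +
    geom_line() +
    labs(x = "migration (px)", y = "normalized intensity") +
    theme_minimal()
}

#' Fraction-positive curve plot with Wilson intervals
#'
#' @param curve A [positive_fraction_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_positive_fraction <- function(curve) {
  d <- curve[curve$occupied, , drop = FALSE]
  ggplot(d, aes(x = .data$acceptor_center, y = .data$fraction)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), alpha = 0.2) +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = "acceptor intensity (AU)", y = "fraction positive") +
    theme_minimal()
}
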