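# Detection of self-poisoning plateaus in fraction-positive curves.
#
# Self-poisoning stalls amyloid growth at high monomer flux, so the fraction
# of assembled cells plateaus (or dips) over an intermediate concentration
# window before rising again. The detector smooths the per-bin fraction
# against log acceptor intensity, computes the slope, and flags a plateau
# when the slope falls below a fraction of its running early-regime maximum
# for a minimum number of consecutive bins and subsequently recovers. A
# monotone saturating curve never recovers after its slope decays, so it is
# never flagged.

#' Detect a self-poisoning plateau in a fraction-positive curve
#'
#' @param curve A [positive_fraction_curve()] tibble.
#' @param slope_frac Threshold fraction of the early-regime maximum slope
#'   below which a bin counts as plateaued (default 0.2).
#' @param min_run Minimum number of consecutive plateaued bins (default 3).
#' @param min_n Minimum events per bin for the bin to enter the fit
#'   (default 10).
#' @param df Equivalent degrees of freedom of the free smoother (default 8).
#' @return An object of class `"plateau_scan"`: `plateau` (flag), `segments`
#'   (tibble of flagged bin ranges with acceptor coordinates), `slopes`
#'   (per-bin smoothed fit, slope and isotonic baseline) and the settings.
#' @examples
#' p <- damfret_preset("pinminus_QB_poisoned", n_cells = 5000, seed = 1)
#' ev <- generate_sample(p) |> apply_gates() |> derive_amfret()
#' ctl <- generate_negative_control(p) |> apply_gates() |> derive_amfret()
#' prof <- build_gate_profile(ctl)
#' detect_poisoning_plateau(positive_fraction_curve(ev, prof))$plateau
#' @export
detect_poisoning_plateau <- function(curve, slope_frac = 0.2, min_run = 3,
                                     min_n = 10, df = 8) {
  use <- curve$n >= min_n & !is.na(curve$fraction)
  if (sum(use) < 10) {
    abort("fewer than 10 usable bins.", class = "qzipper_too_few_bins")
  }
  d <- curve[use, , drop = FALSE]
  x <- log10(d$acceptor_center)
  y <- d$fraction
  sp <- stats::smooth.spline(x, y, w = d$n, df = min(df, sum(use) - 2))
  fit <- stats::predict(sp, x)$y
  slope <- stats::predict(sp, x, deriv = 1)$y
  iso <- stats::isoreg(x, y)$yf

  nb <- length(slope)
  # Early-regime maximum slope seen strictly before each bin.
  run_max <- cummax(pmax(slope, 0))
  prior_max <- c(0, run_max[-nb])
  below <- slope < slope_frac * prior_max & prior_max > 0

  segments <- tibble(
    start_bin = integer(0), end_bin = integer(0),
    acceptor_start = numeric(0), acceptor_end = numeric(0)
  )
  flagged <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_run) next
    i0 <- starts[k]
    i1 <- ends[k]
    thr <- slope_frac * prior_max[i0]
    rises_again <- i1 < nb && any(slope[(i1 + 1):nb] > thr)
    if (rises_again) {
      flagged <- TRUE
      segments <- dplyr::bind_rows(segments, tibble(
        start_bin = d$bin[i0], end_bin = d$bin[i1],
        acceptor_start = d$acceptor_center[i0],
        acceptor_end = d$acceptor_center[i1]
      ))
    }
  }

  structure(
    list(
      plateau = flagged,
      segments = segments,
      slopes = tibble(
        bin = d$bin, acceptor_center = d$acceptor_center,
        fraction = y, fit = fit, slope = slope, isotonic = iso
      ),
      settings = list(
        slope_frac = slope_frac, min_run = min_run, min_n = min_n, df = df
      )
    ),
    class = "plateau_scan"
  )
}

#' @export
print.plateau_scan <- function(x, ...) {
  cat(sprintf(
    "<plateau_scan> plateau: %s (%d segment(s) over %d usable bins)\n",
    x$plateau, nrow(x$segments), nrow(x$slopes)
  ))
  invisible(x)
}

#' @rdname detect_poisoning_plateau
#' @param x A `plateau_scan` object.
#' @param ... Unused.
#' @export
tidy.plateau_scan <- function(x, ...) x$segments

#' @rdname detect_poisoning_plateau
#' @export
glance.plateau_scan <- function(x, ...) {
  tibble(
    plateau = x$plateau,
    n_segments = nrow(x$segments),
    n_bins_used = nrow(x$slopes)
  )
}
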