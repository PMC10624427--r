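# Summary statistics on gated, AmFRET-derived samples against a gate profile.

positive_events <- function(sample, profile) {
  check_channels(sample, c("acceptor", "amfret"))
  bin <- bin_acceptor(sample$acceptor, profile$bin_edges)
  gate <- profile$upper_gate[bin]
  # Events below the lower gate count in denominators but never as positive.
  list(
    bin = bin,
    positive = sample$amfret > gate & sample$amfret >= profile$lower_gate
  )
}

#' Fraction of expressing cells with assembled protein (fgate)
#'
#' The fraction of events whose AmFRET exceeds the upper gate of their
#' acceptor bin. Unitless, in `[0, 1]`; by construction of the gate profile
#' it stays near zero for a sample distributed like the negative control.
#'
#' @param sample Gated, AmFRET-derived event tibble.
#' @param profile A [build_gate_profile()] result.
#' @return A single number in `[0, 1]`.
#' @export
fgate <- function(sample, profile) {
  if (nrow(sample) == 0) abort("empty sample.", class = "qzipper_empty_input")
  mean(positive_events(sample, profile)$positive)
}

#' Per-bin fraction-positive curve with Wilson intervals
#'
#' For each acceptor bin of the profile, the ratio of assembled (above-gate)
#' cells to total cells in the bin, with 95% Wilson score intervals.
#'
#' @inheritParams fgate
#' @param conf_level Confidence level for the Wilson interval (default 0.95).
#' @return A tibble with one row per bin: `bin`, `acceptor_center`, `n`,
#'   `positives`, `fraction` (`NA` for empty bins), `ci_lo`, `ci_hi`,
#'   `occupied` (`n > 0`). The profile's acceptor gain context, if present on
#'   the sample, is carried through as attribute `"au_per_uM"`.
#' @export
positive_fraction_curve <- function(sample, profile, conf_level = 0.95) {
  pe <- positive_events(sample, profile)
  nb <- length(profile$upper_gate)
  f <- factor(pe$bin, levels = seq_len(nb))
  n <- as.integer(table(f))
  pos <- as.integer(tapply(pe$positive, f, sum, default = 0L))
  frac <- ifelse(n > 0, pos / n, NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- wilson_interval(pos, n, z)
  out <- tibble(
    bin = seq_len(nb),
    acceptor_center = profile$bin_centers,
    n = n,
    positives = pos,
    fraction = frac,
    ci_lo = ci$lo,
    ci_hi = ci$hi,
    occupied = n > 0L
  )
  attr(out, "au_per_uM") <- attr(sample, "au_per_uM")
  out
}

wilson_interval <- function(x, n, z) {
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' Fraction of positive cells at intermediate AmFRET
#'
#' Quantifies the growth-limited population sitting between the monomeric
#' and fully assembled modes. On the above-gate (positive) events, a one- or
#' two-component Gaussian location fit (`mclust`, BIC-selected) estimates the
#' upper population's mean and SD; the monomeric SD is estimated from the
#' below-gate events. Intermediate events are positives lying between
#' `k_neg * sigma_neg` and `a_upper - k_pos * sigma_upper`; the returned
#' value is their fraction among positives.
#'
#' @inheritParams fgate
#' @param k_neg,k_pos Multipliers for the lower and upper boundaries
#'   (defaults 3 and 2).
#' @return A single fraction in `[0, 1]`; 0 with a warning when the sample
#'   has no positive population.
#' @export
intermediate_fraction <- function(sample, profile, k_neg = 3, k_pos = 2) {
  pe <- positive_events(sample, profile)
  amf_pos <- sample$amfret[pe$positive]
  if (length(amf_pos) < 10) {
    warn("no detectable positive population; returning 0.")
    return(0)
  }
  amf_neg <- sample$amfret[!pe$positive & sample$amfret >= profile$lower_gate]
  sigma_neg <- if (length(amf_neg) >= 10) stats::mad(amf_neg) else stats::sd(amf_pos)
  # mclust resolves its worker functions in the calling frame, so it must be
  # attached for the duration of the fit; its initialisation subsamples large
  # inputs through the RNG, so seed it locally to keep the pipeline
  # deterministic.
  fit <- withr::with_package("mclust", withr::with_seed(1L, {
    mclust::Mclust(amf_pos, G = 1:2, modelNames = "V", verbose = FALSE)
  }))
  top <- which.max(fit$parameters$mean)
  a_upper <- fit$parameters$mean[top]
  sigma_upper <- sqrt(fit$parameters$variance$sigmasq[
    min(top, length(fit$parameters$variance$sigmasq))
  ])
  lo <- k_neg * sigma_neg
  hi <- a_upper - k_pos * sigma_upper
  if (hi <= lo) {
    return(0)
  }
  mean(amf_pos > lo & amf_pos < hi)
}

#' Median AmFRET of the assembled population at top concentrations
#'
#' Median AmFRET over positive-gated events whose derived concentration lies
#' in the top `top_quantile` of the sample (the concentration regime where
#' essentially all protein is assembled, so the value reflects subunit
#' packing density).
#'
#' @inheritParams fgate
#' @param top_quantile Fraction of the concentration distribution to use
#'   (default 0.1, the top decile).
#' @return A single number.
#' @export
max_amfret <- function(sample, profile, top_quantile = 0.1) {
  check_channels(sample, c("concentration", "amfret"))
  pe <- positive_events(sample, profile)
  cutoff <- stats::quantile(sample$concentration, 1 - top_quantile, names = FALSE)
  sel <- pe$positive & sample$concentration >= cutoff
  if (!any(sel)) {
    abort("no positive events in the top concentration quantile.",
      class = "qzipper_empty_selection"
    )
  }
  stats::median(sample$amfret[sel])
}

#' Smoothed AmFRET versus log-concentration
#'
#' Cubic smoothing spline through the per-bin median AmFRET, weighted by bin
#' counts. The assembled and monomeric populations can be fit separately
#' (`split_populations = TRUE`), which is the appropriate treatment when a
#' persistent negative population coexists with the assembled one.
#'
#' @inheritParams fgate
#' @param df Target equivalent degrees of freedom for the spline (default 8;
#'   capped below the number of occupied bins).
#' @param split_populations Fit above-gate and below-gate events separately?
#' @return A tibble with columns `population` (`"all"`, `"upper"`,
#'   `"lower"`), `bin`, `acceptor_center`, `n`, `median_amfret` and `fit`
#'   (the spline value at the bin).
#' @export
spline_curve <- function(sample, profile, df = 8, split_populations = FALSE) {
  pe <- positive_events(sample, profile)
  fit_one <- function(keep, label) {
    s <- sample[keep, , drop = FALSE]
    b <- pe$bin[keep]
    f <- factor(b, levels = seq_along(profile$upper_gate))
    n <- as.integer(table(f))
    med <- as.numeric(tapply(s$amfret, f, stats::median))
    occ <- which(n > 0)
    if (length(occ) < 10) {
      abort(sprintf("fewer than 10 occupied bins for population '%s'.", label),
        class = "qzipper_too_few_bins"
      )
    }
    x <- log10(profile$bin_centers[occ])
    y <- med[occ]
    sp <- stats::smooth.spline(x, y,
      w = n[occ],
      df = min(df, length(occ) - 1)
    )
    tibble(
      population = label,
      bin = occ,
      acceptor_center = profile$bin_centers[occ],
      n = n[occ],
      median_amfret = y,
      fit = stats::predict(sp, x)$y
    )
  }
  if (split_populations) {
    dplyr::bind_rows(
      fit_one(pe$positive, "upper"),
      fit_one(!pe$positive, "lower")
    )
  } else {
    fit_one(rep(TRUE, nrow(sample)), "all")
  }
}
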