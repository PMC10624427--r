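# Reaction-order recovery from a fraction-positive curve.
#
# With cumulative hazard K c^n, the per-bin positive fraction p(c) obeys
# log(-log(1 - p)) = log K + n log c, so the reaction order is the slope of
# a straight-line fit on the complementary-log-log scale.

#' Recover the nucleation reaction order from an event table
#'
#' Scores each event against the gate profile, bins events into `n_bins`
#' logarithmic bins of the derived per-cell concentration (acceptor / SSC,
#' which tracks concentration without the cell-size spread of the raw
#' acceptor axis), keeps bins with at
#' least `min_n` events and a fraction inside `p_range`, and fits
#' `log(-log(1 - p)) ~ log(c)` by weighted least squares (delta-method
#' weights, so noisy extreme bins do not dominate). The complementary
#' log-log scale degenerates as p approaches 0 or 1 — bins observed at
#' exactly 0 or 1 drop out, which selectively biases the surviving extreme
#' bins — so the fit is restricted to the informative mid-range by default.
#' Valid in the pre-poisoning regime (generate the input with
#' `c_poison = Inf`).
#'
#' @param sample Gated, AmFRET-derived event tibble.
#' @param profile A [build_gate_profile()] result from the matched control.
#' @param min_n Minimum events per usable bin (default 25).
#' @param n_bins Number of logarithmic concentration bins (default 64).
#' @param p_range Fraction-positive range of bins entering the fit
#'   (default `c(0.02, 0.95)`).
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `"reaction_order_fit"` with the fitted order,
#'   its confidence interval, the underlying `lm` fit and the per-bin data.
#'   Use [generics::tidy()] / [generics::glance()] for flat summaries.
#' @examples
#' p <- nucleation_params(n_cells = 5000, seed = 3)
#' ev <- generate_sample(p) |> apply_gates() |> derive_amfret()
#' ctl <- generate_negative_control(p) |> apply_gates() |> derive_amfret()
#' fit <- recover_reaction_order(ev, build_gate_profile(ctl))
#' glance(fit)
#' @export
recover_reaction_order <- function(sample, profile, min_n = 25,
                                   n_bins = 64, p_range = c(0.02, 0.95),
                                   conf_level = 0.95) {
  check_channels(sample, c("concentration", "amfret", "acceptor"))
  pos <- positive_events(sample, profile)$positive
  edges <- exp(seq(log(min(sample$concentration)),
    log(max(sample$concentration)),
    length.out = n_bins + 1
  ))
  b <- bin_acceptor(sample$concentration, edges)
  f <- factor(b, levels = seq_len(n_bins))
  n <- as.integer(table(f))
  x <- as.integer(tapply(pos, f, sum, default = 0L))
  centers <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  p_hat <- ifelse(n > 0, x / n, NA_real_)
  use <- n >= min_n & !is.na(p_hat) &
    p_hat >= p_range[1] & p_hat <= p_range[2] & p_hat > 0 & p_hat < 1
  if (sum(use) < 3) {
    abort("fewer than 3 usable bins with 0 < p < 1.",
      class = "qzipper_too_few_bins"
    )
  }
  p <- p_hat[use]
  # Var[log(-log(1-p_hat))] ~ p / (n (1-p) log(1-p)^2) by the delta method.
  w <- n[use] * (1 - p) * log(1 - p)^2 / p
  dd <- tibble(
    log_c = log(centers[use]),
    cloglog = log(-log(1 - p)),
    n = n[use],
    w = w
  )
  fit <- stats::lm(cloglog ~ log_c, data = dd, weights = w)
  ci <- stats::confint(fit, "log_c", level = conf_level)
  structure(
    list(
      n_order = unname(stats::coef(fit)["log_c"]),
      conf_low = ci[1], conf_high = ci[2],
      conf_level = conf_level,
      fit = fit,
      data = dd,
      n_bins = nrow(dd)
    ),
    class = "reaction_order_fit"
  )
}

#' @export
print.reaction_order_fit <- function(x, ...) {
  cat(sprintf(
    "<reaction_order_fit> n_order = %.3f (%d%% CI %.3f..%.3f) from %d bins\n",
    x$n_order, round(100 * x$conf_level), x$conf_low, x$conf_high, x$n_bins
  ))
  invisible(x)
}

#' @rdname recover_reaction_order
#' @param x A `reaction_order_fit` object.
#' @param ... Unused.
#' @export
tidy.reaction_order_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname recover_reaction_order
#' @export
glance.reaction_order_fit <- function(x, ...) {
  tibble(
    n_order = x$n_order,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    n_bins = x$n_bins,
    r.squared = summary(x$fit)$r.squared
  )
}
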