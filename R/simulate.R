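# Synthetic per-cell cytometry event generation.

#' Generate a synthetic cytometry event table
#'
#' Draws one event per cell from the nucleation-under-rising-concentration
#' model: final concentrations are log-uniform over `c_range` (a ~100-fold
#' expression spread), each cell nucleates with [nucleation_probability()],
#' nucleated cells emit AmFRET around `a_pos` (a fraction `a_mid_frac` of
#' them at the intermediate, growth-limited level `a_pos / 2`), and
#' non-nucleated cells emit around 0. Raw channels are constructed so that
#' `acceptor = concentration * ssc * acceptor_gain`,
#' `fret = amfret * acceptor`, and events fall inside the default [gate_set()]
#' after the default logicle transform. Fully reproducible given `p$seed`.
#'
#' @param p A [nucleation_params()] object.
#' @return A tibble with one row per cell: raw channels (`fs_a`, `fs_h`,
#'   `fs_w`, `ssc`, `donor`, `fret`, `acceptor`, `autofluor`) plus the
#'   generator ground truth (`true_concentration`, `nucleated`, `mid_level`).
#'   The acceptor gain (arbitrary units per uM) is attached as attribute
#'   `"au_per_uM"` for mapping derived concentrations back to uM.
#' @examples
#' ev <- generate_sample(nucleation_params(n_cells = 1000, seed = 7))
#' mean(ev$nucleated)
#' @export
generate_sample <- function(p) {
  stopifnot(inherits(p, "nucleation_params"))
  ch <- p$channels
  withr::with_seed(p$seed, {
    n <- p$n_cells
    conc <- exp(stats::runif(n, log(p$c_range[1]), log(p$c_range[2])))
    prob <- nucleation_probability(conc, p)
    nucleated <- stats::runif(n) < prob
    mid_level <- nucleated & (stats::runif(n) < p$a_mid_frac)
    amfret_mean <- ifelse(nucleated, ifelse(mid_level, p$a_pos / 2, p$a_pos), 0)
    amfret_sd <- ifelse(nucleated, p$sigma_pos, p$sigma_neg)
    amfret <- stats::rnorm(n, amfret_mean, amfret_sd)
    ssc <- stats::rlnorm(n, ch$ssc_meanlog, ch$ssc_sdlog)
    acceptor <- conc * ssc * ch$acceptor_gain
    tibble(
      fs_a = stats::rlnorm(n, ch$fs_a_meanlog, ch$fs_a_sdlog),
      fs_h = stats::rlnorm(n, ch$fs_h_meanlog, ch$fs_h_sdlog),
      fs_w = stats::rlnorm(n, ch$fs_w_meanlog, ch$fs_w_sdlog),
      ssc = ssc,
      donor = conc * ssc * ch$donor_gain,
      fret = amfret * acceptor,
      acceptor = acceptor,
      autofluor = stats::rlnorm(n, ch$autofluor_meanlog, ch$autofluor_sdlog),
      true_concentration = conc,
      nucleated = nucleated,
      mid_level = mid_level
    )
  }) -> events
  attr(events, "au_per_uM") <- ch$acceptor_gain
  attr(events, "params") <- p
  events
}

#' Generate a monomer-only negative control
#'
#' Identical to [generate_sample()] with the nucleation rate forced to zero:
#' the control spans the same concentration range but never assembles. This
#' is the input for [build_gate_profile()].
#'
#' @inheritParams generate_sample
#' @return An event tibble (see [generate_sample()]).
#' @export
generate_negative_control <- function(p) {
  stopifnot(inherits(p, "nucleation_params"))
  p$kappa <- 0
  generate_sample(p)
}
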