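# Stochastic model of amyloid nucleation under rising concentration.
#
# In the assay, expression drives the per-cell protein concentration up
# monotonically over a ~16 h induction, so the fraction of cells with amyloid
# at a given final concentration is the cumulative probability of having
# nucleated while transiting all lower concentrations. For a linear ramp
# c(t) = c_final * t / t_f and a nucleation hazard proportional to c^n, the
# cumulative hazard has the closed form K * c_final^n with the ramp-time
# constant absorbed into K. Self-poisoning (stalling of zipper growth at high
# monomer flux) is modelled as a Hill-type suppression of the hazard with a
# residual escape channel that restores growth at high concentration:
#   Lambda(c) = K c^n * [f_res + (1 - f_res) / (1 + (c / c_poison)^m)]
# Setting f_res = 0 gives a pure Hill suppression; c_poison = Inf disables
# poisoning entirely.

#' Parameters of the generative nucleation model
#'
#' Defaults describe the standard assay conditions: a roughly hundred-fold
#' log-spread of expression (1-200 concentration units, nominally uM),
#' reaction order one, no poisoning, no conformational template.
#'
#' @param kappa Nucleation rate scale (per uM^n_order over the induction;
#'   default 0.02, putting the half-nucleated point near 35 uM).
#' @param n_order Reaction order (default 1).
#' @param c_poison Poisoning midpoint in uM (`Inf` disables; default `Inf`).
#' @param m_hill Poisoning steepness (default 3).
#' @param f_resid Residual hazard fraction escaping poisoning at high
#'   concentration (default 0.15; 0 recovers a pure Hill suppression).
#' @param c_range Final-concentration range `c(min, max)` in uM, sampled
#'   log-uniformly per cell (default `c(1, 200)`).
#' @param a_pos Mean AmFRET of the fully assembled state (default 0.35; the
#'   bilaterally contiguous preset uses a higher value because lamellar
#'   amyloid packs subunits more densely).
#' @param a_mid_frac Fraction of nucleated cells emitted at the intermediate
#'   (growth-limited) AmFRET level, halfway between 0 and `a_pos` (default 0.1).
#' @param sigma_neg,sigma_pos AmFRET emission SDs of the monomeric and
#'   assembled states (defaults 0.02 and 0.06).
#' @param template_factor Multiplier on `kappa` for cells carrying a
#'   pre-existing Q/N-rich amyloid template (default 1).
#' @param n_cells Number of cells to generate (default 20000).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @param channels Named list of emission constants for the raw cytometry
#'   channels (log-normal scatter distributions and linear gains), chosen so
#'   that generated events fall inside the default gates under the default
#'   logicle transform. See Details.
#'
#' @details The channel model: side scatter, forward scatter area/height/width
#' and autofluorescence are log-normal; `acceptor = concentration * ssc *
#' acceptor_gain` (so the derived concentration proxy `acceptor / ssc` is
#' exactly proportional to the true concentration, with
#' `acceptor_gain` arbitrary units per uM); `donor = concentration * ssc *
#' donor_gain`; `fret = amfret * acceptor`.
#'
#' @return An object of class `"nucleation_params"` (a named list).
#' @export
nucleation_params <- function(kappa = 0.02,
                              n_order = 1,
                              c_poison = Inf,
                              m_hill = 3,
                              f_resid = 0.15,
                              c_range = c(1, 200),
                              a_pos = 0.35,
                              a_mid_frac = 0.1,
                              sigma_neg = 0.02,
                              sigma_pos = 0.06,
                              template_factor = 1,
                              n_cells = 20000,
                              seed = 1,
                              channels = list()) {
  p <- list(
    kappa = kappa, n_order = n_order, c_poison = c_poison, m_hill = m_hill,
    f_resid = f_resid, c_range = c_range, a_pos = a_pos,
    a_mid_frac = a_mid_frac, sigma_neg = sigma_neg, sigma_pos = sigma_pos,
    template_factor = template_factor, n_cells = as.integer(n_cells),
    seed = as.integer(seed)
  )
  if (p$kappa < 0 || p$sigma_neg < 0 || p$sigma_pos < 0) {
    abort("rates and SDs must be >= 0.")
  }
  if (p$c_range[1] <= 0 || p$c_range[2] < p$c_range[1]) {
    abort("`c_range` must satisfy 0 < c_min <= c_max.")
  }
  if (p$a_mid_frac < 0 || p$a_mid_frac > 1) abort("`a_mid_frac` must be in [0, 1].")
  if (p$template_factor < 0) abort("`template_factor` must be >= 0.")
  if (p$n_cells < 1) abort("`n_cells` must be >= 1.")
  defaults <- list(
    ssc_meanlog = log(2e5), ssc_sdlog = 0.25,
    fs_a_meanlog = log(5e5), fs_a_sdlog = 0.2,
    fs_h_meanlog = log(4.3e6), fs_h_sdlog = 0.03,
    fs_w_meanlog = log(4e5), fs_w_sdlog = 0.2,
    autofluor_meanlog = log(300), autofluor_sdlog = 0.3,
    acceptor_gain = 10, donor_gain = 0.1
  )
  defaults[names(channels)] <- channels
  p$channels <- defaults
  structure(p, class = "nucleation_params")
}

#' @export
print.nucleation_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<nucleation_params> kappa=%g n=%g c_poison=%g m=%g f_resid=%g ",
      "template=%g c_range=[%g,%g] a_pos=%g mid_frac=%g n_cells=%d seed=%d\n"
    ),
    x$kappa, x$n_order, x$c_poison, x$m_hill, x$f_resid, x$template_factor,
    x$c_range[1], x$c_range[2], x$a_pos, x$a_mid_frac, x$n_cells, x$seed
  ))
  invisible(x)
}

#' Named presets for the standard assay scenarios
#'
#' `pinminus_QU` / `pinminus_QB`: untemplated nucleation of unilaterally or
#' bilaterally contiguous sequences (the latter with higher assembled-state
#' AmFRET and a larger growth-limited intermediate fraction). `PINplus`: the
#' templated regime (hazard multiplied 100-fold, so nucleation is frequent
#' even at the lowest sampled concentrations). `negative_control`: a
#' monomer-only sample (`kappa = 0`) spanning the same concentration range.
#' `pinminus_QB_poisoned`: bilateral preset with a poisoning midpoint at
#' 30 uM.
#'
#' @param name One of `"pinminus_QU"`, `"pinminus_QB"`, `"PINplus"`,
#'   `"negative_control"`, `"pinminus_QB_poisoned"`.
#' @param ... Overrides forwarded to [nucleation_params()].
#' @return A [nucleation_params()] object.
#' @export
damfret_preset <- function(name = c(
                             "pinminus_QU", "pinminus_QB", "PINplus",
                             "negative_control", "pinminus_QB_poisoned"
                           ), ...) {
  name <- match.arg(name)
  base <- switch(name,
    pinminus_QU = list(a_pos = 0.35, a_mid_frac = 0.05),
    pinminus_QB = list(a_pos = 0.60, a_mid_frac = 0.2),
    PINplus = list(a_pos = 0.60, a_mid_frac = 0.2, template_factor = 100),
    negative_control = list(kappa = 0),
    pinminus_QB_poisoned = list(a_pos = 0.60, a_mid_frac = 0.2, c_poison = 30)
  )
  do.call(nucleation_params, utils::modifyList(base, list(...)))
}

#' Cumulative nucleation probability at a final concentration
#'
#' Closed-form probability that a cell whose concentration ramped up to
#' `c_final` has nucleated: `P = 1 - exp(-Lambda(c_final))` with the
#' cumulative hazard described in [nucleation_params()]. Monotone in `kappa`;
#' monotone in `c_final` whenever `f_resid > 0` or `c_poison = Inf`.
#'
#' @param c_final Final concentration(s), > 0 (uM).
#' @param p A [nucleation_params()] object.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' p <- nucleation_params()
#' nucleation_probability(c(1, 35, 200), p)
#' @export
nucleation_probability <- function(c_final, p) {
  stopifnot(inherits(p, "nucleation_params"))
  if (any(c_final <= 0)) abort("`c_final` must be > 0.")
  K <- p$kappa * p$template_factor
  suppress <- if (is.infinite(p$c_poison)) {
    1
  } else {
    p$f_resid + (1 - p$f_resid) / (1 + (c_final / p$c_poison)^p$m_hill)
  }
  1 - exp(-K * c_final^p$n_order * suppress)
}
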