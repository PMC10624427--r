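# Negative-control gate profile: the concentration-binned upper AmFRET gate.

#' Build a gate profile from a negative control
#'
#' Divides the acceptor-intensity axis into `n_bins` logarithmically spaced
#' bins over `acceptor_range`, takes the `percentile` quantile (linear
#' interpolation between order statistics) of the control's AmFRET
#' distribution in each bin, fills invalid bins (geometric centre below
#' `min_acceptor`, above the control's 99th acceptor percentile, or empty)
#' from the nearest valid bin, boxcar-smooths with a width of `smooth_width`
#' bins (edge bins shrink the window symmetrically), and shifts the result
#' up by `shift` AmFRET units. The lower gate is the constant `lower`.
#'
#' @param control A gated, AmFRET-derived negative-control event tibble (see
#'   [apply_gates()], [derive_amfret()]).
#' @param n_bins Number of acceptor bins (default 64).
#' @param percentile Per-bin upper-gate quantile (default 0.99).
#' @param acceptor_range Acceptor intensity range covered by the bins
#'   (default `c(1e5, 1e9)` units; wide enough for all data sets).
#' @param min_acceptor Bins centred below this acceptor intensity are invalid
#'   (default 2e6 units).
#' @param smooth_width Boxcar width in bins (default 5).
#' @param shift Upward shift of the upper gate in AmFRET units (default
#'   0.028).
#' @param lower Constant lower gate in AmFRET units (default -0.2).
#' @return An object of class `"gate_profile"`: bin edges and centres, the
#'   per-bin upper gate, the lower gate, the per-bin validity mask and the
#'   configuration used.
#' @examples
#' ctl <- generate_negative_control(nucleation_params(n_cells = 5000, seed = 1))
#' prof <- ctl |> apply_gates() |> derive_amfret() |> build_gate_profile()
#' range(prof$upper_gate)
#' @export
build_gate_profile <- function(control,
                               n_bins = 64,
                               percentile = 0.99,
                               acceptor_range = c(1e5, 1e9),
                               min_acceptor = 2e6,
                               smooth_width = 5,
                               shift = 0.028,
                               lower = -0.2) {
  check_channels(control, c("acceptor", "amfret"))
  if (nrow(control) == 0) abort("empty control table.", class = "qzipper_empty_input")
  edges <- 10^seq(log10(acceptor_range[1]), log10(acceptor_range[2]),
    length.out = n_bins + 1
  )
  centers <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  bin <- bin_acceptor(control$acceptor, edges)

  q_raw <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  tab <- tapply(control$amfret, factor(bin, levels = seq_len(n_bins)),
    stats::quantile,
    probs = percentile, names = FALSE, type = 7
  )
  q_raw[] <- unlist(tab)
  counts <- as.integer(table(factor(bin, levels = seq_len(n_bins))))

  acc_p99 <- stats::quantile(control$acceptor, 0.99, names = FALSE)
  valid <- counts > 0 & centers >= min_acceptor & centers <= acc_p99 &
    !is.na(q_raw)
  if (!any(valid)) {
    abort("no valid bins in the control.", class = "qzipper_no_valid_bins")
  }

  # nearest-valid fill
  vidx <- which(valid)
  filled <- q_raw
  for (i in which(!valid)) {
    nearest <- vidx[which.min(abs(vidx - i))]
    filled[i] <- q_raw[nearest]
  }

  smoothed <- boxcar_smooth(filled, smooth_width)
  upper <- smoothed + shift
  if (any(upper <= lower)) {
    abort("upper gate fell below the lower gate; check the control.")
  }

  structure(
    list(
      bin_edges = edges,
      bin_centers = centers,
      upper_gate = upper,
      lower_gate = lower,
      valid = valid,
      counts = counts,
      config = list(
        n_bins = n_bins, percentile = percentile,
        acceptor_range = acceptor_range, min_acceptor = min_acceptor,
        smooth_width = smooth_width, shift = shift, lower = lower
      )
    ),
    class = "gate_profile"
  )
}

# Clamp events to the profile's bins: below-range events go to bin 1,
# above-range to bin n.
bin_acceptor <- function(acceptor, edges) {
  b <- findInterval(acceptor, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

# Boxcar mean with symmetric window shrinkage at the edges: bin i averages
# over i +/- h where h = min(half_width, i - 1, n - i).
boxcar_smooth <- function(x, width) {
  n <- length(x)
  h0 <- (width - 1) %/% 2
  vapply(seq_len(n), function(i) {
    h <- min(h0, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' @export
print.gate_profile <- function(x, ...) {
  cat(sprintf(
    "<gate_profile> %d bins over acceptor [%.3g, %.3g]; %d valid; upper gate %.4f..%.4f; lower %.2f\n",
    length(x$upper_gate), x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
    sum(x$valid), min(x$upper_gate), max(x$upper_gate), x$lower_gate
  ))
  invisible(x)
}

#' Tidy a gate profile into a per-bin tibble
#'
#' @param x A [build_gate_profile()] result.
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin`, `acceptor_lo`, `acceptor_hi`,
#'   `acceptor_center`, `upper_gate`, `lower_gate`, `valid`, `n_control`.
#' @export
tidy.gate_profile <- function(x, ...) {
  n <- length(x$upper_gate)
  tibble(
    bin = seq_len(n),
    acceptor_lo = x$bin_edges[-(n + 1)],
    acceptor_hi = x$bin_edges[-1],
    acceptor_center = x$bin_centers,
    upper_gate = x$upper_gate,
    lower_gate = x$lower_gate,
    valid = x$valid,
    n_control = x$counts
  )
}
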