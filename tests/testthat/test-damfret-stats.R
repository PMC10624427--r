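flat_sample <- function(amfret, n = 1000, acc = 1e7) {
  tibble::tibble(
    acceptor = rep(acc, n), ssc = 1e5,
    amfret = rep(amfret, length.out = n),
    concentration = acceptor / ssc
  )
}

test_that("fgate hits its trivial extremes and stays in [0, 1]", {
  prof <- default_profile()
  expect_equal(fgate(flat_sample(10), prof), 1)
  expect_equal(fgate(flat_sample(-0.5), prof), 0) # below the lower gate
  expect_equal(fgate(flat_sample(0), prof), 0)
  expect_error(fgate(flat_sample(0)[0, ], prof), class = "qzipper_empty_input")
})

test_that("the control scores near zero against its own profile", {
  expect_lte(fgate(default_control(), default_profile()), 0.015)
})

test_that("fgate responds monotonically to added events", {
  prof <- default_profile()
  base <- flat_sample(0, n = 500)
  f0 <- fgate(base, prof)
  f_hi <- fgate(dplyr::bind_rows(base, flat_sample(5, n = 100)), prof)
  f_lo <- fgate(dplyr::bind_rows(base, flat_sample(-0.1, n = 100)), prof)
  expect_gte(f_hi, f0)
  expect_lte(f_lo, f0)
})

test_that("fraction-positive curves track the generator truth", {
  prof <- default_profile()
  sat <- gated_sample(nucleation_params(kappa = 100, a_mid_frac = 0, n_cells = 5000, seed = 2))
  cv <- positive_fraction_curve(sat, prof)
  expect_true(all(cv$fraction[cv$n >= 10] > 0.99))
  neg <- gated_sample(nucleation_params(kappa = 0, n_cells = 5000, seed = 2))
  cvn <- positive_fraction_curve(neg, prof)
  expect_true(all(cvn$fraction[cvn$n >= 10] <= 0.02))
  expect_equal(sum(cv$n), nrow(sat))
  expect_true(all(cv$ci_lo - 1e-9 <= cv$fraction & cv$fraction <= cv$ci_hi + 1e-9,
    na.rm = TRUE
  ))
})

test_that("intermediate fraction recovers the generator's mid-level share", {
  prof <- default_profile()
  mid <- gated_sample(damfret_preset("pinminus_QB", a_mid_frac = 0.3, n_cells = 20000, seed = 31))
  expect_lt(abs(intermediate_fraction(mid, prof) - 0.3), 0.1)
  none <- gated_sample(damfret_preset("pinminus_QB", a_mid_frac = 0, n_cells = 20000, seed = 31))
  expect_lt(intermediate_fraction(none, prof), 0.05)
  allneg <- gated_sample(nucleation_params(kappa = 0, n_cells = 2000, seed = 1))
  expect_warning(val <- intermediate_fraction(allneg, prof), "no detectable")
  expect_equal(val, 0)
})

test_that("max_amfret is a median over the assembled top-decile population", {
  prof <- default_profile()
  pm <- flat_sample(0.7, n = 500)
  expect_equal(max_amfret(pm, prof), 0.7)
  # robust to 1% outliers at 10x
  out <- pm
  out$amfret[1:5] <- 7
  expect_equal(max_amfret(out, prof), 0.7)
  qb <- gated_sample(damfret_preset("pinminus_QB", n_cells = 10000, seed = 32))
  qu <- gated_sample(damfret_preset("pinminus_QU", n_cells = 10000, seed = 33))
  expect_gt(max_amfret(qb, prof), max_amfret(qu, prof))
  neg <- gated_sample(nucleation_params(kappa = 0, n_cells = 2000, seed = 2))
  expect_error(max_amfret(neg, prof), class = "qzipper_empty_selection")
})

test_that("the spline reproduces noiseless linear input", {
  prof <- default_profile()
  centers <- prof$bin_centers[20:45]
  ev <- tibble::tibble(
    acceptor = rep(centers, each = 20),
    ssc = 1e5,
    concentration = acceptor / ssc,
    amfret = 0.1 + 0.05 * log10(acceptor)
  )
  sc <- spline_curve(ev, prof)
  expect_lt(max(abs(sc$fit - sc$median_amfret)), 1e-6)
  expect_error(spline_curve(ev[1:40, ], prof), class = "qzipper_too_few_bins")
})

test_that("population-split splines separate upper and lower branches", {
  prof <- default_profile()
  mixed <- gated_sample(damfret_preset("pinminus_QB", n_cells = 20000, seed = 34))
  sc <- spline_curve(mixed, prof, split_populations = TRUE)
  expect_setequal(unique(sc$population), c("upper", "lower"))
  up <- sc[sc$population == "upper", ]
  lo <- sc[sc$population == "lower", ]
  shared_bins <- intersect(up$bin, lo$bin)
  expect_true(all(up$fit[match(shared_bins, up$bin)] >
    lo$fit[match(shared_bins, lo$bin)]))
})
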