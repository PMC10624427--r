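test_that("closed-form nucleation probability matches the ramp quadrature", {
  # Oracle: inhomogeneous-Poisson survival along a linear concentration ramp
  # c(t) = c_final * t / t_f with hazard rate k c(t)^n. The closed form
  # absorbs k t_f / (n + 1) into the package's kappa.
  t_f <- 16 # hours, arbitrary
  for (n_ord in c(1, 2)) {
    p <- nucleation_params(kappa = 0.02, n_order = n_ord)
    k_rate <- p$kappa * (n_ord + 1) / t_f
    for (cf in c(1, 10, 50, 200)) {
      hazard_int <- stats::integrate(
        function(t) k_rate * (cf * t / t_f)^n_ord, 0, t_f
      )$value
      expect_equal(
        nucleation_probability(cf, p), 1 - exp(-hazard_int),
        tolerance = 1e-8
      )
    }
  }
})

test_that("nucleation probability has the right limits and monotonicities", {
  grid <- exp(seq(log(1), log(200), length.out = 50))
  p0 <- nucleation_params(kappa = 0)
  expect_equal(nucleation_probability(grid, p0), rep(0, 50))
  phuge <- nucleation_params(kappa = 1e6)
  expect_true(all(nucleation_probability(grid, phuge) > 1 - 1e-10))
  p1 <- nucleation_params(kappa = 0.01)
  p2 <- nucleation_params(kappa = 0.05)
  expect_true(all(nucleation_probability(grid, p2) >= nucleation_probability(grid, p1)))
  pr <- nucleation_probability(grid, nucleation_params())
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) > 0)) # monotone without poisoning
  expect_error(nucleation_probability(0, p1), "c_final")
})

test_that("finite poisoning midpoint produces a slope dip that recovers", {
  p <- damfret_preset("pinminus_QB_poisoned")
  lc <- seq(log(1), log(200), length.out = 400)
  pr <- nucleation_probability(exp(lc), p)
  slope <- diff(pr) / diff(lc)
  i_min <- which.min(slope)
  # local slope minimum strictly inside the range, near c_poison
  expect_gt(i_min, 10)
  expect_lt(i_min, length(slope) - 10)
  c_at_min <- exp(lc[i_min])
  expect_gt(c_at_min, p$c_poison / 3)
  expect_lt(c_at_min, p$c_poison * 3)
  # slope falls from its early maximum, then rises again
  expect_lt(slope[i_min], 0.2 * max(slope[1:i_min]))
  expect_gt(max(slope[i_min:length(slope)]), 5 * slope[i_min])
})

test_that("the generator is deterministic and seed-sensitive", {
  p <- nucleation_params(n_cells = 2000, seed = 17)
  a <- generate_sample(p)
  b <- generate_sample(p)
  expect_identical(a, b)
  c2 <- generate_sample(nucleation_params(n_cells = 2000, seed = 18))
  expect_false(identical(a$fret, c2$fret))
  # different seeds agree in distribution: marginal means within 3 SE
  for (col in c("ssc", "fs_a", "true_concentration")) {
    se <- stats::sd(a[[col]]) / sqrt(nrow(a))
    expect_lt(abs(mean(a[[col]]) - mean(c2[[col]])), 3.5 * se * sqrt(2))
  }
})

test_that("negative control never emits assembled-level AmFRET", {
  p <- nucleation_params(n_cells = 20000, seed = 3)
  ctl <- generate_negative_control(p)
  expect_false(any(ctl$nucleated))
  amfret <- ctl$fret / ctl$acceptor
  # tail bound: a_pos/2 is ~9 sigma_neg away from 0
  expect_equal(sum(amfret > p$a_pos / 2), 0)
})

test_that("raw channels are positive and concentrations span the range", {
  ev <- generate_sample(nucleation_params(n_cells = 5000, seed = 4))
  for (col in c("fs_a", "fs_h", "fs_w", "ssc", "donor", "acceptor", "autofluor")) {
    expect_true(all(ev[[col]] > 0), label = col)
  }
  expect_gte(min(ev$true_concentration), 1)
  expect_lte(max(ev$true_concentration), 200)
  # log-uniform sampling: roughly equal mass per decade-slice
  thirds <- cut(log(ev$true_concentration), 3)
  expect_true(max(abs(table(thirds) / 5000 - 1 / 3)) < 0.05)
})

test_that("bilateral preset assembles at higher AmFRET than unilateral", {
  qb <- gated_sample(damfret_preset("pinminus_QB", n_cells = 8000, seed = 5))
  qu <- gated_sample(damfret_preset("pinminus_QU", n_cells = 8000, seed = 5))
  med_pos <- function(ev) stats::median(ev$amfret[ev$nucleated & !ev$mid_level])
  expect_gt(med_pos(qb), med_pos(qu))
})

test_that("generated events pass the default gates", {
  ev <- generate_sample(nucleation_params(n_cells = 10000, seed = 6))
  g <- apply_gates(ev)
  expect_gt(nrow(g) / nrow(ev), 0.95)
})
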