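test_that("rolling-ball subtraction removes flat and offset backgrounds", {
  img <- matrix(5, 40, 30)
  expect_equal(rolling_ball_subtract(img, radius = 8), matrix(0, 40, 30))
  withr::with_seed(2, {
    noisy <- matrix(stats::runif(40 * 30, 10, 12), 40, 30)
  })
  # adding a constant leaves the output unchanged
  expect_equal(
    rolling_ball_subtract(noisy + 100, radius = 8),
    rolling_ball_subtract(noisy, radius = 8),
    tolerance = 1e-12
  )
  expect_true(all(rolling_ball_subtract(noisy, radius = 8) >= 0))
  expect_error(rolling_ball_subtract(img, radius = 50), "smaller")
  expect_error(rolling_ball_subtract(img, radius = 0), "radius")
})

test_that("band integrals survive subtraction of a sloped background", {
  bands <- data.frame(row = c(60, 130), width = 3, amplitude = c(80, 50), lane_center = 30)
  clean <- synth_gel_image(200, 60, bands, background_slope = 0)
  sloped <- synth_gel_image(200, 60, bands,
    background_slope = 0.3,
    background_offset = 10
  )
  sub <- rolling_ball_subtract(sloped, radius = 20)
  p_clean <- line_profile(clean, 30)
  p_sub <- line_profile(sub, 30)
  band_int <- function(p, lo, hi) sum(p$intensity[lo:hi])
  for (b in seq_len(nrow(bands))) {
    lo <- bands$row[b] - 12
    hi <- bands$row[b] + 12
    rel <- abs(band_int(p_sub, lo, hi) - band_int(p_clean, lo, hi)) /
      band_int(p_clean, lo, hi)
    expect_lt(rel, 0.05)
  }
})

test_that("line profiles average the lane swath", {
  img <- matrix(rep(1:20, 10), 20, 10)
  p <- line_profile(img, 5, width = 4)
  expect_equal(p$intensity, as.numeric(1:20)) # uniform across columns
  # width 1 extracts a single column
  img2 <- img
  img2[, 5] <- 99
  expect_equal(line_profile(img2, 5, width = 1)$intensity, rep(99, 20))
  expect_error(line_profile(img, 1, width = 10), class = "qzipper_bad_lane")
  # single band peaks at the set row
  bands <- data.frame(row = 77, width = 4, amplitude = 100, lane_center = 8)
  gel <- synth_gel_image(150, 16, bands)
  pk <- line_profile(gel, 8)
  expect_equal(which.max(pk$intensity), 77)
})

test_that("normalization yields unit integral and is idempotent", {
  bands <- data.frame(
    row = c(40, 90), width = 5, amplitude = c(100, 50),
    lane_center = 10
  )
  gel <- synth_gel_image(140, 20, bands)
  p <- line_profile(gel, 10)
  np <- normalize_profile(p)
  expect_equal(qzipper:::profile_integral(np), 1, tolerance = 1e-9)
  expect_equal(normalize_profile(np)$intensity, np$intensity, tolerance = 1e-12)
  # scaling the input does not change the normalized output
  p2 <- p
  p2$intensity <- p2$intensity * 7
  expect_equal(normalize_profile(p2)$intensity, np$intensity, tolerance = 1e-12)
  # peak ratio is preserved
  pk1 <- max(np$intensity[30:50])
  pk2 <- max(np$intensity[80:100])
  expect_equal(pk1 / pk2, 2, tolerance = 0.01)
  zero <- p
  zero$intensity <- 0
  expect_error(normalize_profile(zero), class = "qzipper_degenerate_profile")
})

test_that("profile summaries sit where the mass sits", {
  sym <- data.frame(row = 70, width = 6, amplitude = 100, lane_center = 8)
  p <- line_profile(synth_gel_image(140, 16, sym), 8)
  s <- profile_summary(p)
  expect_equal(s$median_position, 70, tolerance = 1)
  expect_lt(s$q25, 70)
  expect_gt(s$q75, 70)
  bimod <- data.frame(
    row = c(40, 100), width = 4, amplitude = 80,
    lane_center = 8
  )
  pb <- line_profile(synth_gel_image(140, 16, bimod), 8)
  sb <- profile_summary(pb)
  expect_gt(sb$median_position, 45)
  expect_lt(sb$median_position, 95)
  # intensity scale invariance
  pb2 <- pb
  pb2$intensity <- pb2$intensity * 3.7
  expect_equal(profile_summary(pb2), sb, tolerance = 1e-9)
})
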