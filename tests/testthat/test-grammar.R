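test_that("make_repeat builds periodic repeats, truncates, and validates", {
  expect_equal(make_repeat(4, "N", 60), strrep("QQQQN", 12))
  expect_equal(make_repeat(1, "N", 4), "QNQN")
  expect_equal(make_repeat(60, "N", 60), strrep("Q", 60)) # no N fits
  expect_equal(make_repeat(0, "N", 5), "NNNNN") # homopolymer of x
  expect_equal(make_repeat(3, "Q", 7), strrep("Q", 7)) # x = Q gives polyQ
  expect_equal(make_repeat(1, "N", 7, n_x = 2), "QNNQNNQ")
  expect_equal(make_repeat(2, "Q", 6, base = "N"), "NNQNNQ")
  expect_error(make_repeat(4, "Z", 10), "non-canonical")
  expect_error(make_repeat(4, "N", 0), "total_len")
})

test_that("contiguity matches the worked examples", {
  ct <- contiguity(c("QNQNQNQ", make_repeat(4, "N", 30), "NNNN"))
  expect_equal(ct$max_unilateral, c(4L, 4L, 0L))
  expect_equal(ct$max_bilateral, c(1L, 4L, 0L))
})

test_that("contiguity agrees with the brute-force oracle", {
  seqs <- all_qn_sequences(10)
  got <- contiguity(seqs)
  expected <- t(vapply(seqs, oracle_contiguity, c(uni = 0L, bi = 0L)))
  expect_equal(got$max_unilateral, unname(expected[, "uni"]))
  expect_equal(got$max_bilateral, unname(expected[, "bi"]))

  withr::with_seed(99, {
    rnd <- vapply(1:300, function(i) random_seq(sample(5:30, 1)), character(1))
  })
  got <- contiguity(rnd)
  expected <- t(vapply(rnd, oracle_contiguity, c(uni = 0L, bi = 0L)))
  expect_equal(got$max_unilateral, unname(expected[, "uni"]))
  expect_equal(got$max_bilateral, unname(expected[, "bi"]))
})

test_that("contiguity invariants hold on random sequences", {
  withr::with_seed(7, {
    rnd <- vapply(1:200, function(i) random_seq(sample(1:40, 1)), character(1))
  })
  ct <- contiguity(rnd)
  expect_true(all(ct$max_unilateral >= ceiling(ct$max_bilateral / 2)))
  expect_true(all(ct$max_unilateral >= 0 & ct$max_unilateral <= ct$length))
  expect_true(all(ct$max_bilateral >= 0 & ct$max_bilateral <= ct$length))
})

test_that("homopolymer polyQ has the closed-form contiguity", {
  for (L in c(1, 2, 7, 12, 35, 36, 60)) {
    ct <- contiguity(strrep("Q", L))
    expect_equal(ct$max_bilateral, L)
    expect_equal(ct$max_unilateral, ceiling(L / 2))
  }
})

test_that("strand windows require a complete glutamine face", {
  expect_equal(find_strand_windows("QSQSQS"), tibble::tibble(start = 1L, end = 6L))
  expect_equal(nrow(find_strand_windows("QQQQQQ")), 1L)
  expect_equal(nrow(find_strand_windows("QNQNNN")), 0L)
  expect_equal(nrow(find_strand_windows("QQQ", strand_len = 6)), 0L)
  # bilateral mode needs every residue to be Q
  expect_equal(nrow(find_strand_windows("QSQSQS", mode = "bilateral")), 0L)
  expect_equal(nrow(find_strand_windows("QQQQQQ", mode = "bilateral")), 1L)
  # one mid-strand substitution keeps one face but kills the bilateral window
  expect_equal(nrow(find_strand_windows("QQNQQQ")), 1L)
  expect_equal(nrow(find_strand_windows("QQNQQQ", mode = "bilateral")), 0L)
})

test_that("disruption ranks follow the permissiveness ordering", {
  rk <- disruption_rank(c("S", "A", "H", "G", "N"))
  expect_equal(rk$rank, c(1, 2, 3, 4, 4))
  expect_true(all(rk$known))
  expect_true(rk$rank[rk$residue == "A"] > rk$rank[rk$residue == "S"])
  expect_true(rk$rank[rk$residue == "A"] < rk$rank[rk$residue == "H"])
  unk <- disruption_rank("W")
  expect_false(unk$known)
})

test_that("FASTA scan produces the flat grammar report", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">polyQ60", strrep("Q", 60),
    ">Q4N", make_repeat(4, "N", 60),
    ">nucleus33", design_minimal_nucleus()
  ), fa)
  rep <- scan_sequences(fa)
  expect_equal(rep$name, c("polyQ60", "Q4N", "nucleus33"))
  expect_equal(rep$de_novo_competent, c(TRUE, FALSE, TRUE))
  expect_equal(rep$architecture, c("QB", "NONE", "QB"))
  out <- withr::local_tempfile(fileext = ".tsv")
  scan_sequences(fa, out = out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(back$length, c(60, 60, 33))
})
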