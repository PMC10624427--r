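q_series <- function(q, x = "N", n_x = 1) {
  if (q == 0) strrep(x, 60) else make_repeat(q, x, 60, n_x = n_x)
}

test_that("glutamine-interruption series shows the odd-even effect", {
  calls <- vapply(
    0:9, function(q) classify_zipper(q_series(q))$de_novo_competent,
    logical(1)
  )
  expect_equal(calls, c(
    FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, # q = 0..5: odd only
    TRUE, TRUE, TRUE, TRUE # q >= 6: all competent
  ))
})

test_that("the odd-even effect is independent of the interrupter identity", {
  for (X in c("S", "A", "G", "H")) {
    calls <- vapply(
      c(3, 4, 5), function(q) classify_zipper(q_series(q, X))$de_novo_competent,
      logical(1)
    )
    expect_equal(calls, c(TRUE, FALSE, TRUE), label = paste("series", X))
  }
})

test_that("asparagine-predominant repeats are never de novo competent", {
  for (q in 2:4) {
    cz <- classify_zipper(make_repeat(q, "Q", 60, base = "N"))
    expect_false(cz$de_novo_competent, label = paste("N", q, "Q"))
    expect_true(cz$template_competent) # Q+N composition route
  }
})

test_that("the alternating sequence is classified identically from either end", {
  # (NQ)30 and (QN)30 carry the same every-other-position pattern; the
  # grammar cannot (and should not) distinguish them.
  a <- classify_zipper(make_repeat(1, "N", 60))
  b <- classify_zipper(make_repeat(1, "Q", 60, base = "N"))
  expect_equal(a$de_novo_competent, b$de_novo_competent)
  expect_equal(a$max_unilateral, b$max_unilateral)
})

test_that("double insertions abolish competence of odd repeats", {
  for (q in c(1, 3)) {
    expect_false(classify_zipper(q_series(q, n_x = 2))$de_novo_competent,
      label = paste("Q", q, "NN")
    )
  }
})

test_that("a single Q-to-N knockout blocks the minimal nucleus", {
  m <- design_minimal_nucleus()
  expect_true(classify_zipper(m)$de_novo_competent)
  for (i in c(1, 3, 6, 12, 28)) { # positions inside different strands
    mut <- m
    substr(mut, i, i) <- "N"
    expect_false(classify_zipper(mut)$de_novo_competent,
      label = paste("knockout at", i)
    )
  }
})

test_that("polyQ competence respects the clinical length threshold", {
  lens <- c(25, 30, 35, 40, 45, 50, 55, 60)
  calls <- vapply(
    lens, function(L) classify_zipper(strrep("Q", L))$de_novo_competent,
    logical(1)
  )
  expect_equal(calls, lens >= 36)
})

test_that("architecture labels follow the contiguity thresholds", {
  expect_equal(classify_zipper(strrep("Q", 60))$architecture, "QB")
  expect_equal(classify_zipper(q_series(5))$architecture, "QU")
  expect_equal(classify_zipper(q_series(7))$architecture, "QB")
  expect_equal(classify_zipper(q_series(2))$architecture, "NONE")
  expect_equal(classify_zipper(strrep("N", 60))$architecture, "NONE")
})

test_that("template competence uses the Q+N composition heuristic", {
  cz <- classify_zipper(c(q_series(2), strrep("S", 60)))
  expect_equal(cz$template_competent, c(TRUE, FALSE))
  # threshold is configurable
  cz2 <- classify_zipper(q_series(2), qn_threshold = 1.01)
  expect_false(cz2$template_competent)
})

test_that("classification is invariant under sequence reversal", {
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  withr::with_seed(31, {
    rnd <- vapply(1:100, function(i) random_seq(sample(10:45, 1)), character(1))
  })
  fwd <- classify_zipper(rnd)
  bwd <- classify_zipper(vapply(rnd, rev_str, character(1)))
  expect_equal(fwd$de_novo_competent, bwd$de_novo_competent)
  expect_equal(fwd$max_unilateral, bwd$max_unilateral)
  expect_equal(fwd$max_bilateral, bwd$max_bilateral)
  expect_equal(fwd$architecture, bwd$architecture)
})

test_that("de novo competence implies threadability", {
  withr::with_seed(32, {
    rnd <- vapply(1:150, function(i) random_seq(sample(6:60, 1), c("Q", "N", "G")),
      character(1)
    )
  })
  cz <- classify_zipper(rnd)
  expect_true(all(!cz$de_novo_competent | cz$threadable))
  expect_true(all(!cz$de_novo_competent | cz$template_competent))
})

test_that("borderline permissive-serine calls are flagged in the note column", {
  cz <- classify_zipper(q_series(4, "S"))
  expect_false(cz$de_novo_competent)
  expect_match(cz$note, "permissive")
  expect_true(is.na(classify_zipper(q_series(4, "N"))$note))
})
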