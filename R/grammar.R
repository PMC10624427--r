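# Core sequence grammar for the glutamine steric zipper.
#
# A Q zipper strand presents glutamine side chains on one face of a
# beta-strand, i.e. at every other residue position. "Unilateral contiguity"
# counts glutamines occupying consecutive same-parity positions (5 Qs span 9
# residues); "bilateral contiguity" counts consecutive glutamines, which can
# supply both faces of a strand and hence lamellar growth.

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

max_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

contiguity_one <- function(s) {
  ch <- seq_chars(s)
  is_q <- ch == "Q"
  bilateral <- max_run(is_q)
  track_runs <- lapply(0:1, function(p) {
    if (1L + p > length(ch)) {
      return(integer(0))
    }
    idx <- seq.int(1L + p, length(ch), by = 2L)
    r <- rle(is_q[idx])
    runs <- r$lengths[r$values]
    if (length(runs) == 0) integer(0) else as.integer(sort(runs, decreasing = TRUE))
  })
  unilateral <- max(0L, unlist(track_runs))
  list(
    max_unilateral = as.integer(unilateral),
    max_bilateral = as.integer(bilateral),
    runs = tibble(
      parity = c(0L, 1L),
      runs = track_runs
    )
  )
}

#' Glutamine contiguity profile of a sequence
#'
#' Computes, for each sequence, the longest run of glutamines at consecutive
#' same-parity positions (`max_unilateral`: Qs at positions i, i+2, i+4, ...,
#' either parity) and the longest run of consecutive glutamines
#' (`max_bilateral`). De novo zipper propagation requires at least five
#' unilaterally or six bilaterally contiguous glutamines.
#'
#' @param residues Character vector of amino-acid sequences.
#' @param name Optional character vector of sequence names.
#' @return A tibble with one row per sequence: `name`, `length`,
#'   `max_unilateral`, `max_bilateral`, and a list-column `runs` holding the
#'   per-parity run lengths for reporting.
#' @examples
#' contiguity("QNQNQNQ") # 4 unilateral, 1 bilateral
#' @export
contiguity <- function(residues, name = NULL) {
  residues <- validate_qseq(residues)
  if (is.null(name)) name <- sprintf("seq%d", seq_along(residues))
  out <- purrr::map(residues, contiguity_one)
  tibble(
    name = name,
    length = nchar(residues),
    max_unilateral = purrr::map_int(out, "max_unilateral"),
    max_bilateral = purrr::map_int(out, "max_bilateral"),
    runs = purrr::map(out, "runs")
  )
}

#' Candidate zipper strand windows in a sequence
#'
#' In `"unilateral"` mode a window of `strand_len` residues can serve as one
#' zipper strand when one of its two parity tracks is all glutamine
#' (ceiling(strand_len/2) alternating Qs presenting a complete face of side
#' chains). In `"bilateral"` mode every residue of the window must be
#' glutamine: short-strand lamellar zippers engage both faces of each strand
#' (one nucleates, the contralateral one is the lateral growth surface), so a
#' single non-Q anywhere disqualifies the window.
#'
#' @param residues A single amino-acid sequence.
#' @param strand_len Strand length in residues (>= 2, default 6).
#' @param mode `"unilateral"` (one all-Q face suffices, the default) or
#'   `"bilateral"` (the whole window must be glutamine).
#' @return A tibble with columns `start` and `end` (1-based, inclusive); empty
#'   when no window qualifies or `strand_len` exceeds the sequence length.
#' @examples
#' find_strand_windows("QSQSQS") # one window 1..6
#' @export
find_strand_windows <- function(residues, strand_len = 6,
                                mode = c("unilateral", "bilateral")) {
  residues <- validate_qseq(residues)
  mode <- match.arg(mode)
  stopifnot(length(residues) == 1)
  if (strand_len < 2) abort("`strand_len` must be >= 2.")
  ch <- seq_chars(residues)
  L <- length(ch)
  if (strand_len > L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  is_q <- ch == "Q"
  starts <- seq_len(L - strand_len + 1L)
  ok <- vapply(starts, function(i) {
    win <- i:(i + strand_len - 1L)
    if (mode == "bilateral") {
      return(all(is_q[win]))
    }
    a <- win[seq.int(1L, strand_len, by = 2L)]
    b <- win[seq.int(2L, strand_len, by = 2L)]
    all(is_q[a]) || all(is_q[b])
  }, logical(1))
  tibble(start = starts[ok], end = starts[ok] + as.integer(strand_len) - 1L)
}

#' Thread an intramolecular multi-strand zipper through a sequence
#'
#' Searches for `n_strands` ordered, disjoint strand windows (see
#' [find_strand_windows()]) whose connecting loops are at least `min_loop`
#' residues, or `min_loop_gly` residues when the loop is entirely glycine.
#' The search is greedy-leftmost with backtracking and memoisation; any valid
#' placement proves feasibility (existence, not optimality). With the
#' defaults, pure polyQ first threads at 36 residues (4 x 6 strand residues +
#' 3 x 4 loop residues), while a 33-residue design with correctly placed
#' all-glycine loops also threads.
#'
#' @param residues A single amino-acid sequence.
#' @param n_strands Number of strands required (>= 2, default 4).
#' @param strand_len Strand window length (default 6).
#' @param min_loop Minimum generic loop length (default 4).
#' @param min_loop_gly Minimum loop length when the loop is all glycine
#'   (default 3).
#' @return An object of class `"zipper_threading"`: a list with `feasible`,
#'   `windows` (tibble of chosen `start`/`end`), `loop_lengths`, and the
#'   search parameters. Infeasible is a valid result, not an error.
#' @inheritParams find_strand_windows
#' @examples
#' thread_intramolecular(strrep("Q", 36))$feasible # TRUE
#' thread_intramolecular(strrep("Q", 35))$feasible # FALSE
#' @export
thread_intramolecular <- function(residues, n_strands = 4, strand_len = 6,
                                  min_loop = 4, min_loop_gly = 3,
                                  mode = c("unilateral", "bilateral")) {
  residues <- validate_qseq(residues)
  mode <- match.arg(mode)
  stopifnot(length(residues) == 1)
  if (n_strands < 2) abort("`n_strands` must be >= 2.")
  windows <- find_strand_windows(residues, strand_len, mode)
  ch <- seq_chars(residues)

  gap_ok <- function(prev_end, s) {
    gap <- s - prev_end - 1L
    if (gap >= min_loop) return(TRUE)
    if (gap < min_loop_gly || gap < 1L) return(FALSE)
    all(ch[(prev_end + 1L):(s - 1L)] == "G")
  }

  memo <- new.env(parent = emptyenv())
  # Returns the leftmost feasible placement of k strands after prev_end,
  # as a list of c(start, end), or NULL.
  place <- function(prev_end, k) {
    if (k == 0L) return(list())
    key <- paste(prev_end, k)
    if (!is.null(memo[[key]])) {
      return(if (identical(memo[[key]], "fail")) NULL else memo[[key]])
    }
    cand <- which(windows$start > prev_end)
    for (j in cand) {
      s <- windows$start[j]
      if (prev_end > 0L && !gap_ok(prev_end, s)) next
      rest <- place(windows$end[j], k - 1L)
      if (!is.null(rest)) {
        res <- c(list(c(s, windows$end[j])), rest)
        memo[[key]] <- res
        return(res)
      }
    }
    memo[[key]] <- "fail"
    NULL
  }

  sol <- place(0L, as.integer(n_strands))
  if (is.null(sol)) {
    out <- list(
      feasible = FALSE,
      windows = tibble(start = integer(0), end = integer(0)),
      loop_lengths = integer(0)
    )
  } else {
    starts <- vapply(sol, `[`, integer(1), 1L)
    ends <- vapply(sol, `[`, integer(1), 2L)
    out <- list(
      feasible = TRUE,
      windows = tibble(start = starts, end = ends),
      loop_lengths = as.integer(starts[-1] - ends[-length(ends)] - 1L)
    )
  }
  out$params <- list(
    n_strands = n_strands, strand_len = strand_len,
    min_loop = min_loop, min_loop_gly = min_loop_gly, mode = mode
  )
  structure(out, class = "zipper_threading")
}

#' @export
print.zipper_threading <- function(x, ...) {
  cat(sprintf(
    "<zipper_threading> feasible: %s (%d strands of %d, loops >= %d / %d if all-Gly)\n",
    x$feasible, x$params$n_strands, x$params$strand_len,
    x$params$min_loop, x$params$min_loop_gly
  ))
  if (x$feasible) {
    cat("windows:", paste(sprintf("[%d,%d]", x$windows$start, x$windows$end),
      collapse = " "
    ), "\n")
    cat("loops:  ", paste(x$loop_lengths, collapse = " "), "\n")
  }
  invisible(x)
}

# Dominant residue interrupting the best unilateral track; used only to flag
# borderline calls (4 unilaterally contiguous Qs with a permissive serine).
dominant_interrupter <- function(s) {
  ch <- seq_chars(s)
  non_q <- ch[ch != "Q"]
  if (length(non_q) == 0) {
    return(NA_character_)
  }
  names(sort(table(non_q), decreasing = TRUE))[1]
}

#' Classify zipper competence of sequences
#'
#' Combines contiguity and intramolecular threading into the binary grammar
#' call. A sequence is de novo competent when an intramolecular nucleus can
#' be threaded ([thread_intramolecular()]) *and* the resulting zipper can
#' propagate, via either of two routes:
#'
#' * unilateral route: single-face strand windows thread, and the sequence
#'   carries at least `min_unilateral` unilaterally contiguous glutamines
#'   (the long growth track of an axially propagating single zipper);
#' * bilateral route: fully glutamine strand windows thread, and the
#'   sequence carries at least `min_bilateral` bilaterally contiguous
#'   glutamines. Short-strand zippers propagate laterally, engaging the
#'   contralateral face of each strand, so here a strand must be glutamine
#'   on both faces — which is why removing a single carbon (one Q to N) from
#'   a zero-slack minimal nucleus design abolishes competence.
#'
#' Architecture is `QB` (bilateral contiguity, lamellar growth possible) when
#' `max_bilateral >= min_bilateral`, else `QU` when `max_unilateral >=
#' min_unilateral`, else `NONE`. Template competence (the permissive,
#' conformationally templated route available in cells carrying a
#' pre-existing Q/N-rich amyloid) is a stated heuristic: de novo competence or
#' a Q+N composition fraction of at least `qn_threshold`.
#'
#' @param residues Character vector of sequences.
#' @param name Optional names.
#' @param min_unilateral,min_bilateral Propagation thresholds (defaults 5 and
#'   6).
#' @param qn_threshold Q+N composition fraction for the template-competence
#'   heuristic (default 0.5).
#' @inheritParams thread_intramolecular
#' @return A tibble with one row per sequence: contiguity metrics,
#'   `threadable`, `de_novo_competent`, `template_competent`, `architecture`
#'   (`"QB"`, `"QU"` or `"NONE"`), `qn_fraction`, and a `note` column flagging
#'   borderline calls (for example four unilaterally contiguous glutamines
#'   interrupted by permissive serines, reported via [disruption_rank()]).
#' @examples
#' classify_zipper(make_repeat(5, "N", 60))$de_novo_competent # TRUE
#' classify_zipper(make_repeat(4, "N", 60))$de_novo_competent # FALSE
#' @export
classify_zipper <- function(residues, name = NULL,
                            min_unilateral = 5, min_bilateral = 6,
                            qn_threshold = 0.5,
                            n_strands = 4, strand_len = 6,
                            min_loop = 4, min_loop_gly = 3) {
  residues <- validate_qseq(residues)
  ct <- contiguity(residues, name)
  threadable <- purrr::map_lgl(
    residues,
    ~ thread_intramolecular(.x, n_strands, strand_len, min_loop, min_loop_gly)$feasible
  )
  threadable_bilateral <- purrr::map_lgl(
    residues,
    ~ thread_intramolecular(.x, n_strands, strand_len, min_loop, min_loop_gly,
      mode = "bilateral"
    )$feasible
  )
  qn_fraction <- purrr::map_dbl(residues, function(s) {
    ch <- seq_chars(s)
    mean(ch %in% c("Q", "N"))
  })
  de_novo <- (threadable & ct$max_unilateral >= min_unilateral) |
    (threadable_bilateral & ct$max_bilateral >= min_bilateral)
  architecture <- dplyr::case_when(
    ct$max_bilateral >= min_bilateral ~ "QB",
    ct$max_unilateral >= min_unilateral ~ "QU",
    TRUE ~ "NONE"
  )
  note <- purrr::map2_chr(residues, ct$max_unilateral, function(s, uni) {
    if (uni != min_unilateral - 1) {
      return(NA_character_)
    }
    d <- dominant_interrupter(s)
    if (is.na(d)) {
      return(NA_character_)
    }
    rk <- disruption_rank(d)
    if (rk$known && rk$rank <= 1) {
      sprintf(
        "borderline: %d unilaterally contiguous Qs with permissive interrupter (%s)",
        uni, d
      )
    } else {
      NA_character_
    }
  })
  ct |>
    mutate(
      sequence = residues,
      threadable = threadable,
      qn_fraction = qn_fraction,
      de_novo_competent = de_novo,
      template_competent = de_novo | qn_fraction >= qn_threshold,
      architecture = architecture,
      note = note
    ) |>
    select(
      "name", "sequence", "length", "max_unilateral", "max_bilateral",
      "threadable", "de_novo_competent", "template_competent",
      "architecture", "qn_fraction", "note", "runs"
    )
}

#' Batch grammar scan with TSV-ready output
#'
#' Runs [classify_zipper()] over a FASTA file or a tibble of sequences and
#' returns (optionally writes) the flat per-sequence report.
#'
#' @param x Either a path to a FASTA file or a data frame with columns `name`
#'   and `residues`.
#' @param out Optional path; when given the report is written as
#'   tab-separated values.
#' @param ... Passed to [classify_zipper()].
#' @return A tibble: one row per sequence with name, length, contiguity
#'   metrics, threading feasibility, competence calls and architecture.
#' @export
scan_sequences <- function(x, out = NULL, ...) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- read_fasta(x)
  }
  if (!is.data.frame(x) || !all(c("name", "residues") %in% names(x))) {
    abort("`x` must be a FASTA path or a data frame with `name` and `residues`.")
  }
  report <- classify_zipper(x$residues, name = x$name, ...) |>
    select(-"runs", -"sequence")
  if (!is.null(out)) {
    readr::write_tsv(report, out)
  }
  report
}
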