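#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Validate and normalise a character vector of amino-acid sequences.
# Uppercases, then rejects empty strings and non-canonical residue codes.
validate_qseq <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty character vector.", arg))
  }
  x <- unname(toupper(x))
  if (any(!nzchar(x))) {
    abort(sprintf("`%s` contains an empty sequence.", arg))
  }
  letters_used <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  bad <- setdiff(letters_used, AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains non-canonical residue code(s): %s",
      arg, paste(bad, collapse = ", ")
    ))
  }
  x
}

#' Build a periodic glutamine-interruption repeat sequence
#'
#' Constructs sequences of the form `Q^q X^n_x` repeated and truncated to
#' `total_len` residues: tracts of `q` glutamines, each followed by `n_x`
#' copies of the interrupting residue `x`. These are the standard sequence
#' permutations used to probe the glutamine steric-zipper grammar: `q = 4`
#' with `x = "N"` gives the 60-residue `(QQQQN)` repeat, `q = 0` a
#' homopolymer of `x`, and `x = "Q"` plain polyQ. Setting `base` to a residue
#' other than `"Q"` swaps the roles, e.g. `base = "N"`, `x = "Q"` builds the
#' asparagine-predominant `N^q Q` repeats.
#'
#' @param q Number of `base` residues per repeat unit (>= 0).
#' @param x Single interrupting residue code.
#' @param total_len Total sequence length (>= 1).
#' @param n_x Number of interrupting residues per repeat unit (>= 1); `n_x =
#'   2` gives the double-insertion variants.
#' @param base Residue filling the tract (default `"Q"`).
#' @return A single character string of length `total_len`.
#' @examples
#' make_repeat(4, "N", 60) # (QQQQN) x 12
#' make_repeat(1, "N", 4)  # "QNQN"
#' @export
make_repeat <- function(q, x, total_len, n_x = 1, base = "Q") {
  stopifnot(length(q) == 1, length(total_len) == 1, length(n_x) == 1)
  if (q < 0) abort("`q` must be >= 0.")
  if (total_len < 1) abort("`total_len` must be >= 1.")
  if (n_x < 1) abort("`n_x` must be >= 1.")
  x <- validate_qseq(x, "x")
  base <- validate_qseq(base, "base")
  if (nchar(x) != 1 || nchar(base) != 1) {
    abort("`x` and `base` must be single residue codes.")
  }
  unit <- paste0(strrep(base, q), strrep(x, n_x))
  if (q == 0 && n_x == 0) abort("empty repeat unit")
  n_units <- ceiling(total_len / nchar(unit))
  substr(strrep(unit, n_units), 1, total_len)
}

#' Design the minimal intramolecular zipper nucleus sequence
#'
#' Returns the shortest sequence that satisfies the grammar for an
#' intramolecular four-stranded glutamine zipper: `n_strands` tracts of
#' `strand_q` glutamines joined by copies of `loop` (all-glycine loops may be
#' as short as three residues). With the defaults this is a 33-residue
#' sequence of four Q6 tracts linked by three GGG loops.
#'
#' @param n_strands Number of zipper strands (>= 2).
#' @param strand_q Glutamines per strand (>= 1).
#' @param loop Loop sequence inserted between strands (may be `""`).
#' @return A single character string.
#' @examples
#' nchar(design_minimal_nucleus()) # 33
#' @export
design_minimal_nucleus <- function(n_strands = 4, strand_q = 6, loop = "GGG") {
  if (n_strands < 2) abort("`n_strands` must be >= 2.")
  if (strand_q < 1) abort("`strand_q` must be >= 1.")
  if (nzchar(loop)) loop <- validate_qseq(loop, "loop")
  strand <- strrep("Q", strand_q)
  paste0(strrep(paste0(strand, loop), n_strands - 1), strand)
}

#' Ordinal disruptiveness of zipper-interrupting residues
#'
#' Ranks how strongly a residue placed at the outward-facing positions of a
#' glutamine tract disrupts amyloid nucleation, on the empirical ordering
#' serine < alanine < histidine < glycine = asparagine. The rank is for
#' reporting only; the binary competence call in [classify_zipper()] treats
#' every non-Q residue as zipper-incompatible.
#'
#' @param x Character vector of single residue codes.
#' @return A tibble with columns `residue`, `rank` (1 = most permissive) and
#'   `known` (`FALSE` for residues outside the characterised set, which get a
#'   mid-scale placeholder rank).
#' @examples
#' disruption_rank(c("S", "A", "H", "G", "N"))
#' @export
disruption_rank <- function(x) {
  x <- validate_qseq(x, "x")
  if (any(nchar(x) != 1)) abort("`x` must contain single residue codes.")
  ranks <- c(S = 1, A = 2, H = 3, G = 4, N = 4)
  known <- x %in% names(ranks)
  tibble(
    residue = x,
    rank = ifelse(known, unname(ranks[x]), 2.5),
    known = known
  )
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning a tibble
#' ready for [scan_sequences()].
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `name` and `residues`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() requires the Biostrings package.")
  }
  set <- Biostrings::readAAStringSet(path)
  tibble(
    name = names(set),
    residues = validate_qseq(as.character(set), "sequence")
  )
}
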