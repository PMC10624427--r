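# Independent oracles and shared fixtures for the test suite.

# Brute-force contiguity: start a chain at every Q and extend with step 2
# (unilateral) or step 1 (bilateral); report the longest chains. Deliberately
# naive and independent of the rle-based implementation.
oracle_contiguity <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  longest <- function(step) {
    best <- 0L
    for (i in seq_len(L)) {
      if (ch[i] != "Q") next
      k <- 0L
      j <- i
      while (j <= L && ch[j] == "Q") {
        k <- k + 1L
        j <- j + step
      }
      best <- max(best, k)
    }
    best
  }
  c(uni = longest(2L), bi = longest(1L))
}

# Every {Q,N} sequence of length 1..max_len.
all_qn_sequences <- function(max_len) {
  unlist(lapply(seq_len(max_len), function(L) {
    grid <- expand.grid(rep(list(c("Q", "N")), L), stringsAsFactors = FALSE)
    do.call(paste0, grid)
  }))
}

random_seq <- function(len, alphabet = c("Q", "N", "S", "G", "A", "H")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

gated_sample <- function(p) {
  generate_sample(p) |>
    apply_gates() |>
    derive_amfret()
}

gated_control <- function(p) {
  generate_negative_control(p) |>
    apply_gates() |>
    derive_amfret()
}

# A shared default-condition control and profile, built once per test run.
shared <- new.env()
default_profile <- function() {
  if (is.null(shared$profile)) {
    ctl <- gated_control(nucleation_params(n_cells = 30000, seed = 424242))
    shared$control <- ctl
    shared$profile <- build_gate_profile(ctl)
  }
  shared$profile
}
default_control <- function() {
  default_profile()
  shared$control
}
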