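# Event-table I/O: CSV and a minimal FCS 3.0 (list mode, 32-bit float).

#' Default instrument-to-canonical channel map
#'
#' Maps the cytometer channel labels to the canonical column names used
#' throughout the package (`fs_a`, `fs_h`, `fs_w`, `ssc`, `donor`, `fret`,
#' `acceptor`, `autofluor`).
#'
#' @return A named character vector (instrument name -> canonical name).
#' @export
default_channel_map <- function() {
  c(
    "FS00.A" = "fs_a", "FS00.H" = "fs_h", "FS00.W" = "fs_w",
    "SS02.A" = "ssc", "FL03.A" = "donor", "FRET" = "fret",
    "ACCEPTOR" = "acceptor", "FL17.A" = "autofluor"
  )
}

apply_channel_map <- function(df, channel_map) {
  hit <- names(channel_map) %in% names(df)
  for (from in names(channel_map)[hit]) {
    names(df)[names(df) == from] <- channel_map[[from]]
  }
  df
}

#' Read a cytometry event table (CSV or FCS 3.0/3.1)
#'
#' Format is chosen by file extension. Channel names are mapped to the
#' canonical column names via `channel_map`; the standard raw channels must
#' be present after mapping.
#'
#' @param path File path (`.csv` or `.fcs`).
#' @param channel_map Named character vector, instrument -> canonical names.
#' @return An event tibble.
#' @export
read_events <- function(path, channel_map = default_channel_map()) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    fcs = read_fcs(path),
    abort(sprintf("unsupported event-table format: .%s", ext))
  )
  df <- apply_channel_map(as_tibble(df), channel_map)
  check_channels(df, required_channels)
  df
}

#' Write a cytometry event table (CSV or FCS 3.0)
#'
#' CSV keeps all columns at full precision; FCS stores the numeric channels
#' as 32-bit floats in list mode with canonical channel names.
#'
#' @param events Event tibble.
#' @param path Output path (`.csv` or `.fcs`).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(events, path),
    fcs = write_fcs(events, path),
    abort(sprintf("unsupported event-table format: .%s", ext))
  )
  invisible(path)
}

# --- minimal FCS 3.0 ------------------------------------------------------

write_fcs <- function(events, path) {
  num <- events[vapply(events, is.numeric, logical(1))]
  if (ncol(num) == 0) abort("no numeric channels to write.")
  n_par <- ncol(num)
  n_tot <- nrow(num)
  mat <- t(as.matrix(num))

  delim <- "/"
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
    "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kv[sprintf("$P%dN", i)] <- names(num)[i]
    kv[sprintf("$P%dB", i)] <- "32"
    kv[sprintf("$P%dE", i)] <- "0,0"
    kv[sprintf("$P%dR", i)] <- format(ceiling(max(1, max(mat[i, ], na.rm = TRUE))),
      scientific = FALSE
    )
  }
  text_of <- function(bd, ed) {
    paste0(
      delim,
      paste0(names(kv), delim, sub("%BD%", bd, sub("%ED%", ed, unname(kv))),
        delim,
        collapse = ""
      )
    )
  }
  # Fixed-width offsets so the text length is stable across substitution.
  probe <- text_of(sprintf("%012d", 0), sprintf("%012d", 0))
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(probe) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  txt <- text_of(sprintf("%012d", data_start), sprintf("%012d", data_end))
  stopifnot(nchar(txt) == nchar(probe))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf(
    "FCS3.0    %8d%8d%8d%8d%8d%8d",
    text_start, text_end, data_start, data_end, 0L, 0L
  )
  writeChar(hdr, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.numeric(mat), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  hdr <- rawToChar(raw[1:58])
  if (!startsWith(hdr, "FCS3")) abort("not an FCS 3.x file.", class = "qzipper_bad_fcs")
  off <- suppressWarnings(as.integer(substring(
    hdr, seq(11, 51, by = 8), seq(18, 58, by = 8)
  )))
  if (any(is.na(off[1:4]))) abort("malformed FCS header.", class = "qzipper_bad_fcs")
  txt <- rawToChar(raw[(off[1] + 1):(off[2] + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kv <- stats::setNames(vals, toupper(keys))

  if (!identical(kv[["$DATATYPE"]], "F")) {
    abort("only $DATATYPE F (float) FCS files are supported.",
      class = "qzipper_bad_fcs"
    )
  }
  n_par <- as.integer(kv[["$PAR"]])
  n_tot <- as.integer(kv[["$TOT"]])
  data_start <- as.integer(kv[["$BEGINDATA"]])
  if (is.na(data_start) || data_start == 0) data_start <- off[3]
  endian <- if (identical(kv[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  vals <- readBin(raw[(data_start + 1):length(raw)], "numeric",
    n = n_par * n_tot, size = 4, endian = endian
  )
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  cn <- vapply(seq_len(n_par), function(i) {
    nm <- kv[[sprintf("$P%dN", i)]]
    if (is.null(nm) || is.na(nm)) sprintf("P%d", i) else nm
  }, character(1))
  colnames(mat) <- cn
  as_tibble(mat)
}
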