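# Sequential gating of cytometry event tables.
#
# Three gates applied in order on logicle-transformed channels:
#   1. cells:      FS00.A vs SS02.A, rectangle
#   2. singlets:   FS00.H vs FS00.W, rectangle
#   3. expressing: FL03.A (donor) vs FL17.A (autofluorescence), polygon
# Gate coordinates are expressed in transformed (decade) units. Membership is
# inclusive of gate boundaries.

#' Default sequential gate set
#'
#' The three-stage gate used by the DAmFRET pipeline, with the standard
#' coordinates in logicle decade units: a cells rectangle (FS00.A vs SS02.A)
#' of \[2.7, 4.8\] x \[2.7, 4.7\], a singlets rectangle (FS00.H vs FS00.W) of
#' \[4.45, 4.58\] x \[2.5, 4.4\], and an expressing-cells polygon (donor vs
#' autofluorescence) with vertices (1, 0.1), (1.8, 2), (5, 2), (5, 0.1).
#'
#' @param cells_rect,singlets_rect Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param expressing_polygon Two-column matrix or data frame of polygon
#'   vertices (ordered, simple).
#' @return An object of class `"gate_set"`.
#' @export
gate_set <- function(cells_rect = c(2.7, 4.8, 2.7, 4.7),
                     singlets_rect = c(4.45, 4.58, 2.5, 4.4),
                     expressing_polygon = cbind(
                       x = c(1, 1.8, 5, 5),
                       y = c(0.1, 2, 2, 0.1)
                     )) {
  stopifnot(length(cells_rect) == 4, length(singlets_rect) == 4)
  if (cells_rect[1] >= cells_rect[2] || cells_rect[3] >= cells_rect[4] ||
    singlets_rect[1] >= singlets_rect[2] || singlets_rect[3] >= singlets_rect[4]) {
    abort("gate rectangles must be non-degenerate (min < max).")
  }
  poly <- as.matrix(as.data.frame(expressing_polygon))
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    abort("`expressing_polygon` needs >= 3 two-dimensional vertices.")
  }
  structure(
    list(
      cells_rect = cells_rect,
      singlets_rect = singlets_rect,
      expressing_polygon = poly
    ),
    class = "gate_set"
  )
}

in_rect <- function(x, y, rect) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-edge check so that points lying
#' exactly on a polygon edge or vertex count as inside.
#'
#' @param x,y Point coordinates.
#' @param poly Two-column matrix of vertices.
#' @return Logical vector.
#' @keywords internal
#' @export
point_in_polygon <- function(x, y, poly) {
  nv <- nrow(poly)
  px <- poly[, 1]
  py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- px[i]; yi <- py[i]
    xj <- px[j]; yj <- py[j]
    # on-segment: collinear and within bounding box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_seg <- abs(cross) <= 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

required_channels <- c(
  "fs_a", "fs_h", "fs_w", "ssc", "donor", "fret", "acceptor", "autofluor"
)

check_channels <- function(events, needed) {
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(
      sprintf("missing channel(s): %s", paste(missing, collapse = ", ")),
      class = "qzipper_missing_channel"
    )
  }
  invisible(events)
}

#' Apply the sequential DAmFRET gates
#'
#' Logicle-transforms the scatter, donor and autofluorescence channels and
#' applies the cells, singlets and expressing gates in sequence. FRET and
#' acceptor intensities are left untransformed (AmFRET is computed on raw
#' values downstream).
#'
#' @param events Event tibble with channels `fs_a`, `fs_h`, `fs_w`, `ssc`,
#'   `donor`, `fret`, `acceptor`, `autofluor`.
#' @param gates A [gate_set()].
#' @param transform A [logicle_params()] used for all transformed channels.
#' @return The surviving events, with the per-stage counts attached as the
#'   `"stage_counts"` attribute (named integer vector: input, cells,
#'   singlets, expressing).
#' @examples
#' ev <- generate_sample(nucleation_params(n_cells = 500, seed = 1))
#' nrow(apply_gates(ev)) / nrow(ev) # close to 1 by construction
#' @export
apply_gates <- function(events, gates = gate_set(), transform = logicle_params()) {
  check_channels(events, c("fs_a", "fs_h", "fs_w", "ssc", "donor", "autofluor"))
  events <- as_tibble(events)
  n0 <- nrow(events)
  if (n0 == 0) {
    out <- events
    attr(out, "stage_counts") <- c(input = 0L, cells = 0L, singlets = 0L, expressing = 0L)
    return(out)
  }
  tr <- function(v) logicle(v, transform)
  keep1 <- in_rect(tr(events$fs_a), tr(events$ssc), gates$cells_rect)
  e1 <- events[keep1, , drop = FALSE]
  keep2 <- in_rect(tr(e1$fs_h), tr(e1$fs_w), gates$singlets_rect)
  e2 <- e1[keep2, , drop = FALSE]
  keep3 <- point_in_polygon(
    tr(e2$donor), tr(e2$autofluor), gates$expressing_polygon
  )
  e3 <- e2[keep3, , drop = FALSE]
  attr(e3, "stage_counts") <- c(
    input = n0, cells = nrow(e1), singlets = nrow(e2), expressing = nrow(e3)
  )
  e3
}

#' Derive AmFRET and concentration columns
#'
#' AmFRET is the sensitised FRET intensity divided by the directly excited
#' acceptor intensity (FRET per molecule); the per-cell concentration proxy is
#' acceptor divided by side scatter (a cell-volume proxy), in arbitrary
#' units. Events with non-positive acceptor or side scatter cannot be
#' ratioed; they are dropped and counted in the `"excluded"` attribute.
#'
#' @param events Gated event tibble with `fret`, `acceptor` and `ssc`.
#' @return `events` with `amfret` and `concentration` columns; the number of
#'   excluded events is attached as attribute `"excluded"`.
#' @export
derive_amfret <- function(events) {
  check_channels(events, c("fret", "acceptor", "ssc"))
  events <- as_tibble(events)
  bad <- !(events$acceptor > 0 & events$ssc > 0)
  bad[is.na(bad)] <- TRUE
  out <- events[!bad, , drop = FALSE] |>
    mutate(
      amfret = .data$fret / .data$acceptor,
      concentration = .data$acceptor / .data$ssc
    )
  attr(out, "excluded") <- sum(bad)
  attr(out, "stage_counts") <- attr(events, "stage_counts")
  out
}
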