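# SDD-AGE densitometry: background subtraction, lane line profiles,
# integral normalization and lane-comparison summaries.

# Ball structuring-element offsets and heights for grayscale morphology:
# h(dx, dy) = sqrt(r^2 - dx^2 - dy^2) - r (<= 0, 0 at the centre).
ball_kernel <- function(radius) {
  r <- ceiling(radius)
  dx <- rep(-r:r, times = 2 * r + 1)
  dy <- rep(-r:r, each = 2 * r + 1)
  keep <- dx^2 + dy^2 <= radius^2
  list(
    dx = dx[keep], dy = dy[keep],
    h = sqrt(radius^2 - dx[keep]^2 - dy[keep]^2) - radius
  )
}

# Grayscale erosion/dilation with the ball kernel, replicate-padded.
morph_ball <- function(image, kern, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  ri <- seq_len(nr)
  ci <- seq_len(nc)
  for (k in seq_along(kern$dx)) {
    sr <- pmin(pmax(ri + kern$dx[k], 1L), nr)
    sc <- pmin(pmax(ci + kern$dy[k], 1L), nc)
    shifted <- image[sr, sc, drop = FALSE]
    if (op == "erode") {
      out <- pmin(out, shifted - kern$h[k])
    } else {
      out <- pmax(out, shifted + kern$h[k])
    }
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped structuring element of the given radius (the classic
#' rolling-ball algorithm) and subtracts it. Features narrower than the ball
#' survive; smooth background slopes are removed. Output is clamped at zero.
#'
#' @param image Numeric matrix (gel image; rows = migration axis).
#' @param radius Ball radius in pixels (default 200). Must be smaller than
#'   both image dimensions. Runtime grows with `radius^2`.
#' @return Background-subtracted matrix, same dimensions, all values >= 0.
#' @examples
#' img <- matrix(5, 40, 30)
#' range(rolling_ball_subtract(img, radius = 8)) # all zero
#' @export
rolling_ball_subtract <- function(image, radius = 200) {
  if (radius < 1) abort("`radius` must be >= 1.")
  if (radius >= min(dim(image))) {
    abort("`radius` must be smaller than both image dimensions.")
  }
  kern <- ball_kernel(radius)
  background <- morph_ball(morph_ball(image, kern, "erode"), kern, "dilate")
  pmax(image - background, 0)
}

#' Lane line profile
#'
#' Mean intensity per migration row over a lane swath of the given width
#' centred on `lane_center_x` (columns `lane_center_x - floor(w/2) ...
#' + ceiling(w/2) - 1`; `width = 1` extracts a single column).
#'
#' @param image Numeric matrix, rows along the migration axis.
#' @param lane_center_x Lane centre column (1-based).
#' @param width Swath width in pixels (default 10).
#' @return A `lane_profile` tibble with columns `position` (row index) and
#'   `intensity`, and attribute `normalized = FALSE`.
#' @export
line_profile <- function(image, lane_center_x, width = 10) {
  lo <- lane_center_x - floor(width / 2)
  hi <- lo + width - 1
  if (lo < 1 || hi > ncol(image)) {
    abort("lane swath falls outside the image.", class = "qzipper_bad_lane")
  }
  out <- tibble(
    position = seq_len(nrow(image)),
    intensity = rowMeans(image[, lo:hi, drop = FALSE])
  )
  attr(out, "normalized") <- FALSE
  class(out) <- c("lane_profile", class(out))
  out
}

profile_integral <- function(p) {
  # trapezoidal rule over (position, intensity)
  x <- p$position
  y <- p$intensity
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Normalize a lane profile to unit integral
#'
#' Divides intensities by the trapezoidal integral under the profile, so
#' lanes of different total load are directly comparable. Idempotent.
#'
#' @param p A [line_profile()] tibble (columns `position`, `intensity`).
#' @return The profile with integral 1 and attribute `normalized = TRUE`.
#' @export
normalize_profile <- function(p) {
  total <- profile_integral(p)
  if (!is.finite(total) || total <= 0) {
    abort("profile integral must be > 0.", class = "qzipper_degenerate_profile")
  }
  p$intensity <- p$intensity / total
  attr(p, "normalized") <- TRUE
  if (!inherits(p, "lane_profile")) class(p) <- c("lane_profile", class(p))
  p
}

#' Distributional summary of a lane profile
#'
#' Treats the normalized profile as a density over migration position and
#' reports the weighted median and interquartile positions — compact
#' summaries for comparing amyloid size distributions between lanes.
#' Invariant to overall intensity scaling and to constant position offsets
#' (up to the offset itself).
#'
#' @param p A lane profile (normalized or not; normalization is applied).
#' @return A one-row tibble: `median_position`, `q25`, `q75`, `iqr`.
#' @export
profile_summary <- function(p) {
  p <- normalize_profile(p)
  x <- p$position
  y <- p$intensity
  # cumulative trapezoid integral
  cum <- c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  cum <- cum / cum[length(cum)]
  qpos <- function(q) stats::approx(cum, x, xout = q, ties = "ordered")$y
  tibble(
    median_position = qpos(0.5),
    q25 = qpos(0.25),
    q75 = qpos(0.75),
    iqr = qpos(0.75) - qpos(0.25)
  )
}

#' Synthetic gel-lane fixture
#'
#' Gaussian bands on an optional sloped background, for exercising the
#' densitometry chain with known truth.
#'
#' @param nrow_,ncol_ Image dimensions.
#' @param bands Data frame with `row` (band centre), `width` (SD in rows),
#'   `amplitude`, and `lane_center` column positions.
#' @param lane_width Width of each band across columns (default 12).
#' @param background_slope Per-row additive background slope (default 0).
#' @param background_offset Constant background (default 0).
#' @return Numeric matrix.
#' @export
synth_gel_image <- function(nrow_ = 200, ncol_ = 60, bands,
                            lane_width = 12, background_slope = 0,
                            background_offset = 0) {
  img <- matrix(background_offset + background_slope * seq_len(nrow_),
    nrow_, ncol_,
    byrow = FALSE
  )
  rows <- seq_len(nrow_)
  for (i in seq_len(nrow(bands))) {
    prof <- bands$amplitude[i] * exp(-(rows - bands$row[i])^2 / (2 * bands$width[i]^2))
    c0 <- max(1, bands$lane_center[i] - lane_width %/% 2)
    c1 <- min(ncol_, c0 + lane_width - 1)
    img[, c0:c1] <- img[, c0:c1] + prof
  }
  img
}
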