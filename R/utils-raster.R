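#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dnorm median sd quantile fft rnorm runif rpois setNames
NULL

# Raster convention used throughout: numeric matrix, row = depth (axial,
# increasing away from the transducer), col = lateral. attr "spacing_mm"
# holds the pixel pitch. Physical coordinates are (x = lateral mm,
# y = axial/depth mm), both measured from the top-left pixel *centre*
# at (0, 0): x = (col - 1) * spacing, y = (row - 1) * spacing.

mm_to_px <- function(mm, spacing) mm / spacing + 1
px_to_mm <- function(px, spacing) (px - 1) * spacing

#' Separable Gaussian blur with an explicit discrete kernel
#'
#' Convolves a matrix with a normalized, truncated (radius `4*sd`) separable
#' Gaussian. The same discrete kernel is used by [binarize_vessels()] to set
#' the half-peak threshold, so blur and threshold are always consistent.
#'
#' @param x numeric matrix.
#' @param sd kernel standard deviation in pixels; `0` returns `x` unchanged.
#' @return blurred matrix of the same dimensions (zero-padded boundary).
#' @keywords internal
gauss_blur <- function(x, sd) {
  if (sd <= 0) return(x)
  k <- gauss_kernel_1d(sd)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  # pad with zeros, convolve columns then rows via matrix products
  padr <- matrix(0, r, nc)
  xp <- rbind(padr, x, padr)
  xc <- vapply(seq_len(nr), function(i) {
    drop(k %*% xp[i:(i + 2L * r), , drop = FALSE])
  }, numeric(nc))
  xc <- t(xc)  # nr x nc, column-blurred
  padc <- matrix(0, nr, r)
  xp2 <- cbind(padc, xc, padc)
  out <- vapply(seq_len(nc), function(j) {
    drop(xp2[, j:(j + 2L * r), drop = FALSE] %*% k)
  }, numeric(nr))
  dimnames(out) <- NULL
  out
}

gauss_kernel_1d <- function(sd) {
  r <- max(1L, ceiling(4 * sd))
  k <- dnorm(seq(-r, r), sd = sd)
  k / sum(k)
}

#' Peak amplitude of a unit line traversal after Gaussian blur
#'
#' A single-traversal line (value 1 on each visited pixel) convolved with the
#' discrete normalized 2-D Gaussian has, along its interior, amplitude equal to
#' the central weight of the 1-D kernel. This is the "peak value of the
#' two-dimensional Gaussian filter" from which the vessel binarization
#' threshold is derived.
#' @keywords internal
blurred_line_peak <- function(sd) {
  if (sd <= 0) return(1)
  k <- gauss_kernel_1d(sd)
  k[(length(k) + 1L) / 2L]
}

#' Rasterize a segment on a pixel grid (Bresenham-style)
#'
#' Returns the (row, col) pixels traversed by the straight segment joining two
#' sub-pixel endpoints, each pixel listed once. Uses the classic integer
#' Bresenham walk on the rounded endpoints.
#' @keywords internal
bresenham <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  rows <- integer(n); cols <- integer(n)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) { rows <- rows[1:i]; cols <- cols[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 <  dc) { err <- err + dc; r <- r + sr }
  }
  cbind(row = rows, col = cols)
}

# clamp pixel index matrix to raster bounds, dropping out-of-range pixels
clip_pixels <- function(px, nr, nc) {
  keep <- px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc
  px[keep, , drop = FALSE]
}

#' Shift an image by a sub-pixel translation (bilinear)
#'
#' Samples the input at `(row - dy, col - dx)`, i.e. the content moves by
#' `(+dx, +dy)` pixels (dx = columns/lateral, dy = rows/axial). Out-of-field
#' samples are 0.
#' @keywords internal
shift_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) - dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  bilinear_sample(img, rr, cc)
}

bilinear_sample <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get(r0,     c0) +
       (1 - fr) * fc       * get(r0,     c0 + 1) +
       fr       * (1 - fc) * get(r0 + 1, c0) +
       fr       * fc       * get(r0 + 1, c0 + 1)
  matrix(v, nrow(rr), ncol(rr))
}

#' Evaluate a function with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
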