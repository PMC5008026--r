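# Core single-block linear detection: block CT values, directional ratio
# parameters, their maximal magnitude over the direction set, and the
# confidence matrix.

# Unit pixel offset (drow, dcol) of an angle in degrees, on the 8-connected
# grid: components are rounded to {-1, 0, 1}. Angle 0 points to increasing
# columns ("right"), 90 to decreasing rows ("up").
unit_offset <- function(theta) {
  rad <- theta * pi / 180
  c(-round(sin(rad)), round(cos(rad)))
}

# Block-mean image: entry (i, j) is the mean of the N x N block centered
# there; NA where the block does not fit. Accumulates the N^2 shifted copies
# with plain double additions in a fixed order (rows outer, columns inner) so
# that a scalar loop with the same order reproduces it bit-exactly.
block_mean_image <- function(px, N) {
  nb <- N %/% 2
  nr <- nrow(px); nc <- ncol(px)
  ir <- (nb + 1):(nr - nb); ic <- (nb + 1):(nc - nb)
  acc <- matrix(0, length(ir), length(ic))
  for (di in -nb:nb) {
    for (dj in -nb:nb) {
      acc <- acc + px[ir + di, ic + dj]
    }
  }
  out <- matrix(NA_real_, nr, nc)
  out[ir, ic] <- acc / (N * N)
  out
}

#' Block CT value
#'
#' Mean intensity of the `N x N` block centered at a pixel. This is the
#' smoothing primitive of the detector: comparing two flanking block means
#' against a single candidate pixel makes the response robust to noise while
#' staying sensitive to thin dark interfaces.
#'
#' @param image Numeric display matrix.
#' @param center Length-2 integer vector `(row, col)`.
#' @param N Odd block size in pixels.
#' @return The block mean (scalar).
#' @export
block_ct_value <- function(image, center, N = 3) {
  if (N < 1 || N %% 2 == 0) stop("N must be odd and >= 1", call. = FALSE)
  nb <- N %/% 2
  r <- center[1]; c <- center[2]
  if (r - nb < 1 || r + nb > nrow(image) || c - nb < 1 || c + nb > ncol(image))
    stop("block outside image bounds", call. = FALSE)
  s <- 0
  for (di in -nb:nb) {
    for (dj in -nb:nb) {
      s <- s + image[r + di, c + dj]
    }
  }
  s / (N * N)
}

#' Directional ratio parameter at one seed pixel
#'
#' For a seed pixel and direction `theta`, the candidate point `V_c` is the
#' pixel one unit step from the seed along `theta`; `C1` and `C2` are the
#' block CT values centered `floor(w/2)` pixels from the candidate in the
#' directions `theta` and `theta + 180` (or orthogonally, for the
#' `"perpendicular"` variant). The ratio parameter is
#' `(C1 + C2 - 2 V_c) / (2 V_c)`: a scale-free contrast score that is large
#' when the candidate is much darker than its two flanks, i.e. when it lies
#' on a dark boundary interface.
#'
#' Diagonal steps are full-pixel grid steps (no interpolation); distances are
#' Chebyshev pixel counts.
#'
#' @param image Numeric display matrix (strictly positive).
#' @param seed Length-2 integer vector `(row, col)` of the seed pixel.
#' @param theta Direction in degrees.
#' @inheritParams sblda_params
#' @return The signed ratio parameter (scalar).
#' @export
ratio_parameter <- function(image, seed, theta, w = 9, N = 3,
                            orientation = c("along", "perpendicular")) {
  orientation <- match.arg(orientation)
  if (w < 3 || w %% 2 == 0) stop("w must be odd and >= 3", call. = FALSE)
  h <- w %/% 2
  d <- unit_offset(theta)
  o <- if (orientation == "along") d else unit_offset(theta + 90)
  cand <- seed + d
  if (cand[1] < 1 || cand[1] > nrow(image) || cand[2] < 1 || cand[2] > ncol(image))
    stop("candidate point outside image bounds", call. = FALSE)
  vc <- image[cand[1], cand[2]]
  c1 <- block_ct_value(image, cand + h * o, N)
  c2 <- block_ct_value(image, cand - h * o, N)
  (c1 + c2 - 2 * vc) / (2 * vc)
}

#' Maximal directional ratio field
#'
#' Evaluates the ratio parameter at every pixel for every direction of the
#' parameter set and stores the maximum magnitude per pixel. Pixels within
#' `floor(w/2) + floor(N/2) + 1` pixels of the image border (where some block
#' would fall outside the image) form the margin and carry `NA`.
#'
#' The computation is vectorized with shifted-submatrix arithmetic and is
#' bit-exact against a scalar per-pixel/per-direction loop that accumulates
#' block sums in the same (row-outer, column-inner) order.
#'
#' @param image Numeric display matrix, strictly positive.
#' @param params An [sblda_params()] object.
#' @return An object of class `ratio_field`: list with `values` (matrix,
#'   `NA` in the margin) and `margin` (integer border width).
#' @export
max_ratio_field <- function(image, params = sblda_params()) {
  stopifnot(inherits(params, "sblda_params"))
  px <- if (inherits(image, "ct_slice")) image$pixels else image
  if (min(px) <= 0)
    stop("image must be strictly positive (apply windowing first)", call. = FALSE)
  w <- params$w; N <- params$N
  h <- w %/% 2; nb <- N %/% 2
  m <- h + nb + 1L
  nr <- nrow(px); nc <- ncol(px)
  if (nr <= 2 * (w + N) || nc <= 2 * (w + N))
    stop("image too small for detection window: dimensions must exceed 2*(w+N)",
         call. = FALSE)
  C <- block_mean_image(px, N)
  ir <- (m + 1):(nr - m); ic <- (m + 1):(nc - m)
  best <- matrix(0, length(ir), length(ic))
  for (theta in params$directions) {
    d <- unit_offset(theta)
    o <- if (params$orientation == "along") d else unit_offset(theta + 90)
    V <- px[ir + d[1], ic + d[2]]
    C1 <- C[ir + d[1] + h * o[1], ic + d[2] + h * o[2]]
    C2 <- C[ir + d[1] - h * o[1], ic + d[2] - h * o[2]]
    best <- pmax(best, abs((C1 + C2 - 2 * V) / (2 * V)))
  }
  values <- matrix(NA_real_, nr, nc)
  values[ir, ic] <- best
  structure(list(values = values, margin = m), class = "ratio_field")
}

#' @export
print.ratio_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("ratio field: %d x %d, margin %d px, R_m in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$margin, min(v), max(v)))
  invisible(x)
}

#' Confidence matrix
#'
#' Thresholds the maximal ratio field: pixels whose maximal directional ratio
#' magnitude reaches `T` (inclusive) are marked 1 as liver-edge evidence.
#' Margin pixels are 0 (the liver never touches the border of an abdominal
#' CT slice).
#'
#' @param field A `ratio_field` from [max_ratio_field()].
#' @param T Positive threshold.
#' @return Integer 0/1 matrix.
#' @export
confidence_matrix <- function(field, T = 0.85) {
  stopifnot(inherits(field, "ratio_field"))
  if (!is.numeric(T) || T <= 0) stop("T must be > 0", call. = FALSE)
  m <- matrix(0L, nrow(field$values), ncol(field$values))
  m[!is.na(field$values) & field$values >= T] <- 1L
  m
}
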