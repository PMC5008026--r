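#' Intensity windowing of a CT slice
#'
#' Maps Hounsfield units linearly onto the strictly positive display scale
#' `[1, 256]`: HU values inside `[level - width/2, level + width/2]` map
#' linearly, values below clamp to 1 and above to 256. A strictly positive
#' scale guarantees nonzero denominators in the ratio parameter, which
#' divides by pixel intensity.
#'
#' @param slice A [ct_slice()] (or a plain HU matrix).
#' @param width Window width in HU (> 0); default 400.
#' @param level Window level (center) in HU; default 40.
#' @return Numeric matrix on the display scale `[1, 256]`, same shape as the
#'   input.
#' @examples
#' apply_window(matrix(40, 1, 1))  # window center -> 128.5
#' @export
apply_window <- function(slice, width = 400, level = 40) {
  if (!is.numeric(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  px <- if (inherits(slice, "ct_slice")) slice$pixels else slice
  lo <- level - width / 2
  disp <- 1 + (px - lo) / width * 255
  pmin(pmax(disp, 1), 256)
}

#' 2D median filtering with edge replication
#'
#' Replaces every pixel by the median of its `window x window` neighborhood.
#' Borders are handled by edge replication, so the output never leaves the
#' input's value range. Applied to a binary mask this is a majority filter,
#' which is how disconnected boundary fragments are reconnected in
#' postprocessing.
#'
#' @param image Numeric matrix.
#' @param window Odd window size in pixels.
#' @return Filtered matrix of the same shape.
#' @export
median_filter_2d <- function(image, window = 5) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1) return(image)
  h <- window %/% 2
  nr <- nrow(image); nc <- ncol(image)
  pad <- image[pmin(pmax(seq_len(nr + 2 * h) - h, 1), nr),
               pmin(pmax(seq_len(nc + 2 * h) - h, 1), nc)]
  stack <- matrix(0, nr * nc, window * window)
  k <- 1L
  for (dj in 0:(window - 1)) {
    for (di in 0:(window - 1)) {
      stack[, k] <- as.vector(pad[di + seq_len(nr), dj + seq_len(nc)])
      k <- k + 1L
    }
  }
  matrix(matrixStats::rowMedians(stack), nr, nc)
}

#' Histogram-mode seed mask (diagnostic)
#'
#' Diagnostic implementation of histogram-based seeding: pixels within +/- 3
#' display units of the histogram mode are marked. The main pipeline does
#' not use it -- single-block linear detection evaluates every pixel of the
#' input image directly, which is what makes the method insensitive to
#' initialization -- but the mask is useful to visualize why histogram
#' seeding is unreliable on abdominal CT.
#'
#' The mode is computed on integer-rounded display intensities (256 bins).
#' Ties are broken toward the lowest intensity, with a warning.
#'
#' @param image Numeric display matrix.
#' @return Integer 0/1 matrix marking pixels in `[mode - 3, mode + 3]`.
#' @export
histogram_seed_mask <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop("image must be a non-empty matrix", call. = FALSE)
  v <- round(as.vector(image))
  tab <- table(v)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) {
    warning("multimodal histogram; choosing the lowest-intensity mode")
  }
  p <- min(top)
  m <- matrix(0L, nrow(image), ncol(image))
  m[image >= p - 3 & image <= p + 3] <- 1L
  m
}
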