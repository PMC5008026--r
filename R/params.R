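#' Algorithm parameters for single-block linear detection
#'
#' Constructs and validates the full tunable set of the SBLDA liver
#' segmentation pipeline. Defaults are the published operating point of the
#' method: ratio threshold `T = 0.85` with a `w = 9` detection window and
#' `N = 3` block size over the eight 45-degree directions, a 400/40 HU
#' display window, a 5-pixel median denoising window, 2-pixel disk radius for
#' outlier removal, and a 20-pixel disk radius for ring-artifact masking.
#'
#' @param T Ratio-parameter threshold (unitless, > 0). A pixel is marked as
#'   edge evidence when the maximal directional ratio magnitude reaches `T`.
#' @param w Detection window size in pixels (odd, >= 3). The two flanking
#'   blocks are centered `floor(w/2)` pixels from the candidate point.
#' @param N Block size in pixels (odd, >= 1, <= w); block CT values are means
#'   over `N x N` neighborhoods.
#' @param directions Numeric vector of detection angles in degrees.
#' @param window_width Display window width in HU (> 0).
#' @param window_level Display window level (center) in HU.
#' @param median_window Median denoising window in pixels (odd).
#' @param outlier_radius Disk radius (pixels) for morphological outlier
#'   removal; also reused as the erosion radius after inversion.
#' @param ring_radius Disk radius (pixels) of the morphological opening that
#'   builds the ring-artifact body mask.
#' @param gaussian_sigma Gaussian boundary-smoothing sigma in pixels.
#' @param reconnect_window Median reconnection window in pixels (odd).
#' @param orientation `"along"` places the flanking blocks on the detection
#'   axis (the documented reading of the method); `"perpendicular"` places
#'   them orthogonally, as in classic line operators. Exposed for
#'   experimentation; no correctness claim is made for the variant.
#'
#' @return An object of class `sblda_params` (a validated named list).
#' @seealso [load_params()], [segment_liver()]
#' @examples
#' p <- sblda_params()
#' p$T
#' @export
sblda_params <- function(T = 0.85, w = 9, N = 3,
                         directions = seq(0, 315, by = 45),
                         window_width = 400, window_level = 40,
                         median_window = 5, outlier_radius = 2,
                         ring_radius = 20, gaussian_sigma = 2,
                         reconnect_window = 5,
                         orientation = c("along", "perpendicular")) {
  orientation <- match.arg(orientation)
  p <- structure(list(
    T = as.numeric(T), w = as.integer(w), N = as.integer(N),
    directions = as.numeric(directions),
    window_width = as.numeric(window_width),
    window_level = as.numeric(window_level),
    median_window = as.integer(median_window),
    outlier_radius = as.integer(outlier_radius),
    ring_radius = as.integer(ring_radius),
    gaussian_sigma = as.numeric(gaussian_sigma),
    reconnect_window = as.integer(reconnect_window),
    orientation = orientation
  ), class = "sblda_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.finite(p$T) || p$T <= 0) fail("T", "must be > 0")
  if (is.na(p$w) || p$w < 3 || p$w %% 2 == 0) fail("w", "must be odd and >= 3")
  if (is.na(p$N) || p$N < 1 || p$N %% 2 == 0) fail("N", "must be odd and >= 1")
  if (p$N > p$w) fail("N", "must not exceed w")
  if (length(p$directions) < 1 || anyNA(p$directions))
    fail("directions", "must be a non-empty numeric vector of angles")
  if (!is.finite(p$window_width) || p$window_width <= 0)
    fail("window_width", "must be > 0")
  if (!is.finite(p$window_level)) fail("window_level", "must be finite")
  if (is.na(p$median_window) || p$median_window < 1 || p$median_window %% 2 == 0)
    fail("median_window", "must be odd and >= 1")
  if (is.na(p$outlier_radius) || p$outlier_radius < 1)
    fail("outlier_radius", "must be >= 1")
  if (is.na(p$ring_radius) || p$ring_radius < 1)
    fail("ring_radius", "must be >= 1")
  if (!is.finite(p$gaussian_sigma) || p$gaussian_sigma <= 0)
    fail("gaussian_sigma", "must be > 0")
  if (is.na(p$reconnect_window) || p$reconnect_window < 1 ||
      p$reconnect_window %% 2 == 0)
    fail("reconnect_window", "must be odd and >= 1")
  invisible(p)
}

#' Load SBLDA parameters from a configuration file
#'
#' Reads a flat key-value YAML file whose keys mirror the arguments of
#' [sblda_params()]. Keys absent from the file keep their defaults; unknown
#' keys raise an error. An empty file yields the full default set.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `sblda_params` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("T: 0.9", f)
#' load_params(f)$T
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a flat key-value mapping", call. = FALSE)
  known <- names(formals(sblda_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sblda_params, cfg)
}

#' @export
print.sblda_params <- function(x, ...) {
  cat("SBLDA parameters\n")
  cat(sprintf("  T = %g, w = %d, N = %d (%s), directions = %s\n",
              x$T, x$w, x$N, x$orientation,
              paste(x$directions, collapse = "/")))
  cat(sprintf("  display window: %g HU wide at level %g HU\n",
              x$window_width, x$window_level))
  cat(sprintf("  median %d px | outlier disk %d px | ring disk %d px\n",
              x$median_window, x$outlier_radius, x$ring_radius))
  cat(sprintf("  smoothing sigma %g px | reconnect window %d px\n",
              x$gaussian_sigma, x$reconnect_window))
  invisible(x)
}
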