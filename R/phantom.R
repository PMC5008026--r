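# Synthetic abdominal CT phantom generator with exact ground truth.
#
# The phantom emulates the structures the detector targets on an axial
# abdominal slice: an air background, a soft-tissue body disk, a large liver
# ellipse placed against the left body wall, an adjacent organ separated
# from the liver by a weak (less hypodense) interface, thin dark fat-plane
# interfaces around organ boundaries, optional hypo- or hyperdense tumor
# inclusions, an optional bright ring artifact touching the body outline,
# and additive Gaussian HU noise (plus optional salt-and-pepper impulses).

# Run code with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of the synthetic abdominal CT slice. The defaults describe the
#' standard test condition: a 320 x 320 slice, body disk of radius 125 px
#' centered slightly right of the image center (the abdomen bulges right of
#' the liver on an axial slice), a liver ellipse with semi-axes 95 x 75 px
#' resting a few pixels from the left body wall (about 45% of the body cross
#' section), an adjacent organ of semi-axes 50 x 38 px, 3 px fat-plane
#' interfaces around both organs, a 4 px weak-edge corridor where the two
#' organs approach each other, and 10 HU additive Gaussian noise.
#'
#' HU palette: air -1000, soft-tissue background 40, liver 90, neighbor 70,
#' fat interfaces -110, weak-edge corridor -70, ring artifact 300 -- all
#' structure except air and ring inside the 400/40 display window, so
#' windowing does not clip anatomy.
#'
#' @param size Image side in pixels (square slice).
#' @param body_center,body_radius Body disk geometry (pixels, (row, col)).
#' @param liver_center,liver_axes Liver ellipse center and semi-axes
#'   (row, col), pixels.
#' @param liver_hu,background_hu,neighbor_hu Tissue intensities in HU.
#' @param neighbor Logical; draw the adjacent organ.
#' @param neighbor_axes Adjacent organ semi-axes (row, col), pixels.
#' @param neighbor_gap Width in pixels of the weak-edge corridor separating
#'   liver and neighbor.
#' @param gap_hu HU of the weak-edge corridor; closer to the organ values
#'   means a weaker edge.
#' @param rim_hu,rim_width HU and width (px) of the fat-plane interfaces
#'   around organ boundaries.
#' @param noise_sigma Additive Gaussian noise standard deviation in HU.
#' @param salt_pepper Fraction of pixels replaced by impulse noise
#'   (-1000/+1000 HU); default 0.
#' @param ring Logical; draw a bright ring artifact touching the body
#'   outline.
#' @param ring_hu Ring intensity in HU.
#' @param tumor `NULL`, or a list with `center` (row, col), `radius` (px) and
#'   `hu`; must lie fully inside the liver. Tumor pixels count as liver in
#'   the ground truth (whole-liver reference).
#' @param spacing Physical pixel size (row, col) in mm.
#' @param seed Integer RNG seed; generation is deterministic per seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 320,
                         body_center = c(160, 175), body_radius = 125,
                         liver_center = c(160, 130), liver_axes = c(95, 75),
                         liver_hu = 90, background_hu = 40,
                         neighbor = TRUE, neighbor_hu = 70,
                         neighbor_axes = c(50, 38), neighbor_gap = 4,
                         gap_hu = -70, rim_hu = -110, rim_width = 3,
                         noise_sigma = 10, salt_pepper = 0,
                         ring = FALSE, ring_hu = 300,
                         tumor = NULL, spacing = c(1.4, 1.4), seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (s$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (s$salt_pepper < 0 || s$salt_pepper > 1)
    stop("salt_pepper must be in [0, 1]", call. = FALSE)
  # liver (including its rim) must lie inside the body disk
  ang <- seq(0, 2 * pi, length.out = 721)
  lr <- s$liver_center[1] + (s$liver_axes[1] + s$rim_width) * sin(ang)
  lc <- s$liver_center[2] + (s$liver_axes[2] + s$rim_width) * cos(ang)
  if (any((lr - s$body_center[1])^2 + (lc - s$body_center[2])^2 >
          s$body_radius^2))
    stop("liver ellipse (with interface rim) must lie inside the body",
         call. = FALSE)
  if (!is.null(s$tumor)) {
    tr <- s$tumor$center[1] + s$tumor$radius * sin(ang)
    tc <- s$tumor$center[2] + s$tumor$radius * cos(ang)
    if (any((tr - s$liver_center[1])^2 / s$liver_axes[1]^2 +
            (tc - s$liver_center[2])^2 / s$liver_axes[2]^2 > 1))
      stop("tumor must lie fully inside the liver", call. = FALSE)
  }
  invisible(s)
}

# Logical mask of an ellipse (center (row, col), semi-axes (row, col)),
# optionally grown by `grow` pixels on every side.
ellipse_mask <- function(rows, cols, center, axes, grow = 0) {
  outer((rows - center[1])^2 / (axes[1] + grow)^2, rep(1, length(cols))) +
    outer(rep(1, length(rows)), (cols - center[2])^2 / (axes[2] + grow)^2) <= 1
}

#' Generate a synthetic abdominal CT phantom
#'
#' Renders the slice described by a [phantom_spec()] and its exact
#' ground-truth liver mask. Deterministic for a fixed `seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `slice` (a [ct_slice()] in HU), `truth` (0/1 liver
#'   mask; tumor pixels included), and `ring` (0/1 mask of ring-artifact
#'   pixels, all-zero when the ring is disabled).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$size
  rows <- seq_len(n); cols <- seq_len(n)
  rr <- outer(rows, rep(1, n)); cc <- outer(rep(1, n), cols)

  body <- (rr - spec$body_center[1])^2 + (cc - spec$body_center[2])^2 <=
    spec$body_radius^2
  liver <- ellipse_mask(rows, cols, spec$liver_center, spec$liver_axes)
  liver_rim <- ellipse_mask(rows, cols, spec$liver_center, spec$liver_axes,
                            grow = spec$rim_width) & !liver

  hu <- matrix(-1000, n, n)            # air
  hu[body] <- spec$background_hu       # soft tissue
  hu[liver_rim & body] <- spec$rim_hu  # fat plane around the liver

  if (isTRUE(spec$neighbor)) {
    ncenter <- c(spec$liver_center[1],
                 spec$liver_center[2] + spec$liver_axes[2] +
                   spec$neighbor_gap + spec$neighbor_axes[2])
    neigh <- ellipse_mask(rows, cols, ncenter, spec$neighbor_axes)
    neigh_rim <- ellipse_mask(rows, cols, ncenter, spec$neighbor_axes,
                              grow = spec$rim_width) & !neigh
    hu[neigh_rim & body & !liver] <- spec$rim_hu
    # weak-edge corridor: the zone where the dilated organs overlap
    corridor <- ellipse_mask(rows, cols, spec$liver_center, spec$liver_axes,
                             grow = spec$neighbor_gap) &
      ellipse_mask(rows, cols, ncenter, spec$neighbor_axes,
                   grow = spec$neighbor_gap) & !liver & !neigh
    hu[corridor] <- spec$gap_hu
    hu[neigh] <- spec$neighbor_hu
  }
  # guaranteed abdominal-wall layer: the outermost body pixels are always
  # soft tissue, so organ interfaces can graze but never breach the outline
  wall <- body & (rr - spec$body_center[1])^2 + (cc - spec$body_center[2])^2 >
    (spec$body_radius - 1)^2
  hu[wall] <- spec$background_hu

  hu[liver] <- spec$liver_hu

  if (!is.null(spec$tumor)) {
    tum <- (rr - spec$tumor$center[1])^2 + (cc - spec$tumor$center[2])^2 <=
      spec$tumor$radius^2
    hu[tum] <- spec$tumor$hu
  }

  # ring artifacts are concentric circles around the scanner axis (the image
  # center); the visible artifact is a thin bright arc in the air that
  # crosses and touches the body outline where the circle enters the body.
  # The arc is open-ended so it does not enclose the air between itself and
  # the body.
  ring_mask <- matrix(0L, n, n)
  if (isTRUE(spec$ring)) {
    rc <- c(n / 2, n / 2)
    rad <- spec$body_radius + 10
    d2 <- (rr - rc[1])^2 + (cc - rc[2])^2
    ang <- atan2(rr - rc[1], cc - rc[2]) * 180 / pi  # 0 = right, -90 = up
    d2b <- (rr - spec$body_center[1])^2 + (cc - spec$body_center[2])^2
    ring <- abs(sqrt(d2) - rad) <= 1.5 & ang <= -10 & ang >= -170 &
      d2b > (spec$body_radius + 2)^2
    hu[ring] <- spec$ring_hu
    ring_mask[ring] <- 1L
  }

  hu <- with_seed(spec$seed, {
    out <- hu
    if (spec$noise_sigma > 0)
      out <- out + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    if (spec$salt_pepper > 0) {
      k <- round(spec$salt_pepper * n * n)
      idx <- sample.int(n * n, k)
      out[idx] <- ifelse(stats::runif(k) < 0.5, -1000, 1000)
    }
    out
  })

  truth <- matrix(0L, n, n)
  truth[liver] <- 1L
  list(slice = ct_slice(hu, spacing = spec$spacing,
                        origin_note = "synthetic phantom, top-left origin"),
       truth = truth, ring = ring_mask)
}

#' Generate a randomized phantom suite
#'
#' Draws `n` phantoms with jittered geometry around the default
#' specification; `round(n * mix)` of them (chosen at random) contain a
#' tumor inclusion, half cancer-like (hypodense) and half hemangioma-like
#' (mildly hyperdense), mirroring a 1:1 tumor:normal case mix. Reproducible
#' per seed.
#'
#' @param n Number of phantoms (>= 1).
#' @param mix Fraction of phantoms containing a tumor, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param base_spec Template [phantom_spec()]; geometry is jittered around
#'   it, everything else (noise level, palette, weak-edge contrast) is
#'   inherited.
#' @return List of `n` elements, each as returned by [generate_phantom()]
#'   plus the element `spec` used.
#' @export
generate_suite <- function(n = 10, mix = 0.5, seed = 1L,
                           base_spec = phantom_spec()) {
  stopifnot(n >= 1, mix >= 0, mix <= 1)
  with_seed(seed, {
    tumor_idx <- sample.int(n, round(n * mix))
    lapply(seq_len(n), function(i) {
      s <- base_spec
      s$liver_axes <- round(base_spec$liver_axes * stats::runif(2, 0.9, 1.04))
      # the liver rests against the left body wall with a 2 px soft-tissue
      # sliver (the abdominal wall): jitter the craniocaudal position and
      # size, then place the column so the interface rim sits at the wall
      s$liver_center[1] <- base_spec$liver_center[1] + round(stats::runif(1, -5, 5))
      s$liver_center[2] <- base_spec$body_center[2] - base_spec$body_radius +
        2 + s$rim_width + s$liver_axes[2]
      while (!isTRUE(tryCatch({validate_phantom_spec(s); TRUE},
                              error = function(e) FALSE))) {
        s$liver_center[2] <- s$liver_center[2] + 1
      }
      s$neighbor_axes <- round(base_spec$neighbor_axes * stats::runif(2, 0.9, 1.1))
      if (i %in% tumor_idx) {
        hypo <- stats::runif(1) < 0.5
        radius <- round(0.22 * min(s$liver_axes) * stats::runif(1, 0.8, 1.2))
        off <- stats::runif(2, -0.3, 0.3) * (s$liver_axes - radius)
        s$tumor <- list(center = round(s$liver_center + off), radius = radius,
                        hu = if (hypo) 35 else 115)
      } else {
        s$tumor <- NULL
      }
      s$seed <- sample.int(.Machine$integer.max, 1)
      validate_phantom_spec(s)
      out <- generate_phantom(s)
      out$spec <- s
      out
    })
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "phantom: %d x %d px, body r=%d @ (%d,%d), liver %dx%d @ (%d,%d)\n",
    "  neighbor=%s gap=%d px (gap %g HU), noise %g HU, ring=%s, tumor=%s\n"),
    x$size, x$size, x$body_radius, x$body_center[1], x$body_center[2],
    x$liver_axes[1], x$liver_axes[2], x$liver_center[1], x$liver_center[2],
    x$neighbor, x$neighbor_gap, x$gap_hu, x$noise_sigma, x$ring,
    !is.null(x$tumor)))
  invisible(x)
}
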