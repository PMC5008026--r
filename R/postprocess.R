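# Morphological postprocessing: ring-artifact body mask, outlier removal,
# component analysis, inversion, smoothing, anatomical liver selection, and
# the full segmentation pipeline.

# Disk structuring element of the given pixel radius: offsets with
# di^2 + dj^2 <= (r + 0.5)^2, i.e. EBImage's odd-sized "disc" brush.
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Morphology with zero padding so that structures touching the image border
# behave as if surrounded by background (EBImage itself replicates the
# border, which would anchor border-touching structures).
pad_zero <- function(mask, k) {
  out <- matrix(0L, nrow(mask) + 2 * k, ncol(mask) + 2 * k)
  out[k + seq_len(nrow(mask)), k + seq_len(ncol(mask))] <- mask
  out
}
crop_pad <- function(mask, k, nr, nc) mask[k + seq_len(nr), k + seq_len(nc)]

erode_disk <- function(mask, radius) {
  k <- radius + 1L
  m <- EBImage::erode(pad_zero(mask, k), disk_brush(radius))
  as_binary_mask(crop_pad(m, k, nrow(mask), ncol(mask)))
}

dilate_disk <- function(mask, radius) {
  k <- radius + 1L
  m <- EBImage::dilate(pad_zero(mask, k), disk_brush(radius))
  as_binary_mask(crop_pad(m, k, nrow(mask), ncol(mask)))
}

open_disk <- function(mask, radius) dilate_disk(erode_disk(mask, radius), radius)

#' Remove outlier edge pixels
#'
#' Morphological opening with a disk structuring element: edge evidence
#' thinner than the disk (isolated noise responses) is erased while the
#' contiguous boundary bands survive.
#'
#' @param mask Integer 0/1 matrix.
#' @param radius Disk radius in pixels (>= 1); default 2.
#' @return Integer 0/1 matrix.
#' @export
remove_outliers <- function(mask, radius = 2) {
  mask <- as_binary_mask(mask)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  open_disk(mask, as.integer(radius))
}

#' Label connected components
#'
#' 8-connected (default) or 4-connected labeling of the foreground, with
#' per-component pixel counts and centroids. 8-connectivity is the package
#' default throughout: diagonal edge chains produced by the 8-direction
#' detector must not fragment.
#'
#' @param mask Integer 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return An object of class `component_labeling`: list with `labels`
#'   (integer matrix, 0 = background), `sizes` and `centroids` (matrix of
#'   (row, col) means), indexed by label.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_binary_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask == 1L)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) {
    return(structure(list(labels = labels, sizes = integer(0),
                          centroids = matrix(numeric(0), 0, 2)),
                     class = "component_labeling"))
  }
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    okv <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[okv] - 1L) * nr + r2[okv]
    hit <- id[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[fg[okv]][hit], id[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  labels[fg] <- memb
  sizes <- tabulate(memb)
  centroids <- cbind(
    row = rowsum(as.numeric(rows), memb)[, 1] / sizes,
    col = rowsum(as.numeric(cols), memb)[, 1] / sizes
  )
  rownames(centroids) <- NULL
  structure(list(labels = labels, sizes = sizes, centroids = centroids),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("component labeling: %d component(s), %d foreground pixel(s)\n",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

#' Retain the largest connected component
#'
#' Ties are broken toward the smallest centroid column (leftmost), then the
#' smallest label.
#'
#' @inheritParams label_components
#' @return Integer 0/1 matrix containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (length(lab$sizes) == 0)
    stop("mask has no positive pixels", call. = FALSE)
  best <- which(lab$sizes == max(lab$sizes))
  if (length(best) > 1) {
    best <- best[order(lab$centroids[best, "col"], best)]
  }
  out <- matrix(0L, nrow(lab$labels), ncol(lab$labels))
  out[lab$labels == best[1]] <- 1L
  out
}

#' Ring-artifact body mask
#'
#' Builds the mask M used to suppress ring artifacts: the display image is
#' thresholded with Otsu's method to separate the body from the air
#' background, the largest component (the body) is retained and its interior
#' holes are filled (dark organ interfaces inside the body must not puncture
#' the silhouette), and a morphological opening with a large disk shaves off
#' thin bright structures clinging to the body outline -- which is exactly
#' the geometry of a ring artifact.
#'
#' @param image Numeric display matrix on `[1, 256]`.
#' @param radius Disk radius of the opening, in pixels (default 20).
#' @return Integer 0/1 matrix: 1 inside the opened body region.
#' @export
ring_artifact_mask <- function(image, radius = 20) {
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  x01 <- (pmin(pmax(image, 1), 256) - 1) / 255
  thr <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1))
  fg <- matrix(as.integer(x01 > thr), nrow(image), ncol(image))
  if (sum(fg) == 0) stop("empty foreground after thresholding", call. = FALSE)
  # dark organ interfaces crack the silhouette into fragments; fill the
  # enclosed holes first so the largest component is the whole body and not
  # a body fragment
  fg <- matrix(as.integer(EBImage::fillHull(fg)), nrow(fg), ncol(fg))
  body <- largest_component(fg, connectivity = 8)
  m <- open_disk(body, as.integer(radius))
  if (sum(m) == 0)
    stop("body region smaller than the structuring disk", call. = FALSE)
  m
}

#' Invert an edge mask and erode
#'
#' Complements the edge mask and erodes with a disk, converting closed edge
#' contours into interior regions cleanly separated from the surrounding
#' background (diagonal pixel bridges across thin edges are cut by the
#' erosion).
#'
#' @param edge_mask Integer 0/1 matrix of edge evidence.
#' @param radius Disk radius in pixels.
#' @return Integer 0/1 matrix of candidate interior regions.
#' @export
invert_and_erode <- function(edge_mask, radius = 2) {
  edge_mask <- as_binary_mask(edge_mask)
  inv <- 1L - edge_mask
  erode_disk(inv, as.integer(radius))
}

#' Smooth a mask boundary and reconnect small gaps
#'
#' Gaussian-blurs the mask, re-binarizes at 0.5 (which smooths the boundary
#' while approximately preserving area for large convex shapes), then applies
#' a median (majority) filter that closes thin slits and reconnects small
#' disconnected fragments of the boundary.
#'
#' @param mask Integer 0/1 matrix.
#' @param sigma Gaussian sigma in pixels (> 0).
#' @param reconnect_window Odd median window in pixels.
#' @return Integer 0/1 matrix.
#' @export
smooth_and_reconnect <- function(mask, sigma = 2, reconnect_window = 5) {
  mask <- as_binary_mask(mask)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (reconnect_window %% 2 == 0)
    stop("reconnect_window must be odd", call. = FALSE)
  if (sum(mask) == 0) return(mask)
  g <- EBImage::gblur(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                      sigma = sigma)
  b <- matrix(as.integer(g >= 0.5), nrow(mask), ncol(mask))
  as_binary_mask(median_filter_2d(b, reconnect_window))
}

# Remove candidate regions touching the image border (the air field around
# the body and its fragments). The liver never reaches the border of an
# abdominal slice -- the detector margin already treats the border as
# non-edge. If every component touches the border the mask is returned
# unchanged rather than emptied.
drop_border_components <- function(mask, band = 3L) {
  lab <- label_components(mask, 8)
  if (length(lab$sizes) == 0) return(mask)
  lb <- lab$labels
  edge <- c(seq_len(band), nrow(lb) - seq_len(band) + 1L)
  edgec <- c(seq_len(band), ncol(lb) - seq_len(band) + 1L)
  touching <- setdiff(unique(c(lb[edge, ], lb[, edgec])), 0L)
  if (length(touching) == 0 || length(touching) == length(lab$sizes))
    return(mask)
  out <- mask
  out[lb %in% touching] <- 0L
  out
}

#' Select the liver among candidate regions
#'
#' Anatomical rule: on an axial abdominal CT displayed in radiological
#' convention the liver occupies the left part of the image and is the
#' largest organ there. Among components whose centroid column lies left of
#' `0.6 x` image width, the largest is returned; if none qualifies, the
#' overall largest is returned with a warning.
#'
#' @param labeling A `component_labeling` from [label_components()].
#' @param image_shape Length-2 integer vector `(rows, cols)`.
#' @return Integer 0/1 matrix of the selected component.
#' @export
select_liver <- function(labeling, image_shape) {
  stopifnot(inherits(labeling, "component_labeling"))
  if (length(labeling$sizes) == 0)
    stop("no candidate components", call. = FALSE)
  width <- image_shape[2]
  left <- which(labeling$centroids[, "col"] < 0.6 * width)
  pool <- if (length(left) > 0) left else {
    warning("no component in the left region; falling back to the overall largest")
    seq_along(labeling$sizes)
  }
  best <- pool[order(-labeling$sizes[pool],
                     labeling$centroids[pool, "col"], pool)][1]
  out <- matrix(0L, nrow(labeling$labels), ncol(labeling$labels))
  out[labeling$labels == best] <- 1L
  out
}

#' Segment the liver from a CT slice
#'
#' The full pipeline: HU windowing (skipped for display-scaled inputs),
#' median denoising, single-block linear detection (maximal directional
#' ratio field + confidence matrix), morphological outlier removal, largest
#' edge network, inversion and erosion into candidate interior regions,
#' intersection with the ring-artifact body mask, anatomical liver
#' selection, and boundary smoothing/reconnection. Deterministic for fixed
#' inputs.
#'
#' @param slice A [ct_slice()].
#' @param params An [sblda_params()] object.
#' @param apply_ring_mask Apply the ring-artifact body mask M (default TRUE).
#' @param save_intermediates Optional directory; when given, each stage is
#'   written there as a numbered PNG.
#' @return Integer 0/1 liver mask (a single 8-connected component).
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 1))
#' m <- segment_liver(ph$slice, sblda_params())
#' dice(m, ph$truth)
#' }
#' @export
segment_liver <- function(slice, params = sblda_params(),
                          apply_ring_mask = TRUE, save_intermediates = NULL) {
  stopifnot(inherits(slice, "ct_slice"), inherits(params, "sblda_params"))
  stage <- function(name, mask) {
    if (sum(mask) == 0)
      stop(sprintf("segmentation failed at stage '%s': empty mask", name),
           call. = FALSE)
    mask
  }
  dump <- function(i, name, img, clip = c(0, 1)) {
    if (!is.null(save_intermediates)) {
      dir.create(save_intermediates, showWarnings = FALSE, recursive = TRUE)
      write_display_png(img, file.path(save_intermediates,
                                       sprintf("%02d_%s.png", i, name)), clip)
    }
  }

  display <- if (slice$display_scaled) slice$pixels
             else apply_window(slice, params$window_width, params$window_level)
  dump(1, "windowed", display, c(1, 256))
  den <- median_filter_2d(display, params$median_window)
  dump(2, "denoised", den, c(1, 256))

  field <- max_ratio_field(den, params)
  cw <- confidence_matrix(field, params$T)
  stage("confidence", cw)
  dump(3, "confidence", cw)

  cleaned <- stage("outlier removal", remove_outliers(cw, params$outlier_radius))
  dump(4, "opened_edges", cleaned)
  edges <- stage("largest edge network", largest_component(cleaned, 8))
  dump(5, "edge_network", edges)

  interior <- stage("invert and erode",
                    invert_and_erode(edges, params$outlier_radius))
  dump(6, "interior", interior)

  if (apply_ring_mask) {
    # the body silhouette comes from the windowed original image: median
    # filtering can blur thin soft-tissue slivers between an organ interface
    # and the body outline into the interface value, cracking the silhouette
    M <- ring_artifact_mask(display, params$ring_radius)
    dump(7, "ring_mask", M)
    interior <- stage("ring mask intersection",
                      as_binary_mask(interior * M))
  }

  interior <- drop_border_components(interior,
                                     band = params$outlier_radius + 1L)
  lab <- label_components(interior, 8)
  liver <- stage("liver selection", select_liver(lab, dim(slice$pixels)))
  dump(8, "selected", liver)

  out <- stage("smoothing", smooth_and_reconnect(liver, params$gaussian_sigma,
                                                 params$reconnect_window))
  out <- largest_component(out, 8)  # smoothing must not leave satellites
  dump(9, "final", out)
  out
}
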