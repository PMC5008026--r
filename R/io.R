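#' Construct a CT slice object
#'
#' A `ct_slice` holds a rectangular 2D raster of intensities together with
#' physical pixel spacing. Intensities are Hounsfield units for CT-derived
#' data (`display_scaled = FALSE`) or already on the positive display scale
#' `[1, 256]` for phantom/raster inputs (`display_scaled = TRUE`), in which
#' case [segment_liver()] skips HU windowing.
#'
#' Coordinate convention: row-major, origin at the top-left, 1-based matrix
#' indexing; "left of image" means the lowest column indices.
#'
#' @param pixels Numeric matrix of intensities; must be finite-valued.
#' @param spacing Length-2 numeric vector, physical (row, col) pixel size in
#'   mm; both components > 0.
#' @param display_scaled Logical; `TRUE` when `pixels` are already on the
#'   display scale and windowing must be bypassed.
#' @param origin_note Free-text tag recording the orientation convention of
#'   the source data.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing = c(1, 1), display_scaled = FALSE,
                     origin_note = "row-major, origin top-left") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("pixels must be finite-valued", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive values (row, col) in mm", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing,
                 display_scaled = isTRUE(display_scaled),
                 origin_note = origin_note),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("CT slice: %d x %d pixels, spacing %.3g x %.3g mm, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              if (x$display_scaled) "display-scaled" else "Hounsfield units"))
  invisible(x)
}

#' Read a CT slice from DICOM, NIfTI or a grayscale raster
#'
#' DICOM single-frame slices are decoded with the built-in reader
#' (uncompressed little-endian transfer syntaxes), applying RescaleSlope and
#' RescaleIntercept so the result is in Hounsfield units. NIfTI volumes are
#' read with RNifti and the requested axial plane is extracted. PNG/TIFF
#' rasters are taken as already display-scaled: sample values in `[0, 1]` are
#' mapped to the `[1, 256]` display scale and flagged so windowing is skipped.
#'
#' @param path Input file path.
#' @param format One of `"auto"`, `"dicom"`, `"nifti"`, `"raster"`; `"auto"`
#'   dispatches on the file extension.
#' @param slice For NIfTI volumes, the index of the axial plane to extract
#'   (third array dimension).
#' @return A [ct_slice()].
#' @export
read_ct_slice <- function(path, format = c("auto", "dicom", "nifti", "raster"),
                          slice = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    low <- tolower(path)
    format <- if (grepl("\\.dcm$|\\.dicom$", low)) "dicom"
      else if (grepl("\\.nii$|\\.nii\\.gz$", low)) "nifti"
      else if (grepl("\\.png$|\\.tif$|\\.tiff$", low)) "raster"
      else stop("cannot infer format from extension: ", path, call. = FALSE)
  }
  switch(format,
    dicom = read_dicom_slice(path),
    nifti = {
      vol <- RNifti::readNifti(path)
      pd <- RNifti::pixdim(vol)
      arr <- as.array(vol)
      if (length(dim(arr)) == 2) {
        px <- arr
      } else {
        if (slice < 1 || slice > dim(arr)[3])
          stop("slice index out of range", call. = FALSE)
        px <- arr[, , slice]
      }
      sp <- if (length(pd) >= 2 && all(is.finite(pd[1:2])) && all(pd[1:2] > 0)) {
        pd[1:2]
      } else {
        warning("missing pixel spacing; defaulting to 1 x 1 mm")
        c(1, 1)
      }
      ct_slice(px, spacing = sp, origin_note = "NIfTI i-j plane")
    },
    raster = {
      low <- tolower(path)
      img <- if (grepl("\\.png$", low)) png::readPNG(path)
             else tiff::readTIFF(path)
      if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
      ct_slice(img * 255 + 1, spacing = c(1, 1), display_scaled = TRUE,
               origin_note = "raster, top-left origin")
    })
}

#' Write / read a binary mask
#'
#' Masks are written losslessly: PNG and TIFF as 8-bit grayscale with values
#' {0, 255}, NIfTI as an integer volume. `read_mask()` inverts the encoding;
#' the round trip is the identity for every valid binary mask.
#'
#' @param mask Integer or numeric matrix with values in {0, 1}.
#' @param path Output path; format chosen by extension (.png, .tif/.tiff,
#'   .nii/.nii.gz).
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns an
#'   integer 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  low <- tolower(path)
  mnum <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ok <- if (grepl("\\.png$", low)) {
    png::writePNG(mnum, target = path)
    TRUE
  } else if (grepl("\\.tif$|\\.tiff$", low)) {
    tiff::writeTIFF(mnum, where = path)
    TRUE
  } else if (grepl("\\.nii$|\\.nii\\.gz$", low)) {
    RNifti::writeNifti(RNifti::asNifti(mask, datatype = "uint8"), path)
    TRUE
  } else stop("unsupported mask format: ", path, call. = FALSE)
  if (!isTRUE(ok) || !file.exists(path))
    stop("failed to write mask to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  low <- tolower(path)
  m <- if (grepl("\\.png$", low)) png::readPNG(path)
    else if (grepl("\\.tif$|\\.tiff$", low)) tiff::readTIFF(path)
    else if (grepl("\\.nii$|\\.nii\\.gz$", low)) as.array(RNifti::readNifti(path))
    else stop("unsupported mask format: ", path, call. = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_binary_mask(round(as.matrix(m)))
}

# Validate and coerce to an integer 0/1 matrix.
as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("mask values must be strictly in {0, 1}", call. = FALSE)
  m
}

#' Write a display image as an 8-bit grayscale PNG
#'
#' Utility for `--save-intermediates`: maps the `[1, 256]` display scale (or
#' an arbitrary numeric range after clipping) onto `[0, 1]` PNG samples.
#'
#' @param image Numeric matrix.
#' @param path Output PNG path.
#' @param clip Optional two-element range; values are clipped to it before
#'   scaling. Default is the display range `c(1, 256)`.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(image, path, clip = c(1, 256)) {
  x <- pmin(pmax(image, clip[1]), clip[2])
  png::writePNG((x - clip[1]) / (clip[2] - clip[1]), target = path)
  invisible(path)
}
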