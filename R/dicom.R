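# Minimal single-frame DICOM reader.
#
# Supports the uncompressed little-endian transfer syntaxes (implicit VR
# 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1), MONOCHROME1/2
# photometric interpretation, 8- or 16-bit pixels, signed or unsigned.
# RescaleSlope/Intercept are applied so the returned slice is in Hounsfield
# units. Encapsulated (compressed) syntaxes and big-endian files are
# rejected with a format error.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140)
    stop("not a DICOM file (too short): ", path, call. = FALSE)
  off <- 0L
  if (rawToChar(raw[129:132]) == "DICM") {
    off <- 132L
  }
  u16 <- function(i) as.integer(raw[i + 1L]) + 256L * as.integer(raw[i + 2L])
  u32 <- function(i) {
    as.integer(raw[i + 1L]) + 256 * as.integer(raw[i + 2L]) +
      65536 * as.integer(raw[i + 3L]) + 16777216 * as.integer(raw[i + 4L])
  }
  long_vrs <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UT", "UN", "UC", "UR")
  syntax <- if (off > 0L) UID_EXPLICIT_LE else UID_IMPLICIT_LE
  tags <- list()
  pos <- off
  n <- length(raw)
  while (pos + 8 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    meta <- group == 2L
    explicit <- meta || syntax == UID_EXPLICIT_LE
    if (explicit) {
      vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) # undefined length: sequences etc.
      stop("unsupported DICOM element with undefined length", call. = FALSE)
    body <- pos + hdr
    if (body + len > n)
      stop("truncated DICOM element", call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      syntax <- sub("\\x00+$", "", rawToChar(raw[(body + 1L):(body + len)]))
      if (!syntax %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", syntax, call. = FALSE)
    }
    keep <- c("0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,0004", "0028,1052", "0028,1053")
    if (key %in% keep) {
      tags[[key]] <- raw[(body + 1L):(body + len)]
      attr(tags[[key]], "vr") <- vr
    }
    if (key == "7fe0,0010") {
      tags[["pixel_data"]] <- raw[(body + 1L):(body + len)]
      break
    }
    pos <- body + len
  }
  if (is.null(tags$pixel_data))
    stop("no pixel data found in DICOM file: ", path, call. = FALSE)

  as_us <- function(x, default = NULL) {
    if (is.null(x)) return(default)
    as.integer(x[1]) + 256L * as.integer(x[2])
  }
  as_str <- function(x) {
    if (is.null(x)) return(NULL)
    trimws(gsub("\\x00", "", rawToChar(x)))
  }
  rows <- as_us(tags[["0028,0010"]])
  cols <- as_us(tags[["0028,0011"]])
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns", call. = FALSE)
  bits <- as_us(tags[["0028,0100"]], 16L)
  pixrep <- as_us(tags[["0028,0103"]], 0L)
  slope <- 1; intercept <- 0
  s <- as_str(tags[["0028,1053"]]); if (!is.null(s) && nzchar(s)) slope <- as.numeric(s)
  s <- as_str(tags[["0028,1052"]]); if (!is.null(s) && nzchar(s)) intercept <- as.numeric(s)

  spacing <- c(1, 1); sp <- as_str(tags[["0028,0030"]])
  if (!is.null(sp) && nzchar(sp)) {
    parts <- as.numeric(strsplit(sp, "\\\\")[[1]])
    if (length(parts) == 2 && all(is.finite(parts)) && all(parts > 0)) {
      spacing <- parts
    }
  } else {
    warning("DICOM file lacks PixelSpacing; defaulting to 1 x 1 mm")
  }

  pd <- tags$pixel_data
  npix <- rows * cols
  vals <- if (bits == 16) {
    readBin(pd, what = "integer", n = npix, size = 2L,
            signed = pixrep == 1L, endian = "little")
  } else if (bits == 8) {
    readBin(pd, what = "integer", n = npix, size = 1L,
            signed = pixrep == 1L, endian = "little")
  } else stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  if (length(vals) < npix)
    stop("DICOM pixel data shorter than Rows x Columns", call. = FALSE)
  # DICOM pixel data is stored row by row, top-left first
  px <- matrix(as.numeric(vals[seq_len(npix)]), nrow = rows, ncol = cols,
               byrow = TRUE)
  hu <- slope * px + intercept
  photo <- as_str(tags[["0028,0004"]])
  if (!is.null(photo) && photo == "MONOCHROME1") hu <- max(hu) + min(hu) - hu
  ct_slice(hu, spacing = spacing,
           origin_note = "DICOM row-major, top-left origin")
}
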