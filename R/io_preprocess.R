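# Reading CT slices, Hounsfield-unit conversion, and the circular
# parenchyma mask that restricts the sliding-window search region.

#' Construct a CT slice object
#'
#' A `ct_slice` holds the raw detector gray values of one 2D slice together
#' with the linear rescale metadata (slope `K`, intercept `C`) needed to
#' convert them to Hounsfield units, `HU = K * raw + C`.
#'
#' @param pixels Integer (or numeric) matrix of raw gray values, indexed
#'   `[row, col]` with row 1 at the top.
#' @param slope Rescale slope `K`; finite and nonzero.
#' @param intercept Rescale intercept `C`; finite.
#' @param pixel_spacing Optional numeric pair, pixel spacing in mm.
#' @param source_id Identifier carried through detections and metrics.
#' @return An object of class `ct_slice`.
#' @seealso [read_slice()], [to_hounsfield()]
#' @export
ct_slice <- function(pixels, slope, intercept, pixel_spacing = NULL,
                     source_id = "slice") {
  .assert(is.matrix(pixels) && length(pixels) > 0, "pixels must be a non-empty matrix")
  .assert(.is_scalar_number(slope) && slope != 0, "slope must be finite and nonzero")
  .assert(.is_scalar_number(intercept), "intercept must be a finite number")
  structure(list(pixels = pixels, slope = slope, intercept = intercept,
                 pixel_spacing = pixel_spacing, source_id = source_id),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice '%s' %dx%d, slope=%g intercept=%g>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$slope, x$intercept))
  invisible(x)
}

#' Read a CT slice from DICOM, PNG or TIFF
#'
#' DICOM files supply slope/intercept from their rescale tags. PNG/TIFF
#' carry no HU metadata, so the values must come either from the `slope` /
#' `intercept` arguments or from a plain-text sidecar file `<path>.meta`
#' containing `slope <value>` and `intercept <value>` lines (optionally
#' `pixel_spacing <row> <col>`). Explicit arguments always take precedence.
#' Missing rescale information is an error: silently guessed HU values would
#' corrupt every downstream stage.
#'
#' @param path Path to a `.dcm`/`.dicom`, `.png`, `.tif` or `.tiff` file.
#' @param slope,intercept Optional overrides for the rescale metadata.
#' @return A [ct_slice()].
#' @export
read_slice <- function(path, slope = NULL, intercept = NULL) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  sid <- tools::file_path_sans_ext(basename(path))
  if (ext %in% c("dcm", "dicom")) {
    d <- .read_dicom(path)
    K <- if (!is.null(slope)) slope else d$slope
    C <- if (!is.null(intercept)) intercept else d$intercept
    .assert(!is.null(K) && !is.null(C),
            "DICOM file lacks rescale slope/intercept and no override was given")
    return(ct_slice(d$pixels, K, C, d$pixel_spacing, sid))
  }
  raw <- switch(ext,
    png = {
      img <- png::readPNG(path, info = TRUE)
      bits <- attr(img, "info")$bit.depth
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      round(img * (2^bits - 1))
    },
    tif = , tiff = {
      img <- tiff::readTIFF(path, info = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      bits <- attr(img, "bits.per.sample")
      if (is.null(bits)) bits <- 16L
      round(img * (2^bits - 1))
    },
    stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE)
  )
  raw <- matrix(as.numeric(raw), nrow(raw), ncol(raw))  # drop reader attributes
  meta <- .read_sidecar(paste0(path, ".meta"))
  K <- if (!is.null(slope)) slope else meta$slope
  C <- if (!is.null(intercept)) intercept else meta$intercept
  .assert(!is.null(K) && !is.null(C),
          sprintf("no slope/intercept for '%s': supply overrides or a '%s.meta' sidecar",
                  basename(path), basename(path)))
  ct_slice(raw, K, C, meta$pixel_spacing, sid)
}

# Sidecar format: one "key value..." pair per line, '#' comments allowed.
.read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  out <- list()
  for (ln in readLines(path, warn = FALSE)) {
    ln <- sub("#.*$", "", ln)
    toks <- strsplit(trimws(ln), "[[:space:]=:]+")[[1]]
    if (length(toks) < 2L) next
    out[[toks[1L]]] <- as.numeric(toks[-1L])
  }
  out
}

#' Write the sidecar metadata file used by [read_slice()]
#'
#' @param path Image path; the sidecar is written to `<path>.meta`.
#' @param slope,intercept Rescale metadata.
#' @param pixel_spacing Optional numeric pair in mm.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar <- function(path, slope, intercept, pixel_spacing = NULL) {
  lines <- c(sprintf("slope %.10g", slope), sprintf("intercept %.10g", intercept))
  if (!is.null(pixel_spacing))
    lines <- c(lines, paste("pixel_spacing", paste(format(pixel_spacing), collapse = " ")))
  writeLines(lines, paste0(path, ".meta"))
  invisible(paste0(path, ".meta"))
}

#' Convert a CT slice to Hounsfield units
#'
#' Applies the linear rescale `HU = K * raw + C` element-wise. With the
#' usual CT calibration (`K = 1`, `C = -1024`) a raw value of 1024 maps to
#' 0 HU, the absorption of water, and raw 0 maps to -1024 HU (air).
#'
#' @param slice A [ct_slice()].
#' @return An object of class `hu_image` with fields `values` (numeric
#'   matrix in HU), `pixel_spacing` and `source_id`.
#' @export
to_hounsfield <- function(slice) {
  .assert(inherits(slice, "ct_slice"), "slice must be a ct_slice")
  hu_image(slice$slope * slice$pixels + slice$intercept,
           pixel_spacing = slice$pixel_spacing, source_id = slice$source_id)
}

#' Construct an HU image
#'
#' @param values Numeric matrix of Hounsfield-unit values.
#' @param pixel_spacing Optional numeric pair in mm.
#' @param source_id Identifier carried through detections.
#' @return An object of class `hu_image`.
#' @export
hu_image <- function(values, pixel_spacing = NULL, source_id = "slice") {
  .assert(is.matrix(values) && length(values) > 0, "values must be a non-empty matrix")
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 source_id = source_id), class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image '%s' %dx%d, range [%.0f, %.0f] HU>\n", x$source_id,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Rough circular segmentation of the lung parenchyma
#'
#' CT acquisitions are centered on the thorax, so the lung parenchyma can be
#' bounded by a fixed circle about the image center. The default radius of
#' 180 px suits 512x512 thorax slices. The mask does not alter pixel values;
#' it only restricts where sliding windows are generated: a window is kept
#' when its center lies inside the circle.
#'
#' @param hu An [hu_image()] (or plain matrix; only its shape is used).
#' @param radius_px Circle radius in pixels (> 0).
#' @param center Optional `(row, col)` center; defaults to the raster
#'   center `floor(dim/2) + 1`.
#' @return An object of class `parenchyma_mask` with fields `mask` (logical
#'   matrix), `center` and `radius_px`.
#' @export
segment_parenchyma <- function(hu, radius_px = 180, center = NULL) {
  .assert(.is_scalar_number(radius_px) && radius_px > 0, "radius_px must be > 0")
  v <- .as_pixels(hu)
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(center)) center <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
  d2 <- outer((seq_len(nr) - center[1L])^2, (seq_len(nc) - center[2L])^2, `+`)
  structure(list(mask = d2 <= radius_px^2, center = center, radius_px = radius_px),
            class = "parenchyma_mask")
}

#' @export
print.parenchyma_mask <- function(x, ...) {
  cat(sprintf("<parenchyma_mask center=(%d,%d) R=%g, %d px inside>\n",
              x$center[1L], x$center[2L], x$radius_px, sum(x$mask)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal DICOM reader: single-frame uncompressed grayscale, little-endian
# explicit or implicit VR. Covers the rescale and pixel tags this package
# needs; anything exotic (compressed transfer syntaxes, big endian) errors.

.read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.info(path)$size
  buf <- readBin(con, "raw", n = sz)
  .assert(length(buf) > 132 && rawToChar(buf[129:132]) == "DICM",
          "not a DICOM file (missing DICM marker)")
  pos <- 133L  # 1-based offset just past the preamble + marker
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  u32 <- function(i) as.integer(buf[i]) + 256 * as.integer(buf[i + 1L]) +
    65536 * as.integer(buf[i + 2L]) + 16777216 * as.integer(buf[i + 3L])
  tags <- list()
  explicit <- TRUE
  syntax <- NULL
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    in_meta <- group == 2L
    expl <- if (in_meta) TRUE else explicit
    if (expl) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    .assert(len >= 0 && pos + hdr + len - 1L <= length(buf) + 1L,
            "corrupt DICOM element length")
    val <- if (len > 0L) buf[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = val)
    if (key == "0002,0010") {
      syntax <- trimws(rawToChar(val[val != as.raw(0)]))
      if (syntax == "1.2.840.10008.1.2") explicit <- FALSE
      else .assert(syntax == "1.2.840.10008.1.2.1",
                   sprintf("unsupported DICOM transfer syntax '%s'", syntax))
    }
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  num <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    s <- trimws(rawToChar(t$value[t$value != as.raw(0)]))
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    as.integer(t$value[1L]) + 256L * as.integer(t$value[2L])
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- us("0028,0100"); signed <- identical(us("0028,0103"), 1L)
  .assert(!is.null(rows) && !is.null(cols) && !is.null(bits), "DICOM lacks image dimensions")
  pd <- tags[["7fe0,0010"]]
  .assert(!is.null(pd), "DICOM lacks pixel data")
  vals <- readBin(pd$value, "integer", n = rows * cols,
                  size = bits / 8L, signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  list(pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
       slope = if (is.null(num("0028,1053"))) NULL else num("0028,1053")[1L],
       intercept = if (is.null(num("0028,1052"))) NULL else num("0028,1052")[1L],
       pixel_spacing = num("0028,0030"))
}
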