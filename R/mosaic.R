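#' Two-channel microscopy mosaic
#'
#' Container for a registered pair of single-channel rasters: the SHG channel
#' (fibrillar collagen contrast) and the CARS channel (lipid contrast), plus the
#' physical pixel pitch and bit depth. Rasters are plain numeric matrices in
#' native intensity units (0..255 for 8-bit, 0..65535 for 16-bit, arbitrary
#' nonnegative values for 32-bit float).
#'
#' @param shg Numeric matrix of nonnegative SHG intensities.
#' @param cars Numeric matrix of nonnegative CARS intensities, same dimensions.
#' @param pixel_size_um Physical pixel pitch in micrometres per pixel
#'   (isotropic); must be positive.
#' @param bit_depth One of 8, 16 or 32 (32 means floating point).
#'
#' @return An object of class `mosaic_image`: a list with elements `shg`,
#'   `cars`, `pixel_size_um`, `bit_depth`.
#' @examples
#' img <- mosaic_image(matrix(0, 4, 4), matrix(1, 4, 4), pixel_size_um = 2)
#' dim(img$shg)
#' @export
mosaic_image <- function(shg, cars, pixel_size_um, bit_depth = 16) {
  if (!is.matrix(shg) || !is.matrix(cars)) {
    abort("shg and cars must be matrices")
  }
  if (!identical(dim(shg), dim(cars))) {
    abort("shg and cars must have identical dimensions")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be a single positive number")
  }
  if (!bit_depth %in% c(8, 16, 32)) {
    abort("bit_depth must be one of 8, 16, 32")
  }
  if (any(shg < 0, na.rm = TRUE) || any(cars < 0, na.rm = TRUE)) {
    abort("intensities must be nonnegative")
  }
  if (bit_depth < 32) {
    top <- 2^bit_depth - 1
    if (max(shg, cars) > top) {
      abort(sprintf("integer rasters must lie in [0, %d] for bit depth %d",
                    top, bit_depth))
    }
  }
  structure(
    list(shg = shg, cars = cars,
         pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "mosaic_image"
  )
}

#' @export
print.mosaic_image <- function(x, ...) {
  d <- dim(x$shg)
  cat(sprintf(
    "<mosaic_image> %d x %d px, %.3g um/px (%.2f x %.2f mm), %d-bit\n",
    d[1], d[2], x$pixel_size_um,
    d[1] * x$pixel_size_um / 1000, d[2] * x$pixel_size_um / 1000,
    x$bit_depth))
  cat(sprintf("  SHG  range [%g, %g]   CARS range [%g, %g]\n",
              min(x$shg), max(x$shg), min(x$cars), max(x$cars)))
  invisible(x)
}

#' Representable maximum of a mosaic's rasters
#'
#' 255 or 65535 for integer bit depths; the observed channel maximum for
#' 32-bit float rasters.
#' @param x Numeric matrix.
#' @param bit_depth 8, 16 or 32.
#' @return Scalar maximum.
#' @keywords internal
raster_max <- function(x, bit_depth) {
  if (bit_depth < 32) 2^bit_depth - 1 else max(x)
}

#' Convert a physical length to a pixel count
#'
#' Filter radii and band thicknesses are specified in micrometres because the
#' pixel pitch varies with objective and zoom. Conversion is round-half-up with
#' a floor of one pixel, so any positive physical length maps to a usable
#' kernel radius.
#'
#' @param length_um Physical length in micrometres (> 0).
#' @param pixel_size_um Pixel pitch in micrometres per pixel (> 0).
#' @return Integer pixel count, at least 1.
#' @examples
#' um_to_px(50, 2)   # 25
#' um_to_px(15, 2)   # 7.5 rounds half-up to 8
#' um_to_px(0.5, 2)  # clamped to 1
#' @export
um_to_px <- function(length_um, pixel_size_um) {
  if (any(length_um <= 0) || any(pixel_size_um <= 0)) {
    abort("lengths and pixel pitch must be positive")
  }
  pmax(1L, as.integer(floor(length_um / pixel_size_um + 0.5)))
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a two-channel mosaic as a multi-page grayscale TIFF
#'
#' Channel 0 (first page) is SHG, channel 1 is CARS. Integer rasters are stored
#' at their native bit depth; 32-bit float rasters are stored scaled by a
#' power-of-two factor (recorded in the sidecar) because TIFF float samples are
#' kept in \code{[0, 1]} by the writer. The pixel pitch, bit depth and any float
#' scale factor are recorded in a small JSON sidecar next to the image
#' (\code{<path>.meta.json}).
#'
#' @param img A [mosaic_image].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(img, path) {
  stopifnot(inherits(img, "mosaic_image"))
  if (img$bit_depth < 32) {
    top <- 2^img$bit_depth - 1
    pages <- list(img$shg / top, img$cars / top)
    scale <- 1
  } else {
    m <- max(img$shg, img$cars, 1)
    scale <- 2^ceiling(log2(m))
    pages <- list(img$shg / scale, img$cars / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = img$bit_depth,
                  compression = "LZW")
  meta <- list(pixel_size_um = img$pixel_size_um,
               bit_depth = img$bit_depth,
               channels = c("shg", "cars"),
               float_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-channel mosaic TIFF
#'
#' The file must contain exactly two grayscale channels, either as two pages or
#' as one page with two samples per pixel. The pixel pitch is taken, in order of
#' precedence, from the `pixel_size_um` argument, the JSON sidecar written by
#' [write_mosaic()], or the TIFF resolution tags; if none is available an error
#' is raised — the pitch is never silently assumed.
#'
#' @param path Path to a 2-channel grayscale TIFF.
#' @param pixel_size_um Optional explicit pixel pitch in micrometres per pixel.
#' @param channel_order Which page/sample holds which signal; default
#'   `c("shg", "cars")`.
#' @return A [mosaic_image].
#' @export
read_mosaic <- function(path, pixel_size_um = NULL,
                        channel_order = c("shg", "cars")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  channel_order <- match.arg(channel_order[1], c("shg", "cars")) |>
    (\(first) if (first == "shg") c("shg", "cars") else c("cars", "shg"))()
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample %||% 8L
  # a single page with two samples per pixel is also accepted
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3) {
    a <- pages[[1]]
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  if (length(pages) != 2) {
    abort(sprintf("expected a 2-channel TIFF, found %d channel(s): %s",
                  length(pages), path))
  }
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  pitch <- pixel_size_um %||% meta$pixel_size_um %||% pitch_from_tags(info)
  if (is.null(pitch)) {
    abort(paste0("no pixel size available for ", path,
                 ": supply pixel_size_um, a sidecar, or resolution tags"))
  }
  bit_depth <- meta$bit_depth %||% (if (bits >= 32) 32L else as.integer(bits))
  chans <- lapply(pages, function(p) {
    p <- matrix(as.numeric(p), nrow = nrow(p))
    # integer pages come back normalized to [0, 1]; restore native levels
    if (bit_depth < 32) round(p * (2^bit_depth - 1)) else
      p * (meta$float_scale %||% 1)
  })
  names(chans) <- channel_order
  mosaic_image(chans$shg, chans$cars, pixel_size_um = pitch,
               bit_depth = bit_depth)
}

# TIFF x.resolution tag in pixels per unit -> um per pixel
pitch_from_tags <- function(info) {
  res <- info$x.resolution
  if (is.null(res) || !is.finite(res) || res <= 0) return(NULL)
  unit <- info$resolution.unit %||% "inch"
  per_um <- switch(as.character(unit),
                   inch = res / 25400, cm = res / 10000, centimeter = res / 10000,
                   NULL)
  if (is.null(per_um)) return(NULL)
  1 / per_um
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(matrix(as.numeric(mask), nrow = nrow(mask)), path,
                  bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path TIFF path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(m > 0, nrow = nrow(m))
}
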