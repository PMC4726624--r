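#' Overlay the SHG and CARS channels
#'
#' Pixelwise maximum of the two channels. The overlay highlights the specimen
#' support: tissue is bright in at least one of the two signals (collagen in
#' SHG, hepatocyte lipid in CARS), while the slide background is dark in both.
#' The maximum preserves support from either channel without overflowing the
#' integer range the way a sum would.
#'
#' @param img A [mosaic_image].
#' @return Numeric matrix, same dimensions as the channels.
#' @export
overlay_channels <- function(img) {
  stopifnot(inherits(img, "mosaic_image"))
  pmax(img$shg, img$cars)
}

#' Percentile (p-tile) automatic threshold
#'
#' Doyle's p-tile method at p = 0.5: among the occupied histogram bins
#' (distinct pixel values), returns the value `t` minimizing `|F(t) - 0.5|`,
#' where `F(t)` is the cumulative fraction of pixels with value <= `t`. Ties
#' are broken toward the smallest `t`. Pixels strictly greater than `t` are
#' foreground. Because the rule only uses ranks of pixel values, the resulting
#' foreground is invariant under strictly monotone intensity rescaling.
#'
#' @param raster Nonempty numeric matrix or vector.
#' @return The threshold value `t`.
#' @examples
#' percentile_autothreshold(c(rep(0, 50), rep(10, 50)))  # 0
#' @export
percentile_autothreshold <- function(raster) {
  v <- as.numeric(raster)
  if (length(v) == 0) abort("raster must be nonempty")
  tab <- table(v)
  vals <- as.numeric(names(tab))
  cum <- cumsum(as.numeric(tab)) / length(v)
  vals[which.min(abs(cum - 0.5))]
}

#' Circular mean and maximum filters
#'
#' Rank filtering over a disc neighbourhood: a pixel at offset `(dr, dc)`
#' belongs to the kernel iff `dr^2 + dc^2 <= radius_px^2`. At the image edge,
#' out-of-frame coordinates are clamped to the nearest image pixel, so border
#' values are replicated rather than treated as zero (a zero rim would corrupt
#' the low fraction thresholds applied downstream).
#'
#' @param raster Numeric matrix.
#' @param radius_px Kernel radius in pixels (integer >= 1).
#' @return Filtered numeric matrix of the same dimensions.
#' @export
mean_filter <- function(raster, radius_px) {
  check_radius(radius_px)
  disc_mean_cpp(as_num_matrix(raster), as.integer(radius_px))
}

#' @rdname mean_filter
#' @export
max_filter <- function(raster, radius_px) {
  check_radius(radius_px)
  disc_max_cpp(as_num_matrix(raster), as.integer(radius_px))
}

# grayscale erosion: minimum over the disc, via the maximum filter
min_filter <- function(raster, radius_px) {
  -max_filter(-as_num_matrix(raster), radius_px)
}

# shrink a logical mask by a disc of the given pixel radius
erode_mask <- function(mask, radius_px) {
  min_filter(matrix(as.numeric(mask), nrow = nrow(mask)), radius_px) > 0.5
}

check_radius <- function(radius_px) {
  if (length(radius_px) != 1 || is.na(radius_px) || radius_px < 1) {
    abort("radius_px must be a single integer >= 1")
  }
}

as_num_matrix <- function(x) {
  if (!is.matrix(x)) abort("raster must be a matrix")
  if (!is.double(x)) x <- matrix(as.numeric(x), nrow = nrow(x))
  x
}

#' Threshold at a fraction of the representable maximum
#'
#' Foreground pixels are those with value strictly greater than
#' `fraction * M`, where `M` is the representable maximum of the raster's type
#' (255 for 8-bit, 65535 for 16-bit); for float rasters the observed maximum is
#' used. On an 8-bit image a fraction of 0.098 gives a cutoff of 24.99, i.e.
#' integer levels >= 25 are foreground, and 0.0117 gives levels >= 3.
#'
#' @param raster Numeric matrix.
#' @param fraction Fraction in (0, 1).
#' @param max_value Representable maximum `M`; defaults to the observed maximum
#'   (pass 255 for 8-bit semantics).
#' @return Logical matrix (TRUE = foreground).
#' @export
fraction_threshold <- function(raster, fraction, max_value = max(raster)) {
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly between 0 and 1")
  }
  raster > fraction * max_value
}
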