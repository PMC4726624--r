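#' Particle analysis of a binary mask
#'
#' Labels connected foreground components and computes, per particle, its area
#' (pixels and square micrometres), roundness, centroid, and whether it touches
#' the inner boundary band of the sample mask. Roundness follows the
#' equivalent-ellipse convention: `4 * area / (pi * major_axis^2)` with the
#' major axis length taken as `4 * sqrt(lambda_max)` from the component's
#' second-order central moments — 1 for a disc, approximately `b/a` for an
#' ellipse with semi-axes `a > b`.
#'
#' @param mask Logical matrix of foreground pixels.
#' @param pixel_size_um Pixel pitch in micrometres per pixel.
#' @param connectivity 8 (default) or 4.
#' @param sample_mask Optional logical matrix delimiting the specimen; used to
#'   flag particles that touch the specimen border band. When `NULL`, the image
#'   frame border is used instead.
#' @param border_band_um Width of the inner boundary band for border contact,
#'   in micrometres (default 50).
#' @return A tibble with one row per particle: `particle`, `area_px`,
#'   `area_um2`, `roundness`, `centroid_row`, `centroid_col`, `touches_border`.
#'   The integer label matrix is attached as attribute `"labels"` (`particle`
#'   indexes into it).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
#' analyze_particles(m, pixel_size_um = 1)
#' @export
analyze_particles <- function(mask, pixel_size_um, connectivity = 8,
                              sample_mask = NULL, border_band_um = 50) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_components_cpp(mask, as.integer(connectivity))
  n <- attr(lab, "n")
  if (n == 0) {
    out <- tibble::tibble(particle = integer(), area_px = integer(),
                          area_um2 = numeric(), roundness = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          touches_border = logical())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- ((idx - 1) %% nrow(mask)) + 1
  c <- ((idx - 1) %/% nrow(mask)) + 1
  area_px <- tabulate(l, n)
  mr <- rowsum(r, l)[, 1] / area_px
  mc <- rowsum(c, l)[, 1] / area_px
  # second-order central moments -> covariance eigenvalues -> major axis
  dr <- r - mr[l]; dc <- c - mc[l]
  mu20 <- rowsum(dr * dr, l)[, 1] / area_px
  mu02 <- rowsum(dc * dc, l)[, 1] / area_px
  mu11 <- rowsum(dr * dc, l)[, 1] / area_px
  lam_max <- (mu20 + mu02 + sqrt((mu20 - mu02)^2 + 4 * mu11^2)) / 2
  major_px <- 4 * sqrt(lam_max)
  roundness <- ifelse(major_px > 0,
                      pmin(1, 4 * area_px / (pi * major_px^2)), 1)
  band <- border_band(mask, sample_mask, pixel_size_um, border_band_um)
  on_band <- idx %in% which(band)
  touches <- as.logical(rowsum(as.numeric(on_band), l)[, 1] > 0)
  out <- tibble::tibble(
    particle = seq_len(n),
    area_px = as.integer(area_px),
    area_um2 = area_px * pixel_size_um^2,
    roundness = as.numeric(roundness),
    centroid_row = as.numeric(mr),
    centroid_col = as.numeric(mc),
    touches_border = touches
  )
  attr(out, "labels") <- lab
  out
}

# inner boundary band of the sample mask (or of the frame when none given)
border_band <- function(mask, sample_mask, pixel_size_um, border_band_um) {
  band_px <- um_to_px(border_band_um, pixel_size_um)
  if (is.null(sample_mask)) {
    band <- matrix(FALSE, nrow(mask), ncol(mask))
    b <- min(band_px, nrow(mask), ncol(mask))
    band[c(seq_len(b), nrow(mask) - seq_len(b) + 1), ] <- TRUE
    band[, c(seq_len(b), ncol(mask) - seq_len(b) + 1)] <- TRUE
    band
  } else {
    sample_mask & !erode_mask(sample_mask, band_px)
  }
}

# union of the pixels of the given particles, as a logical mask
particle_union <- function(particles, ids) {
  lab <- attr(particles, "labels")
  matrix(lab %in% ids, nrow = nrow(lab))
}
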