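#' Mask pipeline configuration
#'
#' Every numeric parameter of the border- and portal-detection chains, with the
#' published defaults. Radii are physical lengths in micrometres and are
#' converted per image with [um_to_px()].
#'
#' @param border_radii_um Mean/maximum/mean filter radii for specimen-border
#'   detection, in order (default 50, 15, 50).
#' @param border_threshold_fraction Final border threshold as a fraction of the
#'   8-bit maximum (default 0.098, i.e. level 25 of 255).
#' @param portal_radii_um Mean/maximum/mean filter radii for portal/capsule
#'   detection (default 15, 35, 25).
#' @param portal_threshold_fraction Final exclusion threshold fraction
#'   (default 0.0117, i.e. level 3 of 255).
#' @param min_particle_area_um2 Minimum particle area kept for exclusion, in
#'   square micrometres (default 2000). Deliberately permissive: portal tracts
#'   are structures of 50 um and above.
#' @param min_roundness Minimum particle roundness kept for exclusion
#'   (default 0.15).
#' @param connectivity Pixel connectivity for particle analysis (default 8).
#' @param capsule_band_um Width of the inner specimen-border band; any candidate
#'   particle touching it is excluded as capsule regardless of size or
#'   roundness (default 50).
#' @param small_component_fraction Components of the border mask at least this
#'   fraction of the largest one are retained, to support fragmented sections
#'   (default 0.01).
#' @param portal_mean_over Region over which the mean-intensity threshold of the
#'   exclusion chain is computed: `"sample"` (default; the background would drag
#'   a whole-frame mean down arbitrarily with framing) or `"frame"`.
#' @param threshold_max `"type"` (default) to read fraction thresholds against
#'   the representable type maximum, `"observed"` for the observed maximum.
#' @return An object of class `mask_pipeline_config` (a named list).
#' @export
mask_pipeline_config <- function(border_radii_um = c(50, 15, 50),
                                 border_threshold_fraction = 0.098,
                                 portal_radii_um = c(15, 35, 25),
                                 portal_threshold_fraction = 0.0117,
                                 min_particle_area_um2 = 2000,
                                 min_roundness = 0.15,
                                 connectivity = 8,
                                 capsule_band_um = 50,
                                 small_component_fraction = 0.01,
                                 portal_mean_over = c("sample", "frame"),
                                 threshold_max = c("type", "observed")) {
  cfg <- list(
    border_radii_um = border_radii_um,
    border_threshold_fraction = border_threshold_fraction,
    portal_radii_um = portal_radii_um,
    portal_threshold_fraction = portal_threshold_fraction,
    min_particle_area_um2 = min_particle_area_um2,
    min_roundness = min_roundness,
    connectivity = connectivity,
    capsule_band_um = capsule_band_um,
    small_component_fraction = small_component_fraction,
    portal_mean_over = match.arg(portal_mean_over),
    threshold_max = match.arg(threshold_max)
  )
  if (length(cfg$border_radii_um) != 3 || length(cfg$portal_radii_um) != 3 ||
      any(c(cfg$border_radii_um, cfg$portal_radii_um) <= 0)) {
    abort("radii must be three positive lengths each")
  }
  for (f in c(cfg$border_threshold_fraction, cfg$portal_threshold_fraction)) {
    if (f <= 0 || f >= 1) abort("threshold fractions must lie in (0, 1)")
  }
  if (cfg$min_roundness < 0 || cfg$min_roundness > 1) {
    abort("min_roundness must lie in [0, 1]")
  }
  if (!cfg$connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  structure(cfg, class = "mask_pipeline_config")
}

# the shared mean -> maximum -> mean smoothing chain on a 0/255 raster
filter_chain <- function(raster, radii_um, pixel_size_um) {
  r <- um_to_px(radii_um, pixel_size_um)
  raster |>
    mean_filter(r[1]) |>
    max_filter(r[2]) |>
    mean_filter(r[3])
}

#' Detect the specimen area
#'
#' Border detection from the SHG+CARS overlay: percentile auto-threshold, 0/255
#' binary mask, circular mean/maximum/mean filtering (50/15/50 um), and a final
#' threshold at 9.8% of the 8-bit maximum. The largest connected foreground
#' component is kept, together with any component of at least
#' `small_component_fraction` of its area (fragmented sections).
#'
#' @param img A [mosaic_image].
#' @param cfg A [mask_pipeline_config].
#' @return Logical sample mask.
#' @export
detect_sample_area <- function(img, cfg = mask_pipeline_config()) {
  stopifnot(inherits(img, "mosaic_image"))
  ov <- overlay_channels(img)
  t0 <- percentile_autothreshold(ov)
  bin <- matrix(255 * as.numeric(ov > t0), nrow = nrow(ov))
  sm <- filter_chain(bin, cfg$border_radii_um, img$pixel_size_um)
  mx <- if (cfg$threshold_max == "type") 255 else max(sm)
  fg <- fraction_threshold(sm, cfg$border_threshold_fraction, mx)
  if (!any(fg)) abort("no tissue detected")
  lab <- label_components_cpp(fg, as.integer(cfg$connectivity))
  sizes <- tabulate(lab[lab > 0], attr(lab, "n"))
  keep <- which(sizes >= cfg$small_component_fraction * max(sizes))
  matrix(lab %in% keep, nrow = nrow(fg))
}

#' Detect portal areas and the capsule for exclusion
#'
#' Exclusion-mask detection from the SHG channel: pixels above the mean SHG
#' intensity over the sample area are taken as candidate collagen-rich
#' foreground, smoothed with the 15/35/25 um mean/maximum/mean chain to
#' harmonize the fibrillar texture, thresholded at 1.17% of the 8-bit maximum,
#' and submitted to particle analysis. Particles are retained for exclusion
#' when they are both large (`area_um2 >= min_particle_area_um2`) and compact
#' (`roundness >= min_roundness`) — portal areas — or when they touch the inner
#' specimen-border band — the capsule, a bright SHG band at the specimen edge,
#' regardless of size or shape. The union of retained particles, clipped to the
#' sample mask, is the excluded mask.
#'
#' @param img A [mosaic_image].
#' @param sample Logical sample mask from [detect_sample_area()].
#' @param cfg A [mask_pipeline_config].
#' @return A list with `excluded` (logical mask) and `particles` (tibble from
#'   [analyze_particles()] plus a `retained` column).
#' @export
detect_excluded_regions <- function(img, sample, cfg = mask_pipeline_config()) {
  stopifnot(inherits(img, "mosaic_image"), is.logical(sample))
  shg <- img$shg
  ref <- if (cfg$portal_mean_over == "sample") shg[sample] else shg
  m <- mean(ref)
  bin <- matrix(255 * as.numeric(shg > m), nrow = nrow(shg))
  sm <- filter_chain(bin, cfg$portal_radii_um, img$pixel_size_um)
  mx <- if (cfg$threshold_max == "type") 255 else max(sm)
  fg <- fraction_threshold(sm, cfg$portal_threshold_fraction, mx)
  particles <- analyze_particles(fg, img$pixel_size_um,
                                 connectivity = cfg$connectivity,
                                 sample_mask = sample,
                                 border_band_um = cfg$capsule_band_um)
  retained <- (particles$area_um2 >= cfg$min_particle_area_um2 &
                 particles$roundness >= cfg$min_roundness) |
    particles$touches_border
  particles$retained <- retained
  excluded <- particle_union(particles, particles$particle[retained]) & sample
  list(excluded = excluded, particles = particles)
}

#' Segment a mosaic into sample, excluded and parenchyma masks
#'
#' Runs border detection and portal/capsule exclusion, and derives the
#' parenchyma mask as sample AND NOT excluded.
#'
#' @param img A [mosaic_image].
#' @param cfg A [mask_pipeline_config].
#' @return An object of class `shg_segmentation`: list with logical masks
#'   `sample`, `excluded`, `parenchyma`, and the particle tibble `particles`.
#' @export
segment_mosaic <- function(img, cfg = mask_pipeline_config()) {
  sample <- detect_sample_area(img, cfg)
  ex <- detect_excluded_regions(img, sample, cfg)
  structure(
    list(sample = sample, excluded = ex$excluded,
         parenchyma = sample & !ex$excluded, particles = ex$particles,
         pixel_size_um = img$pixel_size_um),
    class = "shg_segmentation"
  )
}

#' @export
print.shg_segmentation <- function(x, ...) {
  a <- x$pixel_size_um^2 / 1e6
  cat(sprintf(
    "<shg_segmentation> sample %.3f mm^2, excluded %.3f mm^2, parenchyma %.3f mm^2\n",
    sum(x$sample) * a, sum(x$excluded) * a, sum(x$parenchyma) * a))
  cat(sprintf("  %d particle(s), %d retained for exclusion\n",
              nrow(x$particles), sum(x$particles$retained)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a segmentation's particle table
#' @param x An `shg_segmentation`.
#' @param ... Unused.
#' @return The particle tibble (one row per candidate particle).
#' @export
tidy.shg_segmentation <- function(x, ...) {
  out <- x$particles
  attr(out, "labels") <- NULL
  out
}

#' Plot a segmentation as a mask map
#'
#' Downsampled raster map of background, parenchyma and excluded regions.
#'
#' @param object An `shg_segmentation`.
#' @param max_px Largest plotted side length in pixels (default 512).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.shg_segmentation <- function(object, max_px = 512, ...) {
  step <- max(1L, ceiling(max(dim(object$sample)) / max_px))
  rows <- seq(1, nrow(object$sample), by = step)
  cols <- seq(1, ncol(object$sample), by = step)
  lab <- matrix("background", length(rows), length(cols))
  lab[object$sample[rows, cols]] <- "parenchyma"
  lab[object$excluded[rows, cols]] <- "excluded"
  df <- tidyr::expand_grid(col = cols, row = rows)  # row varies fastest,
  df$region <- as.vector(lab)                       # matching column-major lab
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          parenchyma = "grey70",
                                          excluded = "seagreen3")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
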