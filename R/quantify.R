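#' Estimate per-channel background outside the specimen
#'
#' Background is the mean signal intensity outside the sample mask, estimated
#' per channel from the same outside-sample region.
#'
#' @param img A [mosaic_image].
#' @param sample Logical sample mask.
#' @return Named list `background_shg`, `background_cars`.
#' @export
estimate_background <- function(img, sample) {
  stopifnot(inherits(img, "mosaic_image"), is.logical(sample))
  outside <- !sample
  if (!any(outside)) abort("sample mask covers the full frame: no background region")
  list(background_shg = mean(img$shg[outside]),
       background_cars = mean(img$cars[outside]))
}

#' Quantify background-subtracted parenchymal intensities
#'
#' The per-biopsy score: mean SHG and CARS intensities over the parenchyma
#' (sample minus capsule and portal areas) after subtracting the background
#' estimated outside the specimen, clamped at zero. The fold-over-background
#' statistic divides the raw (pre-subtraction) parenchymal SHG mean by the SHG
#' background; both the raw and subtracted means are reported.
#'
#' @param img A [mosaic_image].
#' @param seg An `shg_segmentation` from [segment_mosaic()], or any list with
#'   logical `sample`, `excluded`, `parenchyma` masks.
#' @return An object of class `shg_quant`: list with `background_shg`,
#'   `background_cars`, `mean_shg_raw`, `mean_cars_raw`, `mean_shg`,
#'   `mean_cars`, `fold_over_background`, `sample_area_um2`,
#'   `excluded_area_um2`, `parenchyma_fraction`.
#' @export
quantify <- function(img, seg) {
  stopifnot(inherits(img, "mosaic_image"))
  if (!all(c("sample", "excluded", "parenchyma") %in% names(seg))) {
    abort("seg must provide sample, excluded and parenchyma masks")
  }
  if (!identical(dim(seg$sample), dim(img$shg))) {
    abort("segmentation masks do not match the image dimensions")
  }
  if (!any(seg$parenchyma)) abort("no parenchyma to quantify")
  bg <- estimate_background(img, seg$sample)
  raw_shg <- mean(img$shg[seg$parenchyma])
  raw_cars <- mean(img$cars[seg$parenchyma])
  px2 <- img$pixel_size_um^2
  structure(
    list(
      background_shg = bg$background_shg,
      background_cars = bg$background_cars,
      mean_shg_raw = raw_shg,
      mean_cars_raw = raw_cars,
      mean_shg = max(0, raw_shg - bg$background_shg),
      mean_cars = max(0, raw_cars - bg$background_cars),
      fold_over_background =
        if (bg$background_shg > 0) raw_shg / bg$background_shg else NaN,
      sample_area_um2 = sum(seg$sample) * px2,
      excluded_area_um2 = sum(seg$excluded) * px2,
      parenchyma_fraction = sum(seg$parenchyma) / sum(seg$sample)
    ),
    class = "shg_quant"
  )
}

#' Segment and quantify a mosaic in one call
#'
#' @param img A [mosaic_image].
#' @param cfg A [mask_pipeline_config].
#' @return An `shg_quant` (the segmentation is attached as attribute
#'   `"segmentation"`).
#' @export
quantify_mosaic <- function(img, cfg = mask_pipeline_config()) {
  seg <- segment_mosaic(img, cfg)
  q <- quantify(img, seg)
  attr(q, "segmentation") <- seg
  q
}

#' @export
print.shg_quant <- function(x, ...) {
  cat("<shg_quant>\n")
  cat(sprintf("  mean SHG  %8.3f  (raw %.3f, background %.3f)\n",
              x$mean_shg, x$mean_shg_raw, x$background_shg))
  cat(sprintf("  mean CARS %8.3f  (raw %.3f, background %.3f)\n",
              x$mean_cars, x$mean_cars_raw, x$background_cars))
  cat(sprintf("  fold over background %.2f\n", x$fold_over_background))
  cat(sprintf("  sample %.3f mm^2, excluded %.3f mm^2, parenchyma fraction %.3f\n",
              x$sample_area_um2 / 1e6, x$excluded_area_um2 / 1e6,
              x$parenchyma_fraction))
  invisible(x)
}

#' Tidy a quantification result into a one-row tibble
#' @param x An `shg_quant`.
#' @param ... Unused.
#' @return One-row tibble with all quantification fields.
#' @export
tidy.shg_quant <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a quantification result
#' @param x An `shg_quant`.
#' @param ... Unused.
#' @return One-row tibble (same as [tidy.shg_quant()]).
#' @export
glance.shg_quant <- function(x, ...) tidy.shg_quant(x)
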