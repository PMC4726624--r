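#' Specification of a synthetic biopsy phantom
#'
#' Generative parameters for a two-channel liver-biopsy phantom emulating a
#' stitched ~4 x 4 mm mosaic: a smooth tissue blob, a bright collagen capsule
#' band along its border, bright roundish portal areas inside, weak wavy
#' parenchymal fibrils of 20-200 um length (some bridging between portal
#' areas), a moderate hepatocyte CARS signal, and bright CARS lipid droplets.
#' Densities scale with the fibrosis stage (fibrils) and steatosis grade
#' (droplets) unless given explicitly.
#'
#' @param stage Fibrosis stage, integer 0-4.
#' @param steatosis_grade Steatosis grade, integer 0-3.
#' @param frame_px Frame size `(rows, cols)`; default 2048 x 2048.
#' @param pixel_size_um Pixel pitch; default 2 um/px (~4.1 x 4.1 mm frame).
#' @param fibril_density Fibrils per mm^2 of tissue; default scales with stage
#'   (10, 40, 90, 160, 250 for stages 0-4).
#' @param fibril_length_range_um Fibril length range; default (20, 200).
#' @param fibril_intensity Mean SHG amplitude of fibrils (default 12, more than
#'   an order of magnitude dimmer than portal/capsule collagen; chosen so the
#'   full jittered fibril amplitude plus noise stays below the sample-mean
#'   exclusion threshold, letting parenchymal fibrils survive the exclusion
#'   step as they do in real biopsies).
#' @param portal_count Number of portal areas; default `5 + stage`.
#' @param portal_intensity Mean SHG amplitude of portal areas and capsule
#'   (default 400).
#' @param portal_diameter_range_um Portal blob diameter range; default
#'   (100, 400).
#' @param capsule_thickness_um Capsule band thickness; default 60. Zero
#'   suppresses the capsule.
#' @param droplet_density Lipid droplets per mm^2 of tissue; default scales
#'   with steatosis grade (0, 25, 60, 120 for grades 0-3).
#' @param droplet_radius_range_um Droplet radius range; default (5, 25).
#' @param droplet_intensity Mean CARS amplitude of droplets (default 150).
#' @param cars_tissue_intensity Mean hepatocyte CARS amplitude (default 50).
#' @param noise_mean,noise_sd Background noise model: Gaussian with the given
#'   mean and sd, clipped at zero (detector counts are nonnegative).
#' @param tissue_coverage Fraction of the frame covered by tissue; default
#'   drawn uniformly in (0.55, 0.70) per phantom.
#' @param bridging_fraction Fraction of fibrils seeded at a portal area and
#'   headed toward another (default 0.25).
#' @param seed RNG seed; the phantom is fully reproducible from the spec.
#' @return An object of class `phantom_spec` (a named list).
#' @export
phantom_spec <- function(stage = 0, steatosis_grade = 0,
                         frame_px = c(2048, 2048), pixel_size_um = 2,
                         fibril_density = NULL,
                         fibril_length_range_um = c(20, 200),
                         fibril_intensity = 12,
                         portal_count = NULL,
                         portal_intensity = 400,
                         portal_diameter_range_um = c(100, 400),
                         capsule_thickness_um = 60,
                         droplet_density = NULL,
                         droplet_radius_range_um = c(5, 25),
                         droplet_intensity = 150,
                         cars_tissue_intensity = 50,
                         noise_mean = 8, noise_sd = 3,
                         tissue_coverage = NULL,
                         bridging_fraction = 0.25,
                         seed = 1) {
  if (!stage %in% 0:4) abort("stage must be an integer 0-4")
  if (!steatosis_grade %in% 0:3) abort("steatosis_grade must be an integer 0-3")
  fibril_density <- fibril_density %||% c(10, 40, 90, 160, 250)[stage + 1]
  droplet_density <- droplet_density %||% c(0, 25, 60, 120)[steatosis_grade + 1]
  portal_count <- portal_count %||% (5 + stage)
  spec <- list(stage = as.integer(stage),
               steatosis_grade = as.integer(steatosis_grade),
               frame_px = as.integer(frame_px),
               pixel_size_um = pixel_size_um,
               fibril_density = fibril_density,
               fibril_length_range_um = fibril_length_range_um,
               fibril_intensity = fibril_intensity,
               portal_count = as.integer(portal_count),
               portal_intensity = portal_intensity,
               portal_diameter_range_um = portal_diameter_range_um,
               capsule_thickness_um = capsule_thickness_um,
               droplet_density = droplet_density,
               droplet_radius_range_um = droplet_radius_range_um,
               droplet_intensity = droplet_intensity,
               cars_tissue_intensity = cars_tissue_intensity,
               noise_mean = noise_mean, noise_sd = noise_sd,
               tissue_coverage = tissue_coverage,
               bridging_fraction = bridging_fraction,
               seed = as.integer(seed))
  with(spec, {
    if (fibril_density < 0 || droplet_density < 0 || portal_count < 0 ||
        capsule_thickness_um < 0 || fibril_intensity < 0)
      abort("densities, counts, intensities and thicknesses must be >= 0")
    if (any(fibril_length_range_um <= 0) ||
        fibril_length_range_um[1] > fibril_length_range_um[2])
      abort("fibril_length_range_um must be positive with min <= max")
  })
  structure(spec, class = "phantom_spec")
}

# linear indices of a filled (possibly rotated) ellipse, clipped to the frame
ellipse_idx <- function(H, W, cr, cc, a_px, b_px, angle) {
  r0 <- max(1L, floor(cr - a_px)); r1 <- min(H, ceiling(cr + a_px))
  c0 <- max(1L, floor(cc - a_px)); c1 <- min(W, ceiling(cc + a_px))
  if (r0 > r1 || c0 > c1) return(integer())
  rr <- r0:r1; cc2 <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cc2)))
  dc <- outer(rep(1, length(rr)), cc2 - cc)
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  (rep(cc2, each = length(rr))[inside] - 1L) * H + rep(rr, length(cc2))[inside]
}

#' Generate a synthetic biopsy phantom with ground truth
#'
#' Renders the morphology described by the spec into a 16-bit two-channel
#' mosaic plus the true masks that produced it. Fully deterministic given the
#' spec (including its seed); the caller's RNG state is left untouched.
#'
#' @param spec A [phantom_spec].
#' @return A list with `image` (a [mosaic_image]) and `truth` (list of logical
#'   masks `tissue`, `portal`, `capsule`, `fibril`, `droplet` and scalars
#'   `true_fibril_area_fraction`, `true_droplet_area_fraction`), and `spec`
#'   (the spec with the realized tissue coverage filled in).
#' @examples
#' p <- generate_phantom(phantom_spec(stage = 1, frame_px = c(128, 128),
#'                                    pixel_size_um = 16, seed = 1))
#' p$truth$true_fibril_area_fraction
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  H <- spec$frame_px[1]; W <- spec$frame_px[2]
  pitch <- spec$pixel_size_um
  px2_mm2 <- pitch^2 / 1e6

  ## tissue blob: radial Fourier perturbation of a disc
  coverage <- spec$tissue_coverage %||% runif(1, 0.55, 0.70)
  cy <- H / 2; cx <- W / 2
  R0 <- sqrt(coverage * H * W / pi)
  k <- 2:6
  amp <- rnorm(length(k), 0, 0.035)
  phi <- runif(length(k), 0, 2 * pi)
  dr <- matrix(seq_len(H) - cy, H, W)
  dc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  theta <- atan2(dr, dc)
  rad <- R0 * (1 + Reduce(`+`, lapply(seq_along(k), function(i)
    amp[i] * cos(k[i] * theta + phi[i]))))
  rad <- pmin(rad, 0.49 * min(H, W))
  tissue <- sqrt(dr^2 + dc^2) <= rad
  tissue_px <- sum(tissue)

  ## capsule: inner band along the tissue boundary
  if (spec$capsule_thickness_um > 0) {
    capsule <- tissue & !erode_mask(tissue, um_to_px(spec$capsule_thickness_um, pitch))
  } else {
    capsule <- matrix(FALSE, H, W)
  }

  ## portal areas: roundish bright blobs well inside the tissue
  portal <- matrix(FALSE, H, W)
  centers <- NULL
  if (spec$portal_count > 0) {
    max_r_um <- spec$portal_diameter_range_um[2] / 2
    margin_px <- um_to_px(spec$capsule_thickness_um + max_r_um + 40, pitch)
    interior <- erode_mask(tissue, margin_px)
    if (!any(interior)) interior <- tissue & !capsule
    pool <- which(interior)
    pick <- pool[sample.int(length(pool), spec$portal_count,
                            replace = length(pool) < spec$portal_count)]
    pr <- ((pick - 1) %% H) + 1
    pc <- ((pick - 1) %/% H) + 1
    centers <- cbind(pr, pc)
    idx <- lapply(seq_len(spec$portal_count), function(i) {
      d_um <- runif(1, spec$portal_diameter_range_um[1], spec$portal_diameter_range_um[2])
      a <- (d_um / 2) / pitch
      b <- a * runif(1, 0.75, 1)
      ellipse_idx(H, W, pr[i], pc[i], a, b, runif(1, 0, pi))
    })
    portal[unlist(idx)] <- TRUE
    portal <- portal & tissue & !capsule
  }

  ## overflow guard: generative structures must fit the tissue area
  area_mm2 <- tissue_px * px2_mm2
  n_fib <- round(spec$fibril_density * area_mm2)
  n_drop <- round(spec$droplet_density * area_mm2)
  mean_len_px <- mean(spec$fibril_length_range_um) / pitch
  mean_drop_px <- pi * (mean(spec$droplet_radius_range_um) / pitch)^2
  if (n_fib * mean_len_px > 0.8 * tissue_px ||
      n_drop * mean_drop_px > 0.8 * tissue_px) {
    abort("generative densities overflow the tissue area")
  }

  ## fibrils: wavy random-walk polylines, some bridging between portal areas
  fibril <- matrix(FALSE, H, W)
  fibril_amp <- matrix(0, H, W)
  if (n_fib > 0) {
    parenchyma_pool <- which(tissue & !capsule & !portal)
    for (i in seq_len(n_fib)) {
      len_um <- runif(1, spec$fibril_length_range_um[1], spec$fibril_length_range_um[2])
      n_s <- max(2L, as.integer(round(len_um / pitch)))
      if (!is.null(centers) && nrow(centers) >= 2 &&
          runif(1) < spec$bridging_fraction) {
        ij <- sample.int(nrow(centers), 2)
        start <- centers[ij[1], ] + rnorm(2, 0, 2)
        th0 <- atan2(centers[ij[2], 1] - start[1], centers[ij[2], 2] - start[2])
      } else {
        s <- parenchyma_pool[sample.int(length(parenchyma_pool), 1)]
        start <- c(((s - 1) %% H) + 1, ((s - 1) %/% H) + 1)
        th0 <- runif(1, 0, 2 * pi)
      }
      th <- th0 + cumsum(rnorm(n_s, 0, 0.12))
      rr <- round(start[1] + cumsum(sin(th)))
      cc <- round(start[2] + cumsum(cos(th)))
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (!any(ok)) next
      idx <- unique(cbind(rr[ok], cc[ok]) %*% c(1, H) - H)  # (r, c) -> linear
      idx <- idx[tissue[idx] & !portal[idx] & !capsule[idx]]
      if (length(idx) == 0) next
      fibril[idx] <- TRUE
      fibril_amp[idx] <- spec$fibril_intensity * runif(1, 0.7, 1.3)
    }
  }

  ## lipid droplets: bright CARS discs inside the tissue
  droplet <- matrix(FALSE, H, W)
  if (n_drop > 0) {
    pool <- which(tissue & !capsule)
    pick <- pool[sample.int(length(pool), n_drop, replace = length(pool) < n_drop)]
    pr <- ((pick - 1) %% H) + 1
    pc <- ((pick - 1) %/% H) + 1
    idx <- lapply(seq_len(n_drop), function(i) {
      r_px <- max(1, runif(1, spec$droplet_radius_range_um[1],
                           spec$droplet_radius_range_um[2]) / pitch)
      ellipse_idx(H, W, pr[i], pc[i], r_px, r_px, 0)
    })
    droplet[unlist(idx)] <- TRUE
    droplet <- droplet & tissue
  }

  ## render channels: nonnegative noise plus the structures
  n_px <- H * W
  shg <- matrix(pmax(0, rnorm(n_px, spec$noise_mean, spec$noise_sd)), H, W)
  bright <- portal | capsule
  shg[bright] <- shg[bright] + spec$portal_intensity * runif(sum(bright), 0.8, 1.2)
  shg <- shg + fibril_amp
  cars <- matrix(pmax(0, rnorm(n_px, spec$noise_mean, spec$noise_sd)), H, W)
  hep <- tissue & !portal
  cars[hep] <- cars[hep] + spec$cars_tissue_intensity * runif(sum(hep), 0.9, 1.1)
  cars[droplet] <- cars[droplet] + spec$droplet_intensity * runif(sum(droplet), 0.8, 1.2)
  shg <- matrix(pmin(65535, round(shg)), H, W)
  cars <- matrix(pmin(65535, round(cars)), H, W)

  spec$tissue_coverage <- coverage
  list(
    image = mosaic_image(shg, cars, pixel_size_um = pitch, bit_depth = 16),
    truth = list(
      tissue = tissue, portal = portal, capsule = capsule,
      fibril = fibril, droplet = droplet,
      true_fibril_area_fraction = sum(fibril) / max(1, tissue_px),
      true_droplet_area_fraction = sum(droplet) / max(1, tissue_px)
    ),
    spec = spec
  )
}

#' Generate a staged phantom cohort
#'
#' Deterministically derives one phantom spec per sample from a master seed:
#' stages 0-4 each represented `n_per_stage` times, steatosis grades cycling
#' 0-3, and per-sample multiplicative jitter (0.85-1.15) on the fibril and
#' droplet densities so intensity scores vary continuously within stages.
#'
#' @param n_per_stage Samples per fibrosis stage (>= 1).
#' @param base_spec A [phantom_spec] providing the shared geometry; defaults to
#'   a 1024 x 1024 frame at 4 um/px (the same ~4.1 x 4.1 mm field as the full
#'   resolution default, at cohort-evaluation scale).
#' @param seed Master seed.
#' @return A tibble with one row per phantom: `sample_id`, `stage`,
#'   `steatosis_grade`, `fibril_density`, `droplet_density`, `seed`, and
#'   list-columns `spec`, `image`, `truth`.
#' @export
generate_cohort <- function(n_per_stage, base_spec = NULL, seed = 1) {
  if (n_per_stage < 1) abort("n_per_stage must be >= 1")
  base_spec <- base_spec %||%
    phantom_spec(frame_px = c(1024, 1024), pixel_size_um = 4)
  stages <- rep(0:4, each = n_per_stage)
  n <- length(stages)
  plan <- withr::with_seed(seed, {
    tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      stage = stages,
      steatosis_grade = rep_len(rep(0:3, length.out = max(4, n_per_stage * 5)), n),
      fibril_jitter = runif(n, 0.85, 1.15),
      droplet_jitter = runif(n, 0.85, 1.15),
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  plan$spec <- purrr::pmap(plan, function(stage, steatosis_grade, fibril_jitter,
                                          droplet_jitter, seed, ...) {
    s <- base_spec
    s$stage <- as.integer(stage)
    s$steatosis_grade <- as.integer(steatosis_grade)
    s$fibril_density <- c(10, 40, 90, 160, 250)[stage + 1] * fibril_jitter
    s$droplet_density <- c(0, 25, 60, 120)[steatosis_grade + 1] * droplet_jitter
    s$portal_count <- 5L + as.integer(stage)
    s$seed <- seed
    s
  })
  out <- dplyr::select(plan, -"fibril_jitter", -"droplet_jitter")
  gen <- purrr::map(out$spec, generate_phantom)
  out$fibril_density <- purrr::map_dbl(out$spec, "fibril_density")
  out$droplet_density <- purrr::map_dbl(out$spec, "droplet_density")
  out$image <- purrr::map(gen, "image")
  out$truth <- purrr::map(gen, "truth")
  out
}

#' Segmentation accuracy against phantom ground truth
#'
#' @param seg An `shg_segmentation`.
#' @param truth Ground-truth list from [generate_phantom()].
#' @return One-row tibble: `tissue_recall` (fraction of true tissue pixels in
#'   the sample mask), `background_false_inclusion` (fraction of true
#'   background pixels in the sample mask), `excluded_iou`
#'   (intersection-over-union of the excluded mask against true portal plus
#'   capsule).
#' @export
evaluate_segmentation <- function(seg, truth) {
  ex_true <- truth$portal | truth$capsule
  inter <- sum(seg$excluded & ex_true)
  uni <- sum(seg$excluded | ex_true)
  tibble::tibble(
    tissue_recall = sum(seg$sample & truth$tissue) / sum(truth$tissue),
    background_false_inclusion = sum(seg$sample & !truth$tissue) / sum(!truth$tissue),
    excluded_iou = if (uni > 0) inter / uni else NA_real_
  )
}
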