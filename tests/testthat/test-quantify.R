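# a hand-built 20x20 scene: sample square with known parenchymal and
# background levels, a small excluded patch
toy_scene <- function(shg_par = 40, bg = 8, cars_par = 30) {
  H <- 20
  sample <- matrix(FALSE, H, H); sample[5:16, 5:16] <- TRUE
  excluded <- matrix(FALSE, H, H); excluded[5:8, 5:8] <- TRUE
  shg <- matrix(bg, H, H); shg[sample] <- shg_par; shg[excluded] <- 200
  cars <- matrix(bg, H, H); cars[sample] <- cars_par
  img <- mosaic_image(shg, cars, pixel_size_um = 2, bit_depth = 16)
  list(img = img,
       seg = list(sample = sample, excluded = excluded,
                  parenchyma = sample & !excluded))
}

test_that("quantify computes background-subtracted means and fold exactly", {
  s <- toy_scene(shg_par = 40, bg = 8)
  q <- quantify(s$img, s$seg)
  expect_equal(q$background_shg, 8)
  expect_equal(q$mean_shg, 32)
  expect_equal(q$fold_over_background, 5.0)
  expect_equal(q$sample_area_um2, sum(s$seg$sample) * 4)
  expect_equal(q$parenchyma_fraction,
               sum(s$seg$parenchyma) / sum(s$seg$sample))
  expect_equal(nrow(tidy(q)), 1)
})

test_that("zero SHG gives zero mean and an undefined fold", {
  s <- toy_scene()
  s$img <- mosaic_image(matrix(0, 20, 20), s$img$cars, 2, bit_depth = 16)
  q <- quantify(s$img, s$seg)
  expect_equal(q$mean_shg, 0)
  expect_true(is.nan(q$fold_over_background))
})

test_that("degenerate masks raise informative errors", {
  s <- toy_scene()
  expect_error(estimate_background(s$img, matrix(TRUE, 20, 20)), "full frame")
  empty_par <- list(sample = s$seg$sample, excluded = s$seg$sample,
                    parenchyma = s$seg$sample & FALSE)
  expect_error(quantify(s$img, empty_par), "no parenchyma")
})

test_that("quantification ignores intensity inside excluded regions", {
  s <- toy_scene()
  q1 <- quantify(s$img, s$seg)
  s$img$shg[s$seg$excluded] <- 9999
  q2 <- quantify(s$img, s$seg)
  expect_identical(q1$mean_shg, q2$mean_shg)
  expect_identical(q1$mean_cars, q2$mean_cars)
})

test_that("adding a constant offset cancels in the background subtraction", {
  s <- toy_scene()
  q1 <- quantify(s$img, s$seg)
  img2 <- mosaic_image(s$img$shg + 17, s$img$cars + 17, 2, bit_depth = 16)
  q2 <- quantify(img2, s$seg)
  expect_equal(q1$mean_shg, q2$mean_shg)
  expect_equal(q1$mean_cars, q2$mean_cars)
})

test_that("background estimation is unbiased on noisy frames", {
  withr::local_seed(99)
  H <- 150  # >= 10^4 background pixels
  sample <- matrix(FALSE, H, H); sample[40:110, 40:110] <- TRUE
  shg <- matrix(pmax(0, rnorm(H * H, 10, 3)), H, H)
  img <- mosaic_image(shg, shg, 1, bit_depth = 32)
  bg <- estimate_background(img, sample)
  se <- 3 / sqrt(sum(!sample))
  expect_lt(abs(bg$background_shg - 10), 3 * se + 0.01)  # clipping bias is tiny
})

test_that("structure-free phantoms quantify to baseline levels", {
  spec <- test_spec(stage = 0, seed = 8, fibril_density = 0, portal_count = 0,
                    droplet_density = 0)
  p <- generate_phantom(spec)
  q <- quantify_mosaic(p$image)
  n <- sum(attr(q, "segmentation")$parenchyma)
  se <- 3 * sqrt(1 / n + 1 / (512^2 - sum(attr(q, "segmentation")$sample)))
  expect_lte(q$mean_shg, 3 * se + 0.05)
  # CARS stays at the generative hepatocyte level once background is removed
  expect_equal(q$mean_cars, 50, tolerance = 0.05)
})
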