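test_that("sample detection recovers phantom tissue with high recall", {
  p <- cached_phantom(stage = 1, seed = 1)
  seg <- segment_mosaic(p$image)
  ev <- evaluate_segmentation(seg, p$truth)
  expect_gte(ev$tissue_recall, 0.95)
  # masks are mutually consistent
  expect_false(any(seg$excluded & !seg$sample))
  expect_identical(seg$parenchyma, seg$sample & !seg$excluded)
  expect_equal(sum(seg$sample), sum(seg$parenchyma) + sum(seg$excluded))
})

test_that("near-empty images raise a no-tissue error", {
  spec <- test_spec(stage = 0, seed = 2, frame = 256, pitch = 16,
                    fibril_density = 0, portal_count = 0,
                    capsule_thickness_um = 0, cars_tissue_intensity = 0,
                    portal_intensity = 0, droplet_density = 0,
                    noise_mean = 0.05, noise_sd = 0.05)
  p <- generate_phantom(spec)
  expect_error(detect_sample_area(p$image), "no tissue")
})

test_that("a frame fully covered by tissue yields a near-full sample mask", {
  withr::local_seed(31)
  H <- 256
  cars <- matrix(round(pmax(0, rnorm(H * H, 60, 5))), H, H)
  shg <- matrix(round(pmax(0, rnorm(H * H, 10, 3))), H, H)
  img <- mosaic_image(shg, cars, pixel_size_um = 16, bit_depth = 16)
  sam <- detect_sample_area(img)
  expect_gte(mean(sam), 0.99)
})

test_that("segmentation is deterministic", {
  p <- cached_phantom(stage = 2, seed = 4, frame = 256, pitch = 16)
  s1 <- segment_mosaic(p$image)
  s2 <- segment_mosaic(p$image)
  expect_identical(s1$sample, s2$sample)
  expect_identical(s1$excluded, s2$excluded)
  expect_identical(tidy(s1), tidy(s2))
})

test_that("raising the particle size filter never grows the excluded mask", {
  p <- cached_phantom(stage = 2, seed = 5)
  sam <- detect_sample_area(p$image)
  areas <- c(2000, 20000, 100000, 1e6)
  px <- vapply(areas, function(a) {
    cfg <- mask_pipeline_config(min_particle_area_um2 = a)
    sum(detect_excluded_regions(p$image, sam, cfg)$excluded)
  }, numeric(1))
  expect_true(all(diff(px) <= 0))
})

test_that("with bright portal/capsule present, exclusion leaves most parenchyma", {
  # the mean-intensity threshold of the exclusion chain presumes bright
  # collagen-rich regions raising the sample mean above the parenchymal level;
  # with them present, candidate pixels are confined to portal/capsule and the
  # parenchyma (dim fibrils included) survives for quantification
  p <- cached_phantom(stage = 0, seed = 6)
  seg <- segment_mosaic(p$image)
  expect_gte(sum(seg$parenchyma) / sum(seg$sample), 0.6)
  truth_ex <- p$truth$portal | p$truth$capsule
  expect_gte(sum(seg$excluded & truth_ex) / sum(truth_ex), 0.95)
})

test_that("an all-zero SHG channel excludes nothing", {
  p <- cached_phantom(stage = 1, seed = 7, frame = 256, pitch = 16)
  img <- mosaic_image(matrix(0, 256, 256), p$image$cars, 16, bit_depth = 16)
  sam <- detect_sample_area(img)
  ex <- detect_excluded_regions(img, sam)
  expect_false(any(ex$excluded))
  expect_equal(nrow(ex$particles), 0)
})

test_that("exclusion finds the bright portal areas and capsule", {
  p <- cached_phantom(stage = 1, seed = 1)
  seg <- segment_mosaic(p$image)
  truth_ex <- p$truth$portal | p$truth$capsule
  # the excluded mask must cover nearly all truly collagen-rich pixels ...
  expect_gte(sum(seg$excluded & truth_ex) / sum(truth_ex), 0.95)
  # ... and none of the fibrils far from them should disappear wholesale
  expect_gte(sum(p$truth$fibril & seg$parenchyma) / sum(p$truth$fibril), 0.5)
})

test_that("pipeline config validates its fields", {
  expect_error(mask_pipeline_config(border_radii_um = c(50, 15)), "three")
  expect_error(mask_pipeline_config(border_threshold_fraction = 1.2), "\\(0, 1\\)")
  expect_error(mask_pipeline_config(min_roundness = 2), "0, 1")
  expect_error(mask_pipeline_config(connectivity = 6), "4 or 8")
})
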