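test_that("phantom generation is bit-reproducible from its seed", {
  spec <- test_spec(stage = 2, seed = 12, frame = 256, pitch = 16)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image$shg, p2$image$shg)
  expect_identical(p1$image$cars, p2$image$cars)
  expect_identical(p1$truth, p2$truth)
  # and does not disturb the caller's RNG stream
  withr::local_seed(1); a <- runif(1)
  withr::local_seed(1); invisible(generate_phantom(spec)); b <- runif(1)
  expect_identical(a, b)
})

test_that("ground-truth masks are mutually consistent", {
  p <- cached_phantom(stage = 3, seed = 13, frame = 256, pitch = 16)
  tr <- p$truth
  expect_false(any(tr$portal & !tr$tissue))
  expect_false(any(tr$capsule & !tr$tissue))
  expect_false(any(tr$fibril & (tr$portal | tr$capsule)))
  expect_false(any(tr$droplet & !tr$tissue))
  expect_gte(tr$true_fibril_area_fraction, 0)
  expect_lte(tr$true_fibril_area_fraction, 1)
  # the capsule hugs the tissue boundary: every tissue pixel 4-adjacent to
  # background belongs to the capsule band
  H <- nrow(tr$tissue); W <- ncol(tr$tissue)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  next_to_bg <- shift(!tr$tissue, 1, 0) | shift(!tr$tissue, -1, 0) |
    shift(!tr$tissue, 0, 1) | shift(!tr$tissue, 0, -1)
  rim <- tr$tissue & next_to_bg
  expect_gt(sum(rim), 0)
  expect_true(all(tr$capsule[rim]))
})

test_that("zero fibril density leaves the parenchymal SHG at the noise floor", {
  p <- generate_phantom(test_spec(stage = 0, seed = 14, frame = 256, pitch = 16,
                                  fibril_density = 0))
  expect_equal(sum(p$truth$fibril), 0)
  par <- p$truth$tissue & !p$truth$portal & !p$truth$capsule
  expect_equal(mean(p$image$shg[par]), 8, tolerance = 0.15)
})

test_that("stage raises the true fibril burden", {
  f0 <- vapply(1:5, function(s)
    cached_phantom(stage = 0, seed = 100 + s, frame = 256,
                   pitch = 16)$truth$true_fibril_area_fraction, numeric(1))
  f1 <- vapply(1:5, function(s)
    cached_phantom(stage = 1, seed = 200 + s, frame = 256,
                   pitch = 16)$truth$true_fibril_area_fraction, numeric(1))
  expect_gt(mean(f1), mean(f0))
})

test_that("raising fibril intensity raises the parenchymal SHG mean", {
  lo <- generate_phantom(test_spec(stage = 1, seed = 15, frame = 256, pitch = 16,
                                   fibril_intensity = 10))
  hi <- generate_phantom(test_spec(stage = 1, seed = 15, frame = 256, pitch = 16,
                                   fibril_intensity = 30))
  par <- lo$truth$tissue & !lo$truth$portal & !lo$truth$capsule
  expect_gt(mean(hi$image$shg[par]), mean(lo$image$shg[par]))
})

test_that("spec validation rejects bad stages, grades and densities", {
  expect_error(phantom_spec(stage = 7), "stage")
  expect_error(phantom_spec(steatosis_grade = 5), "steatosis")
  expect_error(phantom_spec(fibril_density = -1), ">= 0")
  expect_error(phantom_spec(fibril_length_range_um = c(200, 20)), "min <= max")
  expect_error(
    generate_phantom(test_spec(stage = 0, seed = 1, frame = 128, pitch = 16,
                               fibril_density = 1e6)),
    "overflow")
})

test_that("cohorts are deterministic and cover all stages", {
  base <- test_spec(stage = 0, seed = 1, frame = 256, pitch = 16)
  c1 <- generate_cohort(1, base_spec = base, seed = 7)
  c2 <- generate_cohort(1, base_spec = base, seed = 7)
  expect_equal(nrow(c1), 5)
  expect_equal(c1$stage, 0:4)
  expect_identical(c1$seed, c2$seed)
  expect_identical(c1$image[[3]]$shg, c2$image[[3]]$shg)
  expect_error(generate_cohort(0), ">= 1")
})

test_that("true fibril fraction grows with stage across a small cohort", {
  base <- test_spec(stage = 0, seed = 1, frame = 256, pitch = 16)
  co <- generate_cohort(3, base_spec = base, seed = 9)
  fr <- vapply(co$truth, function(t) t$true_fibril_area_fraction, numeric(1))
  gm <- tapply(fr, co$stage, mean)
  expect_true(all(diff(gm) > 0))
})
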