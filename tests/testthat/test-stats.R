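test_that("Mann-Whitney U and exact p match enumeration on worked cases", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 2 / 6)  # all C(4,2)=6 rank assignments
  expect_true(mw$exact)
  # identical multisets: U = n^2/2 by midranks, p = 1 at full overlap
  x <- c(3, 5, 5, 9)
  mw2 <- mann_whitney_u(x, x)
  expect_equal(unname(mw2$statistic), length(x)^2 / 2)
  expect_equal(mw2$p.value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("U statistics of the two orderings always sum to n1*n2", {
  withr::local_seed(41)
  for (i in 1:40) {
    n1 <- sample(1:10, 1); n2 <- sample(1:10, 1)
    x <- sample(0:5, n1, TRUE)  # heavy ties on purpose
    y <- sample(0:5, n2, TRUE)
    u1 <- unname(mann_whitney_u(x, y)$statistic)
    u2 <- unname(mann_whitney_u(y, x)$statistic)
    expect_equal(u1 + u2, n1 * n2)
  }
})

test_that("exact p agrees with the reference implementation on tie-free data", {
  withr::local_seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  withr::local_seed(43)
  x <- round(rnorm(15, 0, 2)); y <- round(rnorm(15, 1, 2))
  ours <- mann_whitney_u(x, y)
  expect_false(ours$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("Spearman rho is the Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_true(is.nan(spearman_rho(c(2, 2, 2), 1:3)))
  # tie case against a hand-rolled midrank Pearson oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), oracle)
  expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms, range in [-1, 1]
  withr::local_seed(44)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    r <- spearman_rho(a, b)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(spearman_rho(exp(a), b^3 + 5 * b), r)
  }
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("weighted kappa matches hand-evaluated observed/expected matrices", {
  expect_equal(weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(weighted_kappa(c(0, 1), c(1, 0)), -1)
  # 3-category hand case, linear weights: o and e written out explicitly
  a <- c(0, 0, 1, 2, 2, 1)
  b <- c(0, 1, 1, 2, 1, 1)
  k <- 3
  o <- table(factor(a, 0:2), factor(b, 0:2)) / 6
  e <- outer(rowSums(o), colSums(o))
  w <- abs(outer(1:3, 1:3, `-`)) / 2
  expect_equal(weighted_kappa(a, b), 1 - sum(w * o) / sum(w * e))
  wq <- w^2
  expect_equal(weighted_kappa(a, b, weights = "quadratic"),
               1 - sum(wq * o) / sum(wq * e))
  expect_lte(weighted_kappa(a, b), 1)
  expect_error(weighted_kappa(0:1, 1:2, levels = c(0, 1)), "outside")
  expect_error(weighted_kappa(0:2, 0:1), "equal length")
})

test_that("stage summaries test adjacent stages and mark tiny groups", {
  tab <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    fibrosis_stage = rep(0:2, each = 4),
    mean_shg = c(1, 2, 1.5, 1.2, 5, 6, 5.5, 7, 11, 12, 10, 13))
  s <- stage_summary(tab)
  expect_equal(s$stages$n, c(4, 4, 4))
  expect_equal(nrow(s$tests), 2)
  expect_true(all(s$tests$p.value < 0.05))
  expect_identical(tidy(s), s$tests)
  expect_identical(glance(s), s$stages)
  # single sample per stage: summary emitted, tests not computable
  one <- tibble::tibble(fibrosis_stage = 0:4, mean_shg = 1:5)
  s1 <- stage_summary(one)
  expect_equal(nrow(s1$stages), 5)
  expect_true(all(is.na(s1$tests$p.value)))
  # Holm adjustment is available but off by default
  sh <- stage_summary(tab, adjust = "holm")
  expect_true("p.adjusted" %in% names(sh$tests))
  expect_error(stage_summary(tab, score = "nope"), "must contain")
})

test_that("shuffling stage labels removes the adjacent-stage separation", {
  withr::local_seed(46)
  tab <- tibble::tibble(fibrosis_stage = rep(0:4, each = 8),
                        mean_shg = rep(c(1, 3, 6, 10, 15), each = 8) +
                          rnorm(40, 0, 0.3))
  shuffled <- tab
  shuffled$fibrosis_stage <- sample(shuffled$fibrosis_stage)
  p_true <- stage_summary(tab)$tests$p.value
  p_shuf <- stage_summary(shuffled)$tests$p.value
  expect_true(all(p_true < 0.01))
  expect_false(all(p_shuf < 0.05))  # no systematic separation after shuffling
})
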