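#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties:
#' `U = R_x - n_x (n_x + 1) / 2` where `R_x` is the rank sum of `x` in the
#' pooled sample. For combined sample sizes up to `exact_max` the two-sided
#' p-value is computed by exact enumeration over all assignments of the
#' observed (mid)ranks to the two groups:
#' `p = P(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|)`. For larger samples the
#' normal approximation with tie correction and a 0.5 continuity correction is
#' used. Exact enumeration is feasible and preferable for small cohorts, where
#' group sizes rarely exceed a dozen.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact_max Combined-size cutoff for exact enumeration (default 20).
#' @return A list of class `c("shg_mwu", "htest")` with `statistic` (U for
#'   `x`), `p.value`, `exact`, and sample sizes.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (N <= exact_max) {
    if (ties) {
      u_all <- enumerate_u(r, n1)
      p <- mean(abs(u_all - mid) >= abs(U - mid) - 1e-9)
    } else {
      tab <- exact_u_table(n1, n2)  # cached null distribution, untied ranks
      p <- tab[[as.character(round(U))]]
    }
    exact <- TRUE
  } else {
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (abs(U - mid) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(0, z)))
    exact <- FALSE
  }
  structure(
    list(statistic = c(U = U), p.value = p, exact = exact,
         n = c(n1 = n1, n2 = n2),
         method = "Mann-Whitney U test (two-sided)",
         data.name = "x and y"),
    class = c("shg_mwu", "htest"))
}

# all U values over assignments of the given (mid)ranks to group 1
enumerate_u <- function(r, n1) {
  idx <- utils::combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

# two-sided exact p-value lookup for untied ranks, cached per (n1, n2)
.mwu_cache <- new.env(parent = emptyenv())
exact_u_table <- function(n1, n2) {
  key <- paste(sort(c(n1, n2)), collapse = "_")
  if (!is.null(.mwu_cache[[key]])) {
    tab <- .mwu_cache[[key]]
  } else {
    u_all <- enumerate_u(seq_len(n1 + n2), min(n1, n2))
    mid <- n1 * n2 / 2
    us <- 0:(n1 * n2)
    tab <- as.list(vapply(us, function(u)
      mean(abs(u_all - mid) >= abs(u - mid)), numeric(1)))
    names(tab) <- as.character(us)
    .mwu_cache[[key]] <- tab
  }
  tab
}

#' Tidy a Mann-Whitney result
#' @param x An `shg_mwu`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `exact`, `n1`, `n2`.
#' @export
tidy.shg_mwu <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic), p.value = x$p.value,
                 exact = x$exact, n1 = unname(x$n["n1"]),
                 n2 = unname(x$n["n2"]), method = x$method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Returns `NaN` when either vector is
#' constant (ranks have zero variance).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`, or `NaN`.
#' @examples
#' spearman_rho(1:3, c(10, 20, 30))  # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NaN)
  stats::cor(rank(x), rank(y))
}

#' Weighted kappa for ordinal inter-rater agreement
#'
#' Chance-corrected agreement with distance-weighted disagreement penalties:
#' `kappa_w = 1 - sum(w * o) / sum(w * e)` with disagreement weights
#' `w_ij = |i - j| / (k - 1)` (linear, default) or its square (quadratic),
#' observed proportion matrix `o`, and expected matrix `e` from the two
#' raters' marginals. Fibrosis stages are ordinal with arguably equidistant
#' steps, hence the linear default.
#'
#' @param ratings_a,ratings_b Equal-length vectors of ordinal category labels.
#' @param weights `"linear"` or `"quadratic"`.
#' @param levels The declared ordered category set; defaults to the sorted
#'   union of observed labels. Labels outside this set are an error.
#' @return Kappa in `[-Inf, 1]`; 1 iff perfect agreement.
#' @examples
#' weighted_kappa(c(0, 1), c(1, 0))  # -1
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           weights = c("linear", "quadratic"),
                           levels = NULL) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b)) {
    abort("rating vectors must have equal length")
  }
  if (length(ratings_a) == 0) abort("ratings must be nonempty")
  levels <- levels %||% sort(unique(c(ratings_a, ratings_b)))
  if (!all(ratings_a %in% levels) || !all(ratings_b %in% levels)) {
    abort("ratings contain labels outside the declared category set")
  }
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  k <- length(levels)
  if (k == 1) return(1)
  o <- table(a, b) / length(a)
  marg_a <- rowSums(o); marg_b <- colSums(o)
  e <- outer(marg_a, marg_b)
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  w <- if (weights == "linear") d else d^2
  denom <- sum(w * e)
  if (denom == 0) return(1)  # all mass on one category for both raters
  1 - sum(w * o) / denom
}

#' Per-stage summary with adjacent-stage tests
#'
#' Summarizes a cohort table per fibrosis stage (n, mean, sd, median, IQR of
#' the chosen score) and tests adjacent stage pairs (0 vs 1, 1 vs 2, ...) with
#' the two-sided Mann-Whitney U test. No multiple-testing correction is applied
#' by default; Holm adjustment is available. Pairs where either group has fewer
#' than two samples are reported with `p.value = NA` (not computable).
#'
#' @param table Data frame with at least `fibrosis_stage` and the score column.
#' @param score Column to summarize (default `mean_shg`), as a string.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return An object of class `shg_stage_summary`: list of tibbles `stages`
#'   and `tests`.
#' @export
stage_summary <- function(table, score = "mean_shg",
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!"fibrosis_stage" %in% names(table) || !score %in% names(table)) {
    abort(sprintf("table must contain columns 'fibrosis_stage' and '%s'", score))
  }
  tab <- dplyr::as_tibble(table)
  stages <- tab |>
    dplyr::group_by(fibrosis_stage = .data$fibrosis_stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[score]]),
      sd = sd(.data[[score]]),
      median = median(.data[[score]]),
      iqr = stats::IQR(.data[[score]]),
      .groups = "drop") |>
    dplyr::arrange(.data$fibrosis_stage)
  present <- sort(unique(tab$fibrosis_stage))
  pairs <- purrr::keep(
    purrr::map(head(present, -1), ~ c(.x, .x + 1)),
    ~ all(. %in% present))
  tests <- purrr::map_dfr(pairs, function(pr) {
    g1 <- tab[[score]][tab$fibrosis_stage == pr[1]]
    g2 <- tab[[score]][tab$fibrosis_stage == pr[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      return(tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                            statistic = NA_real_, p.value = NA_real_))
    }
    mw <- mann_whitney_u(g1, g2)
    tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                   statistic = unname(mw$statistic), p.value = mw$p.value)
  })
  if (adjust == "holm" && nrow(tests) > 0) {
    tests$p.adjusted <- stats::p.adjust(tests$p.value, "holm")
  }
  structure(list(stages = stages, tests = tests, score = score),
            class = "shg_stage_summary")
}

#' @export
print.shg_stage_summary <- function(x, ...) {
  cat(sprintf("<shg_stage_summary> score: %s\n", x$score))
  print(x$stages)
  cat("adjacent-stage Mann-Whitney tests:\n")
  print(x$tests)
  invisible(x)
}

#' Tidy the adjacent-stage tests of a stage summary
#' @param x An `shg_stage_summary`.
#' @param ... Unused.
#' @return Tibble of adjacent-stage test results.
#' @export
tidy.shg_stage_summary <- function(x, ...) x$tests

#' Per-stage summary rows of a stage summary
#' @param x An `shg_stage_summary`.
#' @param ... Unused.
#' @return Tibble with one row per stage.
#' @export
glance.shg_stage_summary <- function(x, ...) x$stages
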