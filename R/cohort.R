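#' Quantify every phantom of a cohort
#'
#' Runs segmentation and quantification over a cohort tibble from
#' [generate_cohort()] and returns the per-biopsy cohort table: one row per
#' sample with the fibrosis stage, steatosis grade, generative densities and
#' all quantification fields.
#'
#' @param cohort Tibble from [generate_cohort()] (needs `sample_id`, `stage`,
#'   `steatosis_grade` and the `image` list-column).
#' @param cfg A [mask_pipeline_config].
#' @return A tibble (the cohort table), one row per sample, with an attached
#'   `"segmentations"` attribute (list of `shg_segmentation`).
#' @export
quantify_cohort <- function(cohort, cfg = mask_pipeline_config()) {
  stopifnot(all(c("sample_id", "stage", "steatosis_grade", "image") %in%
                  names(cohort)))
  segs <- purrr::map(cohort$image, segment_mosaic, cfg = cfg)
  quants <- purrr::map2(cohort$image, segs, quantify)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = cohort$sample_id,
                   fibrosis_stage = cohort$stage,
                   steatosis_grade = cohort$steatosis_grade),
    purrr::map_dfr(quants, tidy)
  )
  if ("fibril_density" %in% names(cohort)) {
    out$fibril_density <- cohort$fibril_density
  }
  if ("droplet_density" %in% names(cohort)) {
    out$droplet_density <- cohort$droplet_density
  }
  attr(out, "segmentations") <- segs
  class(out) <- c("shg_cohort", class(out))
  out
}

#' Plot a cohort table
#'
#' Mean background-subtracted SHG intensity per fibrosis stage (points with
#' per-stage group means), the per-sample analogue of the cohort intensity
#' figures this score is designed for.
#'
#' @param object A cohort table (`shg_cohort` or any data frame with
#'   `fibrosis_stage` and the score column).
#' @param score Column to plot (default `"mean_shg"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shg_cohort <- function(object, score = "mean_shg", ...) {
  df <- dplyr::as_tibble(object)
  means <- df |>
    dplyr::group_by(.data$fibrosis_stage) |>
    dplyr::summarise(m = mean(.data[[score]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fibrosis_stage),
                                   y = .data[[score]])) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(x = factor(.data$fibrosis_stage), y = .data$m),
                        shape = 95, size = 12, colour = "firebrick") +
    ggplot2::labs(x = "fibrosis stage", y = score) +
    ggplot2::theme_classic()
}

#' Read and write cohort tables as CSV
#'
#' @param table Cohort table (data frame).
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a tibble and validates the schema.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(dplyr::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  validate_cohort_table(readr::read_csv(path, show_col_types = FALSE))
}

validate_cohort_table <- function(tab) {
  need <- c("sample_id", "fibrosis_stage", "mean_shg", "mean_cars")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("cohort CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(!tab$fibrosis_stage %in% 0:4)) {
    abort("fibrosis_stage values must lie in 0-4")
  }
  tab
}
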