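#' Summarize the pits of one subject-condition
#'
#' Pits are pooled across both discs and all scans of a subject under one
#' culture condition before medians are taken. Per shape class the median
#' width, depth and FWHM are reported (missing when the class is empty,
#' never zero), together with the shape percentages (which sum to 100 when
#' any pits exist) and the median erosion area: the per-subject median of
#' individual pit areas by default, or the median over scans of the total
#' eroded area per scan when `config$area_mode == "per_scan_total"` (the
#' latter requires a `trace_id` column).
#'
#' @param pits A tibble of pits for one subject x condition, as produced
#'   by [analyze_trace] (rows may be bound across scans). Must contain
#'   `width`, `depth`, `fwhm`, `area`, `shape_class`.
#' @param subject_id,group,condition Identifiers copied into the summary.
#' @param planar_percent Optional planar resorbed-area percentage for this
#'   subject x condition.
#' @param config A [pit_config].
#' @return A one-row tibble with `n_pits`, per-class counts and
#'   percentages, per-class median geometry, and `median_area`.
#' @export
summarize_subject <- function(pits, subject_id = NA_character_,
                              group = NA_character_,
                              condition = NA_character_,
                              planar_percent = NA_real_,
                              config = pit_config()) {
  base <- tibble::tibble(
    subject_id = as.character(subject_id),
    group = as.character(group),
    condition = as.character(condition)
  )
  n <- nrow(pits)
  counts <- vapply(pit_shape_classes, function(cl) {
    sum(pits$shape_class == cl)
  }, integer(1))
  pct <- if (n > 0L) unname(100 * counts / n) else rep(NA_real_, 3L)

  class_median <- function(cl, var) {
    v <- pits[[var]][pits$shape_class == cl]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }
  geom <- tibble::tibble(
    median_width_unidented = class_median("unidented", "width"),
    median_depth_unidented = class_median("unidented", "depth"),
    median_fwhm_unidented = class_median("unidented", "fwhm"),
    median_width_bidented = class_median("bidented", "width"),
    median_depth_bidented = class_median("bidented", "depth"),
    median_fwhm_bidented = class_median("bidented", "fwhm"),
    median_width_multidented = class_median("multidented", "width"),
    median_depth_multidented = class_median("multidented", "depth"),
    median_fwhm_multidented = class_median("multidented", "fwhm")
  )

  median_area <- if (n == 0L) {
    NA_real_
  } else if (config$area_mode == "per_scan_total") {
    if (is.null(pits$trace_id)) {
      rlang::abort("area_mode 'per_scan_total' needs a trace_id column",
                   class = "pitscan_validation_error")
    }
    totals <- pits |>
      dplyr::group_by(.data$trace_id) |>
      dplyr::summarise(total = sum(.data$area), .groups = "drop")
    stats::median(totals$total)
  } else {
    stats::median(pits$area)
  }

  dplyr::bind_cols(
    base,
    tibble::tibble(
      n_pits = n,
      n_unidented = counts[["unidented"]],
      n_bidented = counts[["bidented"]],
      n_multidented = counts[["multidented"]],
      pct_unidented = pct[1L],
      pct_bidented = pct[2L],
      pct_multidented = pct[3L],
      median_area = median_area
    ),
    geom,
    tibble::tibble(planar_pct = as.double(planar_percent))
  )
}

#' Summarize every subject-condition cell of a cohort pit table
#'
#' @param pit_table A tibble of pits with columns `subject_id`, `group`,
#'   `condition` plus the pit metric columns (and `trace_id`).
#' @param planar A tibble with `subject_id`, `condition`,
#'   `planar_pct` (optional).
#' @param config A [pit_config].
#' @return A tibble of [summarize_subject] rows, one per subject x
#'   condition present in `pit_table` (and in `planar`, for subjects whose
#'   scans yielded no pits).
#' @export
summarize_cohort <- function(pit_table, planar = NULL,
                             config = pit_config()) {
  cells <- dplyr::distinct(pit_table, .data$subject_id, .data$group,
                           .data$condition)
  out <- purrr::pmap(cells, function(subject_id, group, condition) {
    rows <- pit_table[pit_table$subject_id == subject_id &
                        pit_table$condition == condition, ]
    pp <- NA_real_
    if (!is.null(planar)) {
      hit <- planar$subject_id == subject_id & planar$condition == condition
      if (any(hit)) pp <- planar$planar_pct[which(hit)[1L]]
    }
    summarize_subject(rows, subject_id, group, condition, pp, config)
  }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$group, .data$subject_id, .data$condition)
}

#' Cross-subject pit-shape distribution
#'
#' For each group x condition cell and each shape class, the median and
#' inclusive (linear-interpolation) 25th-75th percentiles of the
#' subject-level percentages.
#'
#' @param summaries A tibble of subject summaries ([summarize_subject]).
#' @return A long tibble: `group`, `condition`, `shape_class`,
#'   `n_subjects`, `median_pct`, `q1_pct`, `q3_pct`.
#' @export
shape_distribution <- function(summaries) {
  summaries |>
    dplyr::select("group", "condition", "subject_id",
                  dplyr::starts_with("pct_")) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"),
                        names_to = "shape_class", names_prefix = "pct_",
                        values_to = "pct") |>
    dplyr::mutate(shape_class = factor(.data$shape_class,
                                       levels = pit_shape_classes)) |>
    dplyr::group_by(.data$group, .data$condition, .data$shape_class) |>
    dplyr::summarise(
      n_subjects = sum(!is.na(.data$pct)),
      median_pct = stats::median(.data$pct, na.rm = TRUE),
      q1_pct = stats::quantile(.data$pct, 0.25, na.rm = TRUE, type = 7,
                               names = FALSE),
      q3_pct = stats::quantile(.data$pct, 0.75, na.rm = TRUE, type = 7,
                               names = FALSE),
      .groups = "drop"
    )
}
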