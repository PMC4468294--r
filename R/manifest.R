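#' Cohort manifest
#'
#' The manifest maps trace files to the study design: one row per scan with
#' columns `trace_path`, `subject_id`, `group`, `condition`, `disc_index`,
#' `scan_index`. Groups are `charcot`, `diabetic`, `control`; culture
#' conditions are `rankl` (M-CSF + RANKL) and `rankl_anti_tnf`
#' (M-CSF + RANKL + anti-TNF-alpha).
#'
#' @name cohort_manifest
NULL

pit_groups <- c("charcot", "diabetic", "control")
pit_conditions <- c("rankl", "rankl_anti_tnf")
pit_shape_classes <- c("unidented", "bidented", "multidented")

normalize_label <- function(x, allowed, what) {
  norm <- gsub("(^_)|(_$)", "", gsub("[^a-z0-9]+", "_", tolower(trimws(x))))
  # common aliases for the anti-TNF condition
  norm[norm %in% c("anti_tnf", "rankl_anti_tnf_alpha", "m_csf_rankl_anti_tnf")] <-
    "rankl_anti_tnf"
  norm[norm %in% c("m_csf_rankl")] <- "rankl"
  bad <- setdiff(unique(norm), allowed)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("unknown %s label(s) %s; allowed: %s", what,
              paste0("'", bad, "'", collapse = ", "),
              paste(allowed, collapse = ", ")),
      class = "pitscan_validation_error"
    )
  }
  norm
}

#' Read and validate a cohort manifest
#'
#' @param path Path to a CSV file with columns `trace_path`, `subject_id`,
#'   `group`, `condition`, `disc_index`, `scan_index`.
#' @return A validated tibble with normalized `group` and `condition`
#'   labels.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("manifest not found: %s", path),
                 class = "pitscan_io_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest A data frame with the manifest columns.
#' @export
validate_manifest <- function(manifest) {
  required <- c("trace_path", "subject_id", "group", "condition",
                "disc_index", "scan_index")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("manifest missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "pitscan_validation_error"
    )
  }
  if (nrow(manifest) == 0L) {
    rlang::abort("manifest has no rows", class = "pitscan_validation_error")
  }
  m <- tibble::as_tibble(manifest)
  m$group <- normalize_label(m$group, pit_groups, "group")
  m$condition <- normalize_label(m$condition, pit_conditions, "condition")
  m$disc_index <- as.integer(m$disc_index)
  m$scan_index <- as.integer(m$scan_index)
  m$subject_id <- as.character(m$subject_id)

  key <- paste(m$subject_id, m$condition, m$disc_index, m$scan_index,
               sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("duplicate manifest key (subject/condition/disc/scan): %s",
              dup[1]),
      class = "pitscan_validation_error"
    )
  }
  multi_group <- m |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_group) > 0L) {
    rlang::abort(
      sprintf("subject %s is assigned to more than one group",
              multi_group$subject_id[1]),
      class = "pitscan_validation_error"
    )
  }
  m
}

#' Write a cohort manifest to CSV
#'
#' @param manifest A manifest tibble (see [read_manifest]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(validate_manifest(manifest), path, progress = FALSE)
  invisible(path)
}
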