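#' Pit detection and analysis configuration
#'
#' Tunable parameters of the trace analysis and cohort statistics. All
#' lengths are in micrometres.
#'
#' @param min_depth Minimum pit depth (um) for a segmented interval to be
#'   reported as a pit. Default 0.5.
#' @param min_width Minimum pit width (um). Default 1.0.
#' @param ridge_fraction Fraction of the pit's maximum depth used for the
#'   ridge tolerance when counting dents: an internal ridge separates two
#'   dents when the smoothed profile rises to within
#'   `max(2 * noise_sigma, ridge_fraction * depth)` of the baseline.
#'   Default 0.10.
#' @param smooth_window Width (um) of the centred moving-average window
#'   applied before segmentation and dent counting. Depth, FWHM and area
#'   are always measured on the unsmoothed trace. Default 1.0.
#' @param alpha Significance level for the group comparisons. Default 0.05.
#' @param area_mode How the per-subject "median erosion area" is formed:
#'   `"per_pit"` (median of individual pit areas, the default) or
#'   `"per_scan_total"` (median over scans of the total eroded area per
#'   scan).
#' @param shape_test How the condition effect on the pit-shape distribution
#'   is tested: `"per_class_mw"` (Mann-Whitney on subject-level percentages
#'   per shape class, the default) or `"pooled_chisq"` (single chi-square
#'   on pooled pit counts).
#' @param seed Optional integer seed recorded with the run.
#'
#' @return A list of class `pit_config`.
#' @export
pit_config <- function(min_depth = 0.5,
                       min_width = 1.0,
                       ridge_fraction = 0.10,
                       smooth_window = 1.0,
                       alpha = 0.05,
                       area_mode = c("per_pit", "per_scan_total"),
                       shape_test = c("per_class_mw", "pooled_chisq"),
                       seed = NULL) {
  area_mode <- match.arg(area_mode)
  shape_test <- match.arg(shape_test)
  if (!is.numeric(min_depth) || min_depth <= 0) {
    rlang::abort("min_depth must be > 0", class = "pitscan_validation_error")
  }
  if (!is.numeric(min_width) || min_width <= 0) {
    rlang::abort("min_width must be > 0", class = "pitscan_validation_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be in (0, 1)",
                 class = "pitscan_validation_error")
  }
  if (!is.numeric(ridge_fraction) || ridge_fraction <= 0 ||
        ridge_fraction >= 1) {
    rlang::abort("ridge_fraction must be in (0, 1)",
                 class = "pitscan_validation_error")
  }
  structure(
    list(
      min_depth = min_depth,
      min_width = min_width,
      ridge_fraction = ridge_fraction,
      smooth_window = smooth_window,
      alpha = alpha,
      area_mode = area_mode,
      shape_test = shape_test,
      seed = seed
    ),
    class = "pit_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are ignored; absent keys take the [pit_config] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pit_config`.
#' @export
read_pit_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path),
                 class = "pitscan_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keep <- intersect(names(raw), names(formals(pit_config)))
  do.call(pit_config, raw[keep])
}
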