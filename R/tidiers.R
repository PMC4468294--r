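#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pit table of an analyzed trace
#'
#' @param x A `pit_analysis` from [analyze_trace].
#' @param ... Unused.
#' @return The pit tibble (one row per detected pit).
#' @method tidy pit_analysis
#' @export
tidy.pit_analysis <- function(x, ...) {
  x$pits
}

#' One-row summary of an analyzed trace
#'
#' @param x A `pit_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: pit counts by shape class, total eroded
#'   area, and the baseline fit.
#' @method glance pit_analysis
#' @export
glance.pit_analysis <- function(x, ...) {
  tibble::tibble(
    source_id = x$source_id,
    n_pits = nrow(x$pits),
    n_unidented = sum(x$pits$shape_class == "unidented"),
    n_bidented = sum(x$pits$shape_class == "bidented"),
    n_multidented = sum(x$pits$shape_class == "multidented"),
    total_area = sum(x$pits$area),
    baseline_level = x$baseline$intercept,
    baseline_slope = x$baseline$slope,
    noise_sigma = x$baseline$noise_sigma,
    frac_unresorbed = x$baseline$frac_unresorbed
  )
}

#' @method tidy pit_baseline
#' @export
tidy.pit_baseline <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, slope = x$slope,
    noise_sigma = x$noise_sigma, frac_unresorbed = x$frac_unresorbed
  )
}

#' @method tidy pit_comparison
#' @export
tidy.pit_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a comparison table
#'
#' @param x A `pit_comparison` from [compare_groups].
#' @param ... Unused.
#' @return A one-row tibble with row counts and the significance level.
#' @method glance pit_comparison
#' @export
glance.pit_comparison <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_tested = sum(x$flag == ""),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_insufficient = sum(x$flag == "insufficient n"),
    alpha = attr(x, "alpha")
  )
}
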