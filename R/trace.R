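#' Construct a profilometry trace
#'
#' A trace is one stylus pass across a resorbed bone disc: a tibble with
#' columns `position` and `height`, both in micrometres, plus scan metadata
#' stored as attributes. Heights are relative to the instrument zero; erosion
#' is downward (more negative). All downstream pit metrics are measured from
#' the estimated unresorbed-surface baseline, not from zero.
#'
#' @param position Numeric vector of strictly increasing sampling positions
#'   (um from scan start).
#' @param height Numeric vector of surface heights (um), same length as
#'   `position`.
#' @param scan_length Nominal scan length (um). Defaults to the observed
#'   span of `position`.
#' @param sample_interval Nominal sampling interval (um). Defaults to the
#'   median spacing of `position`.
#' @param vertical_range Instrument vertical measurement range (um);
#'   default 65.5, the Dektak setting used for these scans.
#' @param source_id Free-text identifier of the scan.
#'
#' @return A tibble of class `pit_trace` with columns `position`, `height`
#'   and attributes `scan_length`, `sample_interval`, `vertical_range`,
#'   `source_id`.
#' @export
#' @examples
#' tr <- pit_trace(seq(0, 100, by = 0.5), rnorm(201, 0, 0.05))
#' trace_metadata(tr)
pit_trace <- function(position, height,
                      scan_length = NULL, sample_interval = NULL,
                      vertical_range = 65.5, source_id = "") {
  position <- as.double(position)
  height <- as.double(height)
  if (length(position) != length(height)) {
    rlang::abort("`position` and `height` must have equal length.",
                 class = "pitscan_validation_error")
  }
  if (is.null(scan_length)) {
    scan_length <- max(position) - min(position)
  }
  if (is.null(sample_interval)) {
    sample_interval <- stats::median(diff(position))
  }
  out <- tibble::tibble(position = position, height = height)
  attr(out, "scan_length") <- as.double(scan_length)
  attr(out, "sample_interval") <- as.double(sample_interval)
  attr(out, "vertical_range") <- as.double(vertical_range)
  attr(out, "source_id") <- as.character(source_id)
  class(out) <- c("pit_trace", class(tibble::tibble()))
  validate_pit_trace(out)
}

#' @rdname pit_trace
#' @param trace A `pit_trace`.
#' @export
trace_metadata <- function(trace) {
  list(
    scan_length = attr(trace, "scan_length"),
    sample_interval = attr(trace, "sample_interval"),
    vertical_range = attr(trace, "vertical_range"),
    source_id = attr(trace, "source_id"),
    n_samples = nrow(trace)
  )
}

validate_pit_trace <- function(trace) {
  pos <- trace$position
  h <- trace$height
  if (length(pos) < 16L) {
    rlang::abort(
      sprintf("a trace needs at least 16 samples, got %d", length(pos)),
      class = "pitscan_validation_error"
    )
  }
  if (anyNA(pos) || anyNA(h) || any(!is.finite(pos)) || any(!is.finite(h))) {
    rlang::abort("positions and heights must be finite and non-missing",
                 class = "pitscan_validation_error")
  }
  if (any(diff(pos) <= 0)) {
    rlang::abort("positions not increasing",
                 class = "pitscan_validation_error")
  }
  span <- max(pos) - min(pos)
  scan_length <- attr(trace, "scan_length")
  if (span > scan_length + 1e-9) {
    rlang::abort(
      sprintf("position span %.6g um exceeds scan_length %.6g um",
              span, scan_length),
      class = "pitscan_validation_error"
    )
  }
  vr <- attr(trace, "vertical_range")
  if (any(abs(h) > vr + 1e-9)) {
    rlang::abort(
      sprintf("|height| exceeds vertical_range %.6g um", vr),
      class = "pitscan_validation_error"
    )
  }
  trace
}

#' Read a profilometry trace from a plain-text file
#'
#' The trace dialect is two numeric columns (position um, height um),
#' whitespace- or comma-delimited, with optional `#`-prefixed metadata
#' header lines of the form `# key: value`. Recognised keys are
#' `scan_length_um`, `sample_interval_um`, `vertical_range_um` and
#' `source_id`; absent metadata default to the observed span, the median
#' sample spacing, and 65.5 um respectively.
#'
#' @param path Path to a trace file.
#' @return A [pit_trace].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("trace file not found: %s", path),
                 class = "pitscan_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)

  meta <- list()
  for (ln in lines[is_meta]) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("[:=]", body)) {
      key <- trimws(sub("[:=].*$", "", body))
      val <- trimws(sub("^[^:=]*[:=]\\s*", "", body))
      meta[[key]] <- val
    }
  }

  data_idx <- which(!is_meta & !is_blank)
  fields <- strsplit(trimws(lines[data_idx]), "[,[:space:]]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 2L)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("line %d: expected two numeric columns", data_idx[bad[1]]),
      class = "pitscan_parse_error"
    )
  }
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  ht <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(pos) | is.na(ht))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("line %d: non-numeric value '%s'",
              data_idx[bad[1]], trimws(lines[data_idx[bad[1]]])),
      class = "pitscan_parse_error"
    )
  }

  num_meta <- function(key) {
    if (is.null(meta[[key]])) NULL else as.numeric(meta[[key]])
  }
  pit_trace(
    pos, ht,
    scan_length = num_meta("scan_length_um"),
    sample_interval = num_meta("sample_interval_um"),
    vertical_range = if (is.null(num_meta("vertical_range_um"))) 65.5 else
      num_meta("vertical_range_um"),
    source_id = if (is.null(meta[["source_id"]])) basename(path) else
      meta[["source_id"]]
  )
}

#' Write a profilometry trace to a plain-text file
#'
#' Writes the dialect read by [read_trace]; round-trips are exact to
#' 1e-9 um.
#'
#' @param trace A valid [pit_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_pit_trace(trace)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) {
                    rlang::abort(sprintf("cannot write trace file: %s", path),
                                 class = "pitscan_io_error")
                  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# scan_length_um: %.9f", attr(trace, "scan_length")),
    sprintf("# sample_interval_um: %.9f", attr(trace, "sample_interval")),
    sprintf("# vertical_range_um: %.9f", attr(trace, "vertical_range")),
    sprintf("# source_id: %s", attr(trace, "source_id")),
    sprintf("%.9f %.9f", trace$position, trace$height)
  ), con)
  invisible(path)
}

#' @export
print.pit_trace <- function(x, ...) {
  md <- trace_metadata(x)
  cat(sprintf(
    "<pit_trace> %d samples, %.6g um span (interval %.4g um), source '%s'\n",
    md$n_samples, max(x$position) - min(x$position),
    md$sample_interval, md$source_id
  ))
  NextMethod()
}
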