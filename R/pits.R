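#' @keywords internal
#' @noRd
smooth_heights <- function(h, sample_interval, window_um) {
  k <- max(1L, round(window_um / sample_interval))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || k >= length(h)) return(h)
  half <- (k - 1L) %/% 2L
  padded <- c(rep(h[1L], half), h, rep(h[length(h)], half))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2L))[
    (half + 1L):(half + length(h))]
}

# deficit = baseline level - height; positive below the unresorbed surface
trace_deficits <- function(trace, baseline, config) {
  raw <- baseline$level - trace$height
  hs <- smooth_heights(trace$height, attr(trace, "sample_interval"),
                       config$smooth_window)
  list(raw = raw, smooth = baseline$level - hs)
}

depth_gate_of <- function(baseline, config) {
  max(3 * baseline$noise_sigma, config$min_depth / 2)
}

noise_gate_of <- function(baseline) {
  # the 1e-9 um floor (sub-picometre) guards exact-arithmetic traces
  # against float rounding of the fitted level
  max(2 * baseline$noise_sigma, 1e-9)
}

# interpolate the position where the deficit crosses `gate` between samples
# i (outside, deficit <= gate) and i + 1 (inside, deficit > gate)
cross_position <- function(pos, deficit, i, gate) {
  d0 <- deficit[i]
  d1 <- deficit[i + 1L]
  if (d1 == d0) return(pos[i])
  pos[i] + (gate - d0) / (d1 - d0) * (pos[i + 1L] - pos[i])
}

#' Segment the sub-surface erosions of a trace into pit extents
#'
#' Candidate pits are seeded where the smoothed trace drops below
#' `level - depth_gate` (with `depth_gate = max(3 * noise_sigma,
#' min_depth / 2)`) and extended outward on the raw trace to the nearest
#' crossing of `level - noise_gate` (`noise_gate = 2 * noise_sigma`),
#' with crossing positions linearly interpolated between samples. Returns
#' to the unresorbed level shorter than `min_width` do not separate pits;
#' a full return above `level - noise_gate` for at least `min_width` does.
#' Extents whose maximum raw drop is below `min_depth` or whose width is
#' below `min_width` are discarded.
#'
#' @param trace A [pit_trace].
#' @param baseline A [pit_baseline] estimated from the same trace.
#' @param config A [pit_config].
#' @return A tibble with one row per extent, in position order:
#'   `start`, `end` (interpolated boundary positions, um) and the sample
#'   index range `i1`, `i2`.
#' @export
segment_pits <- function(trace, baseline, config = pit_config()) {
  d <- trace_deficits(trace, baseline, config)
  segment_pits_impl(trace$position, d$raw, d$smooth, baseline, config)
}

segment_pits_impl <- function(pos, raw, smooth, baseline, config) {
  empty <- tibble::tibble(start = double(), end = double(),
                          i1 = integer(), i2 = integer())
  noise_gate <- noise_gate_of(baseline)
  depth_gate <- depth_gate_of(baseline, config)

  above <- raw > noise_gate
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # close sub-min_width returns to the surface (they do not separate pits)
  n_runs <- length(r$lengths)
  for (j in seq_len(n_runs)) {
    if (!r$values[j] && j > 1L && j < n_runs) {
      gap <- pos[min(ends[j] + 1L, length(pos))] -
        pos[max(starts[j] - 1L, 1L)]
      if (gap < config$min_width) r$values[j] <- TRUE
    }
  }
  merged <- rle(inverse.rle(r))
  m_ends <- cumsum(merged$lengths)
  m_starts <- m_ends - merged$lengths + 1L
  keep <- which(merged$values)

  out <- vector("list", length(keep))
  n <- length(pos)
  for (k in seq_along(keep)) {
    i1 <- m_starts[keep[k]]
    i2 <- m_ends[keep[k]]
    # require a seed below the depth gate on the smoothed profile
    if (!any(smooth[i1:i2] > depth_gate)) next
    start <- if (i1 > 1L) cross_position(pos, raw, i1 - 1L, noise_gate) else
      pos[1L]
    end <- if (i2 < n) cross_position(rev(pos), rev(raw), n - i2, noise_gate) else
      pos[n]
    if (max(raw[i1:i2]) < config$min_depth) next
    if ((end - start) < config$min_width) next
    out[[k]] <- tibble::tibble(start = start, end = end, i1 = i1, i2 = i2)
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) empty else dplyr::arrange(out, .data$start)
}

#' Count the dents of a pit and classify its shape
#'
#' A dent starts and finishes at the level of the unresorbed surface; two
#' dents of one pit are separated by an internal ridge that rises back to
#' within `ridge_tolerance` of the baseline, where `ridge_tolerance =
#' max(2 * noise_sigma, ridge_fraction * depth)`. Operationally the dent
#' count is the number of maximal runs of the smoothed profile below
#' `level - ridge_tolerance` that also reach the seeding depth gate, which
#' equals one plus the number of qualifying internal ridges. Pits are
#' `unidented` (1 dent), `bidented` (2) or `multidented` (3 or more).
#'
#' @param trace A [pit_trace].
#' @param extent One extent row from [segment_pits] (or a list with `i1`,
#'   `i2`).
#' @param baseline The matching [pit_baseline].
#' @param config A [pit_config].
#' @return A one-row tibble with `dent_count` and `shape_class`.
#' @export
count_dents <- function(trace, extent, baseline, config = pit_config()) {
  d <- trace_deficits(trace, baseline, config)
  k <- count_dents_impl(d$raw, d$smooth, extent$i1, extent$i2, baseline,
                        config)
  tibble::tibble(dent_count = k, shape_class = shape_class_of(k))
}

count_dents_impl <- function(raw, smooth, i1, i2, baseline, config) {
  if (i2 - i1 + 1L < 4L) {
    rlang::abort("degenerate pit extent (< 4 samples)",
                 class = "pitscan_validation_error")
  }
  idx <- i1:i2
  depth <- max(raw[idx])
  ridge_tol <- max(2 * baseline$noise_sigma, config$ridge_fraction * depth)
  depth_gate <- depth_gate_of(baseline, config)

  core <- smooth[idx] > ridge_tol
  n_dents <- 0L
  if (any(core)) {
    r <- rle(core)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (max(raw[idx[starts[j]:ends[j]]]) >= depth_gate) {
        n_dents <- n_dents + 1L
      }
    }
  }
  max(1L, n_dents)
}

shape_class_of <- function(dent_count) {
  cls <- ifelse(dent_count <= 1L, "unidented",
                ifelse(dent_count == 2L, "bidented", "multidented"))
  factor(cls, levels = pit_shape_classes)
}

#' Measure the geometry of one pit
#'
#' Width is the distance between the interpolated baseline-crossing
#' boundaries; depth is the maximum drop from the baseline within the
#' extent (leftmost position on ties); FWHM is the distance between the
#' outermost interpolated crossings of the half-of-maximum-depth contour;
#' area is the trapezoid-rule integral of the drop over the extent (um^2).
#' Depth, FWHM and area are measured on the unsmoothed trace.
#'
#' @inheritParams count_dents
#' @return A one-row tibble: `start`, `end`, `width`, `depth`, `fwhm`,
#'   `area`.
#' @export
measure_pit <- function(trace, extent, baseline, config = pit_config()) {
  d <- trace_deficits(trace, baseline, config)
  tibble::as_tibble(
    measure_pit_impl(trace$position, d$raw, extent$i1, extent$i2,
                     extent$start, extent$end, noise_gate_of(baseline))
  )
}

measure_pit_impl <- function(pos, raw, i1, i2, start, end, noise_gate) {
  idx <- i1:i2
  dseg <- raw[idx]
  pseg <- pos[idx]
  m <- length(idx)
  depth <- max(dseg)
  if (depth <= 0) {
    rlang::abort("pit extent has non-positive depth (segmentation contract)",
                 class = "pitscan_internal_error")
  }
  half <- depth / 2

  at <- which(dseg >= half)
  l <- at[1L]
  r <- at[length(at)]
  xl <- if (l == 1L) max(start, pseg[1L] - 0) else
    cross_position(pseg, dseg, l - 1L, half)
  xr <- if (r == m) pseg[m] else
    cross_position(rev(pseg), rev(dseg), m - r, half)
  xl <- max(xl, start)
  xr <- min(xr, end)
  fwhm <- xr - xl

  dpos <- pmax(dseg, 0)
  area <- sum(diff(pseg) * (dpos[-1L] + dpos[-m]) / 2)
  # boundary slivers between the interpolated crossings and the first/last
  # samples; the deficit at the boundary equals the noise gate by definition
  area <- area + (pseg[1L] - start) * (dpos[1L] + noise_gate) / 2 +
    (end - pseg[m]) * (dpos[m] + noise_gate) / 2

  list(start = start, end = end, width = end - start,
       depth = depth, fwhm = fwhm, area = area)
}

#' Analyze one trace: baseline, segmentation, dent counts, pit metrics
#'
#' Runs [estimate_baseline], [segment_pits], and per extent [count_dents]
#' and [measure_pit], returning all detected pits in position order.
#'
#' @param trace A [pit_trace].
#' @param config A [pit_config].
#' @return An object of class `pit_analysis`: a list with the `trace`
#'   source id, the `baseline`, and `pits`, a tibble with columns `pit`,
#'   `start`, `end`, `width`, `depth`, `fwhm`, `area`, `dent_count`,
#'   `shape_class`. Use [tidy()] to extract the pit table.
#' @export
#' @examples
#' set.seed(1)
#' tr <- generate_trace(synthetic_preset(), seed = 1)$trace
#' fit <- analyze_trace(tr)
#' generics::tidy(fit)
analyze_trace <- function(trace, config = pit_config()) {
  baseline <- estimate_baseline(trace, config)
  d <- trace_deficits(trace, baseline, config)
  extents <- segment_pits_impl(trace$position, d$raw, d$smooth,
                               baseline, config)
  k <- nrow(extents)
  metrics <- vector("list", k)
  dents <- integer(k)
  gate <- noise_gate_of(baseline)
  for (j in seq_len(k)) {
    metrics[[j]] <- measure_pit_impl(trace$position, d$raw, extents$i1[j],
                                     extents$i2[j], extents$start[j],
                                     extents$end[j], gate)
    dents[j] <- count_dents_impl(d$raw, d$smooth, extents$i1[j],
                                 extents$i2[j], baseline, config)
  }
  col <- function(nm) vapply(metrics, `[[`, 0, nm)
  pits <- tibble::tibble(
    pit = seq_len(k),
    start = col("start"), end = col("end"), width = col("width"),
    depth = col("depth"), fwhm = col("fwhm"), area = col("area"),
    dent_count = dents, shape_class = shape_class_of(dents)
  )
  structure(
    list(
      source_id = attr(trace, "source_id"),
      trace = trace,
      baseline = baseline,
      pits = pits,
      config = config
    ),
    class = "pit_analysis"
  )
}

#' @export
print.pit_analysis <- function(x, ...) {
  cat(sprintf(
    "<pit_analysis> '%s': %d pits (%s), noise_sigma %.4g um\n",
    x$source_id, nrow(x$pits),
    paste(table(x$pits$shape_class), names(table(x$pits$shape_class)),
          collapse = ", "),
    x$baseline$noise_sigma
  ))
  print(x$pits)
  invisible(x)
}

#' Planar resorption mask
#'
#' A binary raster of a disc surface, `TRUE`/1 where resorbed.
#'
#' @param grid A logical or 0/1 matrix.
#' @param pixel_size Pixel edge length (um).
#' @return An object of class `planar_mask`.
#' @export
planar_mask <- function(grid, pixel_size = 1) {
  grid <- matrix(as.logical(grid), nrow = nrow(grid))
  if (pixel_size <= 0) {
    rlang::abort("pixel_size must be > 0", class = "pitscan_validation_error")
  }
  if (all(grid)) {
    rlang::abort("mask has no unresorbed pixels",
                 class = "pitscan_validation_error")
  }
  structure(grid, pixel_size = pixel_size, class = c("planar_mask", "matrix"))
}

#' Percentage of the disc surface that is resorbed
#'
#' @param mask A [planar_mask] (or plain logical matrix).
#' @return Resorbed area as a percentage in `[0, 100]`.
#' @export
resorbed_area_percent <- function(mask) {
  100 * mean(as.logical(mask))
}
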