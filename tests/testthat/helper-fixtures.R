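# Analytic trace fixtures, built on a uniform grid.

# piecewise-linear profile through (x, y) vertices, flat outside
piecewise_trace <- function(vertices, from = 0, to = NULL, by = 0.1,
                            level = 0, noise_sd = 0, seed = NULL) {
  if (is.null(to)) to <- max(vertices$x) + 50
  pos <- seq(from, to, by = by)
  h <- rep(level, length(pos))
  xs <- vertices$x
  ys <- vertices$y
  inside <- pos >= min(xs) & pos <= max(xs)
  h[inside] <- level + stats::approx(xs, ys, xout = pos[inside])$y
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    h <- h + stats::rnorm(length(h), 0, noise_sd)
  }
  pit_trace(pos, h)
}

# triangular pit: vertices (x0, 0), (x0 + w/2, -d), (x0 + w, 0)
triangle_trace <- function(x0 = 100, width = 20, depth = 8, ...) {
  piecewise_trace(
    list(x = c(x0, x0 + width / 2, x0 + width), y = c(0, -depth, 0)),
    ...
  )
}

# W-shaped pit: two depth-`depth` lobes joined by a ridge at -ridge_drop
w_pit_trace <- function(x0 = 100, lobe = 5, depth = 6, ridge_drop = 0.1,
                        ...) {
  piecewise_trace(
    list(
      x = x0 + c(0, lobe, 2 * lobe, 3 * lobe, 4 * lobe),
      y = c(0, -depth, -ridge_drop, -depth, 0)
    ),
    ...
  )
}

# a three-pit trace with known analytic geometry
three_pit_trace <- function(by = 0.1, noise_sd = 0, seed = NULL,
                            level = 0) {
  v <- list(
    x = c(100, 110, 120,   300, 306, 312,   500, 512, 524),
    y = c(0, -8, 0,        0, -4, 0,        0, -6, 0)
  )
  pos <- seq(0, 650, by = by)
  h <- rep(0, length(pos))
  for (k in c(1, 4, 7)) {
    seg <- pos >= v$x[k] & pos <= v$x[k + 2]
    h[seg] <- stats::approx(v$x[k:(k + 2)], v$y[k:(k + 2)],
                            xout = pos[seg])$y
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    h <- h + stats::rnorm(length(h), 0, noise_sd)
  }
  pit_trace(pos, h + level)
}

small_manifest <- function(n_subjects = 10, conditions = 2, discs = 2,
                           scans = 5) {
  g <- expand.grid(
    subject = seq_len(n_subjects), cond = seq_len(conditions),
    disc = seq_len(discs), scan = seq_len(scans)
  )
  tibble::tibble(
    trace_path = sprintf("traces/s%02d_c%d_d%d_s%d.txt",
                         g$subject, g$cond, g$disc, g$scan),
    subject_id = sprintf("subj_%02d", g$subject),
    group = "charcot",
    condition = c("rankl", "rankl_anti_tnf")[g$cond],
    disc_index = g$disc,
    scan_index = g$scan
  )
}

# minimal pit tibble for summary tests
fake_pits <- function(dent_counts, widths = NULL, depths = NULL,
                      fwhms = NULL, areas = NULL, trace_id = "t1") {
  n <- length(dent_counts)
  tibble::tibble(
    trace_id = rep_len(trace_id, n),
    width = widths %||% rep(10, n),
    depth = depths %||% rep(2, n),
    fwhm = fwhms %||% rep(5, n),
    area = areas %||% rep(12, n),
    dent_count = as.integer(dent_counts),
    shape_class = factor(
      ifelse(dent_counts <= 1, "unidented",
             ifelse(dent_counts == 2, "bidented", "multidented")),
      levels = c("unidented", "bidented", "multidented")
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small, fast cohort specification for pipeline tests: short scans
# with proportionally narrower pits so scans never erode out
tiny_spec <- function(seed = 1) {
  spec <- default_cohort_spec(seed = seed)
  spec$n_subjects <- c(charcot = 2L, diabetic = 2L, control = 2L)
  spec$scans_per_subject <- 2L
  spec$scan$scan_length <- 300
  for (g in names(spec$presets)) {
    for (cond in names(spec$presets[[g]])) {
      p <- spec$presets[[g]][[cond]]
      spec$presets[[g]][[cond]] <- synthetic_preset(
        pits_per_mm = p$pits_per_mm,
        dent_mixture = p$dent_mixture,
        depth_median = p$depth_median,
        width_median = 8,
        planar_median = p$planar_median
      )
    }
  }
  spec
}
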