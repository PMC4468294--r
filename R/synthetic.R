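#' Generative parameters of one group x condition cell
#'
#' A preset describes the pit population a Dektak scan of one culture
#' condition would see: a Poisson pit density along the scan, a mixture
#' over dent counts (1, 2, 3+; 3+ resolved uniformly over 3 or 4), a
#' log-normal depth and per-dent width distribution, the relative height
#' of the internal ridges of compound pits, the surface roughness, and the
#' median planar resorbed fraction used for mask generation.
#'
#' Defaults are the Charcot M-CSF + RANKL cell; see [default_presets] for
#' the full calibrated cohort.
#'
#' @param pits_per_mm Expected pit density (count per mm of scan).
#' @param dent_mixture Probabilities of 1, 2 and 3+ dents; must sum to 1.
#' @param depth_median,depth_log_sd Log-normal dent depth (median um,
#'   log-sd).
#' @param width_median,width_log_sd Log-normal per-dent width (median um,
#'   log-sd).
#' @param ridge_relief Internal ridges of compound pits rise to within
#'   `ridge_relief * min(adjacent dent depths)` of the baseline.
#' @param noise_sigma Gaussian surface roughness (um).
#' @param planar_median Median planar resorbed area (%) for mask
#'   generation.
#' @return A list of class `synthetic_preset`.
#' @export
synthetic_preset <- function(pits_per_mm = 7.5,
                             dent_mixture = c(0.36, 0.24, 0.40),
                             depth_median = 3.5, depth_log_sd = 0.35,
                             width_median = 25, width_log_sd = 0.30,
                             ridge_relief = 0.05,
                             noise_sigma = 0.02,
                             planar_median = 20) {
  if (abs(sum(dent_mixture) - 1) > 1e-9 || any(dent_mixture < 0)) {
    rlang::abort("dent_mixture must be non-negative and sum to 1",
                 class = "pitscan_validation_error")
  }
  if (any(c(depth_median, width_median) <= 0) || pits_per_mm < 0 ||
        noise_sigma < 0 || planar_median < 0) {
    rlang::abort("preset scale parameters must be positive",
                 class = "pitscan_validation_error")
  }
  if (ridge_relief <= 0 || ridge_relief >= 1) {
    rlang::abort("ridge_relief must be in (0, 1)",
                 class = "pitscan_validation_error")
  }
  structure(
    list(
      pits_per_mm = pits_per_mm,
      dent_mixture = unname(dent_mixture),
      depth_median = depth_median, depth_log_sd = depth_log_sd,
      width_median = width_median, width_log_sd = width_log_sd,
      ridge_relief = ridge_relief,
      noise_sigma = noise_sigma,
      planar_median = planar_median
    ),
    class = "synthetic_preset"
  )
}

#' Calibrated default presets for the three study groups
#'
#' Dent-count mixtures for the Charcot cells are set to the reported
#' shape distributions (36/24/40 % under M-CSF + RANKL, 53/22/25 % under
#' anti-TNF); diabetic and control cells share the post-anti-TNF mixture
#' in both conditions (the anti-TNF treatment has no effect outside the
#' Charcot group). Charcot RANKL pits are deeper and wider than all other
#' cells, and the Charcot anti-TNF planar median is 0.7x the RANKL value
#' (a 30 % reduction). Depth/width scales are package defaults, not
#' literature-anchored values.
#'
#' @return A nested list `presets[[group]][[condition]]` of
#'   [synthetic_preset] objects.
#' @export
default_presets <- function() {
  normalised <- function(planar) {
    synthetic_preset(
      dent_mixture = c(0.53, 0.22, 0.25),
      depth_median = 2.0, width_median = 18,
      planar_median = planar
    )
  }
  list(
    charcot = list(
      rankl = synthetic_preset(),  # 0.36/0.24/0.40, deep and wide
      rankl_anti_tnf = synthetic_preset(
        dent_mixture = c(0.53, 0.22, 0.25),
        depth_median = 2.2, width_median = 18,
        planar_median = 14
      )
    ),
    diabetic = list(
      rankl = normalised(8),
      rankl_anti_tnf = normalised(8)
    ),
    control = list(
      rankl = normalised(8),
      rankl_anti_tnf = normalised(8)
    )
  )
}

#' Deterministic seed splitting
#'
#' Mixes a master seed with structural indices (group, subject, condition,
#' disc, scan) into a 31-bit seed by iterated polynomial hashing, so any
#' subset of a cohort can be regenerated without replaying global RNG
#' state.
#'
#' @param ... Integers to mix (master seed first).
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(...) {
  vals <- as.double(c(...))
  x <- 0
  for (v in vals) {
    x <- (x * 1000003 + (v %% 1000003)) %% 2147483629
  }
  as.integer(x)
}

#' Draw one synthetic pit shape
#'
#' The dent count is drawn from the preset mixture; each dent is a
#' raised-cosine bump (compact support, analytic area `depth * width / 2`)
#' with its own log-normal depth and width. Dents are combined by
#' pointwise maximum of their height deficits, spaced so each internal
#' ridge rises to exactly `ridge_relief * min(adjacent dent depths)` below
#' the baseline.
#'
#' @param preset A [synthetic_preset].
#' @return A list of class `synthetic_pit`: `dent_count`, `shape_class`,
#'   `depths`, `widths`, `centers` (um, relative to the left edge),
#'   `extent` (total support width, um), `max_depth`.
#' @export
sample_pit <- function(preset) {
  k <- sample.int(3L, 1L, prob = preset$dent_mixture)
  if (k == 3L) k <- sample(3:4, 1L)
  d <- stats::rlnorm(k, log(preset$depth_median), preset$depth_log_sd)
  w <- stats::rlnorm(k, log(preset$width_median), preset$width_log_sd)

  # distance from a dent centre at which its deficit equals r
  t_off <- function(dd, ww, r) {
    (ww / (2 * pi)) * acos(pmin(1, pmax(-1, 2 * r / dd - 1)))
  }
  centers <- numeric(k)
  if (k > 1L) {
    for (j in 2:k) {
      r <- preset$ridge_relief * min(d[j - 1L], d[j])
      centers[j] <- centers[j - 1L] +
        t_off(d[j - 1L], w[j - 1L], r) + t_off(d[j], w[j], r)
    }
  }
  left <- centers[1L] - w[1L] / 2
  centers <- centers - left
  structure(
    list(
      dent_count = k,
      shape_class = shape_class_of(k),
      depths = d, widths = w, centers = centers,
      extent = centers[k] + w[k] / 2,
      max_depth = max(d)
    ),
    class = "synthetic_pit"
  )
}

#' Evaluate the height deficit of a synthetic pit
#'
#' @param pit A [sample_pit] result.
#' @param x Positions (um) in the pit's own coordinates (0 = left edge).
#' @return Deficit (um, >= 0) at each `x`.
#' @export
pit_deficit <- function(pit, x) {
  out <- numeric(length(x))
  for (j in seq_len(pit$dent_count)) {
    t <- x - pit$centers[j]
    inside <- abs(t) <= pit$widths[j] / 2
    if (any(inside)) {
      b <- (pit$depths[j] / 2) *
        (1 + cos(2 * pi * t[inside] / pit$widths[j]))
      out[inside] <- pmax(out[inside], b)
    }
  }
  out
}

default_scan <- function() {
  list(scan_length = 1000, sample_interval = 0.056, vertical_range = 65.5)
}

#' Generate one synthetic profilometry trace with ground truth
#'
#' Pit count is Poisson with mean `pits_per_mm * scan_length / 1000`;
#' pits are placed uniformly with at least `min_gap` um between extents by
#' rejection (up to 100 redraws each, then the pit is dropped). Heights
#' are `level` minus the summed pit deficits plus Gaussian noise.
#'
#' @param preset A [synthetic_preset].
#' @param scan Scan metadata: list with `scan_length`, `sample_interval`,
#'   `vertical_range` (um). Defaults to the Dektak settings
#'   (1000 / 0.056 / 65.5).
#' @param seed Optional integer seed (set with [set.seed] when given).
#' @param level Baseline height (um), default 0.
#' @param min_gap Minimum gap between pit extents (um).
#' @param source_id Identifier stored in the trace.
#' @return A list with `trace` (a [pit_trace]) and `truth`, a tibble of
#'   the placed pits (`start`, `end`, `center`, `width`, `dent_count`,
#'   `shape_class`, `max_depth`).
#' @export
generate_trace <- function(preset, scan = default_scan(), seed = NULL,
                           level = 0, min_gap = 5, source_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  L <- scan$scan_length
  pos <- seq(0, L, by = scan$sample_interval)
  n <- length(pos)

  n_target <- stats::rpois(1L, preset$pits_per_mm * L / 1000)
  deficit <- numeric(n)
  truth <- list()
  dropped <- 0L
  placed <- matrix(numeric(0), ncol = 2L)

  for (i in seq_len(n_target)) {
    pit <- sample_pit(preset)
    ok <- FALSE
    if (pit$extent < L) {
      for (try in seq_len(100L)) {
        s <- stats::runif(1L, 0, L - pit$extent)
        e <- s + pit$extent
        if (nrow(placed) == 0L ||
              all(e + min_gap <= placed[, 1L] | s - min_gap >= placed[, 2L])) {
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) {
      dropped <- dropped + 1L
      next
    }
    placed <- rbind(placed, c(s, e))
    i1 <- max(1L, ceiling(s / scan$sample_interval) + 1L)
    i2 <- min(n, floor(e / scan$sample_interval) + 1L)
    idx <- i1:i2
    deficit[idx] <- pmax(deficit[idx], pit_deficit(pit, pos[idx] - s))
    truth[[length(truth) + 1L]] <- tibble::tibble(
      start = s, end = e, center = (s + e) / 2, width = pit$extent,
      dent_count = pit$dent_count, shape_class = pit$shape_class,
      max_depth = pit$max_depth
    )
  }
  if (n_target > 0L && dropped > n_target / 2) {
    rlang::abort(
      sprintf("pit placement infeasible: %d of %d pits rejected; lower pits_per_mm or pit widths",
              dropped, n_target),
      class = "pitscan_validation_error"
    )
  }

  noise <- if (preset$noise_sigma > 0) {
    stats::rnorm(n, 0, preset$noise_sigma)
  } else {
    numeric(n)
  }
  trace <- pit_trace(
    pos, level - deficit + noise,
    scan_length = L, sample_interval = scan$sample_interval,
    vertical_range = scan$vertical_range, source_id = source_id
  )
  truth <- if (length(truth) > 0L) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$start)
  } else {
    tibble::tibble(start = double(), end = double(), center = double(),
                   width = double(), dent_count = integer(),
                   shape_class = factor(character(),
                                        levels = pit_shape_classes),
                   max_depth = double())
  }
  list(trace = trace, truth = truth)
}

#' Generate a planar resorption mask
#'
#' Random ellipses (log-normal semi-axes, axis-aligned) are rasterized
#' onto a square grid until the resorbed fraction reaches the target
#' percentage.
#'
#' @param preset A [synthetic_preset]; the target defaults to its
#'   `planar_median`.
#' @param seed Optional integer seed.
#' @param grid_size Mask edge length in pixels (default 512).
#' @param target_percent Resorbed-area target (%); must be < 80 (beyond
#'   that, overlapping-ellipse coverage is no longer a physical pit
#'   pattern).
#' @return A list with `mask` (a [planar_mask]) and `fraction_percent`,
#'   the exact rasterized resorbed percentage.
#' @export
generate_surface_mask <- function(preset, seed = NULL, grid_size = 512L,
                                  target_percent = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target_percent)) target_percent <- preset$planar_median
  if (target_percent >= 80) {
    rlang::abort("target resorbed fraction must be < 80%",
                 class = "pitscan_validation_error")
  }
  g <- as.integer(grid_size)
  mask <- matrix(FALSE, g, g)
  target <- target_percent / 100
  r_med <- 0.035 * g  # median semi-axis, px
  guard <- 0L
  while (mean(mask) < target && guard < 10000L) {
    guard <- guard + 1L
    a <- stats::rlnorm(1L, log(r_med), 0.3)
    b <- stats::rlnorm(1L, log(r_med), 0.3)
    cx <- stats::runif(1L, 1, g)
    cy <- stats::runif(1L, 1, g)
    rows <- max(1L, floor(cx - a)):min(g, ceiling(cx + a))
    cols <- max(1L, floor(cy - b)):min(g, ceiling(cy + b))
    inside <- outer(((rows - cx) / a)^2, ((cols - cy) / b)^2, `+`) <= 1
    mask[rows, cols] <- mask[rows, cols] | inside
  }
  mk <- planar_mask(mask, pixel_size = 1)
  list(mask = mk, fraction_percent = 100 * mean(mask))
}

#' Apply between-subject jitter to a preset
#'
#' Multiplies the scale parameters (pit density, depth and width medians,
#' planar median) by independent log-normal factors and jitters the
#' dent-count mixture multiplicatively with renormalisation.
#'
#' @param preset A [synthetic_preset].
#' @param jitter_sd Log-sd of the multiplicative jitter (default 0.15).
#' @return A jittered `synthetic_preset`.
#' @export
jitter_preset <- function(preset, jitter_sd = 0.15) {
  if (jitter_sd <= 0) return(preset)
  f <- stats::rlnorm(4L, 0, jitter_sd)
  mix <- preset$dent_mixture * stats::rlnorm(3L, 0, jitter_sd)
  synthetic_preset(
    pits_per_mm = preset$pits_per_mm * f[1L],
    dent_mixture = mix / sum(mix),
    depth_median = preset$depth_median * f[2L],
    depth_log_sd = preset$depth_log_sd,
    width_median = preset$width_median * f[3L],
    width_log_sd = preset$width_log_sd,
    ridge_relief = preset$ridge_relief,
    noise_sigma = preset$noise_sigma,
    planar_median = min(79, preset$planar_median * f[4L])
  )
}

cohort_design <- function(n_subjects = c(charcot = 10, diabetic = 8,
                                         control = 9),
                          scans_per_subject = 10L, discs = 2L) {
  groups <- names(n_subjects)
  disc_of <- rep_len(seq_len(discs), scans_per_subject)
  scan_in_disc <- stats::ave(disc_of, disc_of, FUN = seq_along)
  purrr::imap(as.list(n_subjects), function(ns, g) {
    gi <- match(g, groups)
    tidyr::expand_grid(
      group = g, group_idx = gi, subject_idx = seq_len(ns),
      cond_idx = seq_along(pit_conditions),
      scan_slot = seq_len(scans_per_subject)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      subject_id = sprintf("%s_%02d", .data$group, .data$subject_idx),
      condition = pit_conditions[.data$cond_idx],
      disc_index = disc_of[.data$scan_slot],
      scan_index = scan_in_disc[.data$scan_slot]
    )
}

#' Generate a full synthetic cohort
#'
#' Emulates the study design: three groups (default 10 Charcot, 8
#' diabetic, 9 control subjects), two culture conditions, and
#' `scans_per_subject` Dektak scans per subject split over `discs` bone
#' discs, plus one planar resorption mask per subject x condition.
#' Per-subject generating parameters are jittered copies of the cell
#' preset; every trace and mask gets its own seed derived from the master
#' seed by [derive_seed], so the output is fully deterministic and any
#' subset can be regenerated independently.
#'
#' @param presets Nested list `presets[[group]][[condition]]` of
#'   [synthetic_preset]s; default [default_presets()].
#' @param n_subjects Named integer vector of subjects per group.
#' @param scans_per_subject Scans per subject (pooled over discs).
#' @param discs Number of discs per subject.
#' @param jitter_sd Between-subject log-normal jitter sd.
#' @param seed Master seed (integer).
#' @param scan Scan metadata (see [generate_trace]).
#' @param config When a [pit_config] is supplied, every trace is analyzed
#'   as it is generated and the detected pit table is returned.
#' @param keep_traces Keep the generated traces in memory (`TRUE` for
#'   writing them out later; set `FALSE` for large multi-seed loops).
#' @param masks Generate planar masks (`TRUE` by default).
#' @param traces Generate traces at all (`FALSE` for mask-only planar
#'   studies; seed derivation is unaffected).
#' @return A list with `manifest`, `traces` (named list of [pit_trace] or
#'   `NULL`), `truth` (generated pit table with design columns),
#'   `subject_truth` (per subject x condition generating parameters and
#'   planar target), `planar` (tibble of realized mask fractions),
#'   `masks` (named list of [planar_mask] or `NULL`), and `pit_table`
#'   (detected pits; only when `config` is given).
#' @export
generate_cohort <- function(presets = default_presets(),
                            n_subjects = c(charcot = 10, diabetic = 8,
                                           control = 9),
                            scans_per_subject = 10L, discs = 2L,
                            jitter_sd = 0.15, seed = 1L,
                            scan = default_scan(),
                            config = NULL, keep_traces = TRUE,
                            masks = TRUE, traces = TRUE) {
  for (g in names(n_subjects)) {
    for (cond in pit_conditions) {
      if (is.null(presets[[g]][[cond]])) {
        rlang::abort(
          sprintf("missing preset for cell %s / %s", g, cond),
          class = "pitscan_validation_error"
        )
      }
    }
  }
  design <- cohort_design(n_subjects, scans_per_subject, discs)

  gen_traces <- isTRUE(traces)
  trace_store <- if (keep_traces && gen_traces) list() else NULL
  mask_list <- if (masks) list() else NULL
  truth_rows <- list()
  pit_rows <- list()
  subject_rows <- list()
  planar_rows <- list()

  cells <- dplyr::distinct(design, .data$group, .data$group_idx,
                           .data$subject_idx, .data$subject_id,
                           .data$cond_idx, .data$condition)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    base_preset <- presets[[cell$group]][[cell$condition]]
    set.seed(derive_seed(seed, cell$group_idx, cell$subject_idx,
                         cell$cond_idx, 0, 0))
    preset <- jitter_preset(base_preset, jitter_sd)
    subject_rows[[ci]] <- tibble::tibble(
      subject_id = cell$subject_id, group = cell$group,
      condition = cell$condition,
      pits_per_mm = preset$pits_per_mm,
      mix_unidented = preset$dent_mixture[1L],
      mix_bidented = preset$dent_mixture[2L],
      mix_multidented = preset$dent_mixture[3L],
      depth_median = preset$depth_median,
      width_median = preset$width_median,
      planar_target = preset$planar_median
    )

    if (masks) {
      mres <- generate_surface_mask(
        preset, seed = derive_seed(seed, cell$group_idx, cell$subject_idx,
                                   cell$cond_idx, 99, 0))
      planar_rows[[ci]] <- tibble::tibble(
        subject_id = cell$subject_id, group = cell$group,
        condition = cell$condition,
        planar_pct = mres$fraction_percent
      )
      mask_list[[paste(cell$subject_id, cell$condition, sep = "_")]] <-
        mres$mask
    }

    rows <- design[design$subject_id == cell$subject_id &
                     design$condition == cell$condition, ]
    if (!gen_traces) next
    for (ri in seq_len(nrow(rows))) {
      row <- rows[ri, ]
      trace_id <- sprintf("%s_%s_d%d_s%02d", row$subject_id, row$condition,
                          row$disc_index, row$scan_index)
      gt <- generate_trace(
        preset, scan = scan,
        seed = derive_seed(seed, row$group_idx, row$subject_idx,
                           row$cond_idx, row$disc_index, row$scan_index),
        source_id = trace_id
      )
      if (nrow(gt$truth) > 0L) {
        truth_rows[[trace_id]] <- dplyr::mutate(
          gt$truth, trace_id = trace_id, subject_id = row$subject_id,
          group = row$group, condition = row$condition, .before = 1L
        )
      }
      if (keep_traces) trace_store[[trace_id]] <- gt$trace
      if (!is.null(config)) {
        fit <- tryCatch(analyze_trace(gt$trace, config),
                        pitscan_baseline_error = function(e) NULL)
        if (!is.null(fit) && nrow(fit$pits) > 0L) {
          pit_rows[[trace_id]] <- dplyr::mutate(
            fit$pits, trace_id = trace_id, subject_id = row$subject_id,
            group = row$group, condition = row$condition, .before = 1L
          )
        }
      }
    }
  }

  manifest <- design |>
    dplyr::mutate(
      trace_path = file.path("traces", sprintf(
        "%s_%s_d%d_s%02d.txt", .data$subject_id, .data$condition,
        .data$disc_index, .data$scan_index))
    ) |>
    dplyr::select("trace_path", "subject_id", "group", "condition",
                  "disc_index", "scan_index")

  list(
    manifest = manifest,
    traces = trace_store,
    truth = dplyr::bind_rows(truth_rows),
    subject_truth = dplyr::bind_rows(subject_rows),
    planar = if (masks) dplyr::bind_rows(planar_rows) else NULL,
    masks = mask_list,
    pit_table = if (!is.null(config)) dplyr::bind_rows(pit_rows) else NULL,
    seed = seed
  )
}

#' Simulate a cohort and analyze it in one pass
#'
#' Streaming convenience for recovery studies: generates the cohort with
#' [generate_cohort] while analyzing each trace as it appears (traces are
#' not kept), then aggregates to subject summaries.
#'
#' @inheritParams generate_cohort
#' @param config A [pit_config] used for the analysis.
#' @return A list with `summaries` (per subject x condition,
#'   [summarize_cohort]), `pit_table`, `truth`, `subject_truth`, `planar`.
#' @export
simulate_and_analyze <- function(presets = default_presets(),
                                 n_subjects = c(charcot = 10, diabetic = 8,
                                                control = 9),
                                 scans_per_subject = 10L, discs = 2L,
                                 jitter_sd = 0.15, seed = 1L,
                                 scan = default_scan(),
                                 config = pit_config(), masks = TRUE) {
  sim <- generate_cohort(
    presets, n_subjects, scans_per_subject, discs, jitter_sd, seed,
    scan = scan, config = config, keep_traces = FALSE, masks = masks
  )
  summaries <- summarize_cohort(sim$pit_table, planar = sim$planar,
                                config = config)
  list(
    summaries = summaries,
    pit_table = sim$pit_table,
    truth = sim$truth,
    subject_truth = sim$subject_truth,
    planar = sim$planar
  )
}
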