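#' Default cohort specification
#'
#' The full run configuration of the simulate-analyze-stats pipeline:
#' cohort sizes (10 Charcot, 8 diabetic, 9 control subjects), two culture
#' conditions, ten 1000-um scans per subject over two discs, the
#' calibrated per-cell presets, and the detection parameters.
#'
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      n_subjects = c(charcot = 10L, diabetic = 8L, control = 9L),
      scans_per_subject = 10L,
      discs = 2L,
      jitter_sd = 0.15,
      scan = default_scan(),
      presets = default_presets(),
      detection = pit_config(seed = as.integer(seed))
    ),
    class = "cohort_spec"
  )
}

#' Read a cohort specification from YAML or JSON
#'
#' Absent fields take the [default_cohort_spec] values; preset cells are
#' given as `presets: {group: {condition: {param: value, ...}}}` and
#' every group x condition cell must be present once any preset is
#' overridden.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` spec.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cohort spec not found: %s", path),
                 class = "pitscan_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- default_cohort_spec()
  for (key in c("seed", "scans_per_subject", "discs", "jitter_sd")) {
    if (!is.null(raw[[key]])) spec[[key]] <- raw[[key]]
  }
  if (!is.null(raw$n_subjects)) {
    spec$n_subjects <- unlist(raw$n_subjects)
  }
  if (!is.null(raw$scan)) {
    spec$scan <- utils::modifyList(spec$scan, raw$scan)
  }
  if (!is.null(raw$detection)) {
    keep <- intersect(names(raw$detection), names(formals(pit_config)))
    spec$detection <- do.call(pit_config, raw$detection[keep])
  }
  if (!is.null(raw$presets)) {
    spec$presets <- list()
    for (g in names(n_subjects_names(spec))) {
      for (cond in pit_conditions) {
        cellraw <- raw$presets[[g]][[cond]]
        if (is.null(cellraw)) {
          rlang::abort(
            sprintf("cohort spec missing preset for cell %s / %s", g, cond),
            class = "pitscan_validation_error"
          )
        }
        keep <- intersect(names(cellraw), names(formals(synthetic_preset)))
        args <- cellraw[keep]
        if (!is.null(args$dent_mixture)) {
          args$dent_mixture <- unlist(args$dent_mixture)
        }
        spec$presets[[g]][[cond]] <- do.call(synthetic_preset, args)
      }
    }
  }
  spec
}

n_subjects_names <- function(spec) {
  stats::setNames(as.list(spec$n_subjects), names(spec$n_subjects))
}

write_pgm <- function(mask, path) {
  g <- matrix(as.integer(mask), nrow = nrow(mask))
  writeLines(c(
    "P2", paste(ncol(g), nrow(g)), "1",
    apply(g, 1L, paste, collapse = " ")
  ), path)
  invisible(path)
}

log_msg <- function(log_path, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the trace files, the cohort manifest, the generated pit ground
#' truth, the per-subject generating parameters, the planar masks (ASCII
#' PGM) with their realized fractions, and the resolved spec.
#'
#' @param spec A `cohort_spec` ([default_cohort_spec]) or a path to a
#'   YAML/JSON spec.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return The run report (list), invisibly.
#' @export
run_simulate <- function(spec = default_cohort_spec(), out_dir,
                         seed = NULL) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")

  sim <- generate_cohort(
    presets = spec$presets, n_subjects = spec$n_subjects,
    scans_per_subject = spec$scans_per_subject, discs = spec$discs,
    jitter_sd = spec$jitter_sd, seed = spec$seed, scan = spec$scan,
    keep_traces = TRUE, masks = TRUE
  )

  for (nm in names(sim$traces)) {
    write_trace(sim$traces[[nm]],
                file.path(out_dir, "traces", paste0(nm, ".txt")))
  }
  write_manifest(sim$manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "truth_pits.csv"),
                   progress = FALSE)
  readr::write_csv(sim$subject_truth,
                   file.path(out_dir, "subject_truth.csv"), progress = FALSE)
  readr::write_csv(sim$planar, file.path(out_dir, "planar_truth.csv"),
                   progress = FALSE)
  for (nm in names(sim$masks)) {
    write_pgm(sim$masks[[nm]],
              file.path(out_dir, "masks", paste0(nm, ".pgm")))
  }
  resolved <- unclass(spec)
  resolved$detection <- unclass(resolved$detection)
  resolved$presets <- purrr::map(resolved$presets, ~ purrr::map(.x, unclass))
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- list(
    stage = "simulate", seed = spec$seed,
    n_traces = length(sim$traces),
    n_manifest_rows = nrow(sim$manifest),
    n_generated_pits = nrow(sim$truth),
    n_masks = length(sim$masks)
  )
  log_msg(log_path, "simulate: %d traces, %d generated pits, %d masks (seed %d)",
          report$n_traces, report$n_generated_pits, report$n_masks,
          spec$seed)
  jsonlite::write_json(report, file.path(out_dir, "simulate_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Analyze every trace of a cohort manifest
#'
#' Runs [analyze_trace] per manifest row (traces failing baseline
#' estimation are skipped with a logged reason, not fatal), writes the
#' combined pit table and the per-subject summaries.
#'
#' @param manifest_path Path to the manifest CSV; trace paths are resolved
#'   relative to its directory.
#' @param config A [pit_config] or path to one.
#' @param out_dir Output directory.
#' @param planar_path Optional CSV of planar percentages (`subject_id`,
#'   `condition`, `planar_pct`), e.g. the `planar_truth.csv` from
#'   [run_simulate].
#' @return The run report, invisibly.
#' @export
run_analyze <- function(manifest_path, config = pit_config(), out_dir,
                        planar_path = NULL) {
  if (is.character(config)) config <- read_pit_config(config)
  manifest <- read_manifest(manifest_path)
  root <- dirname(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")

  skipped <- list()
  pit_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    tpath <- row$trace_path
    if (!file.exists(tpath)) tpath <- file.path(root, row$trace_path)
    trace_id <- sub("\\.[^.]+$", "", basename(row$trace_path))
    fit <- tryCatch(
      analyze_trace(read_trace(tpath), config),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      skipped[[trace_id]] <- fit
      log_msg(log_path, "skipped %s: %s", trace_id, fit)
      next
    }
    if (nrow(fit$pits) > 0L) {
      pit_rows[[trace_id]] <- dplyr::mutate(
        fit$pits, trace_id = trace_id, subject_id = row$subject_id,
        group = row$group, condition = row$condition, .before = 1L
      )
    }
  }
  pit_table <- dplyr::bind_rows(pit_rows)
  if (nrow(pit_table) == 0L) {
    rlang::abort("no pits detected in any trace",
                 class = "pitscan_validation_error")
  }
  planar <- if (!is.null(planar_path)) {
    readr::read_csv(planar_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  summaries <- summarize_cohort(pit_table, planar = planar, config = config)

  out_pits <- pit_table |>
    dplyr::transmute(
      trace_id = .data$trace_id, pit_index = .data$pit,
      start_um = .data$start, end_um = .data$end, width_um = .data$width,
      depth_um = .data$depth, fwhm_um = .data$fwhm, area_um2 = .data$area,
      dent_count = .data$dent_count,
      shape_class = as.character(.data$shape_class),
      subject_id = .data$subject_id, group = .data$group,
      condition = .data$condition
    )
  readr::write_csv(out_pits, file.path(out_dir, "pits.csv"),
                   progress = FALSE)
  readr::write_csv(summaries, file.path(out_dir, "subject_summaries.csv"),
                   progress = FALSE)

  report <- list(
    stage = "analyze",
    n_manifest_rows = nrow(manifest),
    n_analyzed = nrow(manifest) - length(skipped),
    n_skipped = length(skipped),
    skipped = skipped,
    n_pits = nrow(pit_table),
    n_summaries = nrow(summaries)
  )
  log_msg(log_path, "analyze: %d/%d traces analyzed (%d skipped), %d pits, %d summaries",
          report$n_analyzed, report$n_manifest_rows, report$n_skipped,
          report$n_pits, report$n_summaries)
  jsonlite::write_json(report, file.path(out_dir, "analyze_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the cohort statistics on subject summaries
#'
#' Executes [compare_groups] and [shape_distribution] and writes the
#' comparison table (CSV + JSON) and a human-readable report.
#'
#' @param summaries_path Path to `subject_summaries.csv` (or a summaries
#'   tibble).
#' @param config A [pit_config] or path to one.
#' @param out_dir Output directory.
#' @return The run report, invisibly.
#' @export
run_stats <- function(summaries_path, config = pit_config(), out_dir) {
  if (is.character(config)) config <- read_pit_config(config)
  summaries <- if (is.character(summaries_path)) {
    readr::read_csv(summaries_path, show_col_types = FALSE, progress = FALSE)
  } else {
    summaries_path
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")

  comparisons <- compare_groups(summaries, config)
  if (all(comparisons$flag == "insufficient n")) {
    rlang::abort("nothing to compare: fewer than 2 subjects in every cell",
                 class = "pitscan_validation_error")
  }
  dist <- shape_distribution(summaries)

  readr::write_csv(tibble::as_tibble(comparisons),
                   file.path(out_dir, "comparisons.csv"), progress = FALSE)
  readr::write_csv(dist, file.path(out_dir, "shape_distribution.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(alpha = config$alpha,
         comparisons = tibble::as_tibble(comparisons),
         shape_distribution = dist),
    file.path(out_dir, "comparisons.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  sig <- comparisons[!is.na(comparisons$significant) &
                       comparisons$significant, ]
  txt <- c(
    sprintf("pitscan comparison report (alpha = %g)", config$alpha),
    sprintf("%d subject summaries, %d comparison rows, %d significant",
            nrow(summaries), nrow(comparisons), nrow(sig)),
    "",
    "significant rows:",
    sprintf("  %-28s %-34s %-24s p = %.4g",
            sig$endpoint, sig$comparison, sig$scope, sig$p_value)
  )
  writeLines(txt, file.path(out_dir, "report.txt"))

  report <- list(
    stage = "stats",
    n_summaries = nrow(summaries),
    n_rows = nrow(comparisons),
    n_tested = sum(comparisons$flag == ""),
    n_significant = nrow(sig),
    alpha = config$alpha
  )
  log_msg(log_path, "stats: %d rows (%d tested, %d significant at %g)",
          report$n_rows, report$n_tested, report$n_significant,
          config$alpha)
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the full simulate - analyze - stats pipeline
#'
#' @param spec A `cohort_spec` or path to one.
#' @param out_dir Output directory; stages write into `simulate/`,
#'   `analyze/`, `stats/` subdirectories.
#' @param seed Optional master-seed override.
#' @return A list of the three stage reports, invisibly.
#' @export
run_pipeline <- function(spec = default_cohort_spec(), out_dir,
                         seed = NULL) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  sim_dir <- file.path(out_dir, "simulate")
  ana_dir <- file.path(out_dir, "analyze")
  sta_dir <- file.path(out_dir, "stats")
  rep1 <- run_simulate(spec, sim_dir)
  rep2 <- run_analyze(file.path(sim_dir, "manifest.csv"), spec$detection,
                      ana_dir,
                      planar_path = file.path(sim_dir, "planar_truth.csv"))
  rep3 <- run_stats(file.path(ana_dir, "subject_summaries.csv"),
                    spec$detection, sta_dir)
  invisible(list(simulate = rep1, analyze = rep2, stats = rep3))
}
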