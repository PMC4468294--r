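#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reporting `U = min(U1, U2)` with ties counted
#' one half. The p-value is exact (full enumeration of rank assignments)
#' when `n1 + n2 <= 12` and there are no ties, otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble of class `pit_test`: `test`, `statistic`,
#'   `p_value`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y) {
  x <- as.double(x)
  y <- as.double(y)
  if (length(x) == 0L || length(y) == 0L) {
    rlang::abort("both samples must be non-empty",
                 class = "pitscan_validation_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    rlang::abort("samples must be finite", class = "pitscan_validation_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u1 <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  has_ties <- anyDuplicated(pooled) > 0L

  if (stats::var(pooled) == 0) {
    p <- 1
    method <- "degenerate (all values equal)"
  } else if (!has_ties && n1 + n2 <= 12L) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    if (!is.finite(p)) p <- 1
    method <- "normal approximation, tie and continuity corrected"
  }
  new_pit_test("mann_whitney_u", u, p, c(n1, n2), method)
}

#' Kruskal-Wallis test
#'
#' Rank-based k-sample test with tie correction; the p-value comes from
#' the chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A one-row `pit_test` tibble.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    rlang::abort("need a list of >= 2 groups",
                 class = "pitscan_validation_error")
  }
  if (any(lengths(groups) == 0L)) {
    rlang::abort("every group must be non-empty",
                 class = "pitscan_validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    rlang::abort("samples must be finite", class = "pitscan_validation_error")
  }
  if (stats::var(values) == 0) {
    return(new_pit_test("kruskal_wallis", 0, 1, lengths(groups),
                        "degenerate (all values equal)"))
  }
  kt <- stats::kruskal.test(groups)
  new_pit_test("kruskal_wallis", unname(kt$statistic), kt$p.value,
               lengths(groups),
               sprintf("chi-square approximation, df = %d",
                       unname(kt$parameter)))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; the p-value comes from the chi-square
#' distribution with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table A matrix of non-negative counts with no zero row or
#'   column margin.
#' @return A one-row `pit_test` tibble.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || anyNA(tab)) {
    rlang::abort("counts must be non-negative",
                 class = "pitscan_validation_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("zero row/column margin: expected counts must be positive",
                 class = "pitscan_validation_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_pit_test("chi_square", unname(ct$statistic), ct$p.value,
               rowSums(tab),
               sprintf("Pearson, no continuity correction, df = %d",
                       unname(ct$parameter)))
}

new_pit_test <- function(test, statistic, p_value, n, method) {
  out <- tibble::tibble(
    test = test,
    statistic = as.double(statistic),
    p_value = min(1, max(0, as.double(p_value))),
    n = paste(n, collapse = ","),
    method = method
  )
  class(out) <- c("pit_test", class(out))
  out
}

#' Compare the cohort's groups and culture conditions endpoint by endpoint
#'
#' Reproduces the study's statistical design on subject-level summaries:
#' for every endpoint (per-class median width/depth/FWHM, median erosion
#' area, planar resorbed %, and the per-class shape percentages) it runs a
#' three-group Kruskal-Wallis per condition, pairwise between-group
#' Mann-Whitney tests per condition, and within-group between-condition
#' Mann-Whitney tests. No multiple-testing adjustment is applied; each row
#' is flagged significant at `config$alpha`. Cells with fewer than two
#' non-missing subjects are flagged `insufficient n` and not tested.
#'
#' @param summaries A subject-summary tibble ([summarize_cohort]).
#' @param config A [pit_config].
#' @return A tibble of class `pit_comparison`: `endpoint`, `comparison`,
#'   `scope`, `test`, `statistic`, `p_value`, `n`, `significant`, `flag`.
#' @export
compare_groups <- function(summaries, config = pit_config()) {
  endpoints <- intersect(
    c("pct_unidented", "pct_bidented", "pct_multidented", "median_area",
      "median_width_unidented", "median_depth_unidented",
      "median_fwhm_unidented", "median_width_bidented",
      "median_depth_bidented", "median_fwhm_bidented",
      "median_width_multidented", "median_depth_multidented",
      "median_fwhm_multidented", "planar_pct"),
    names(summaries)
  )
  groups_here <- intersect(pit_groups, unique(summaries$group))
  conds_here <- intersect(pit_conditions, unique(summaries$condition))

  cell_values <- function(ep, g, cond) {
    v <- summaries[[ep]][summaries$group == g & summaries$condition == cond]
    v[!is.na(v)]
  }
  skipped_row <- function(ep, comparison, scope, test, ns) {
    tibble::tibble(endpoint = ep, comparison = comparison, scope = scope,
                   test = test, statistic = NA_real_, p_value = NA_real_,
                   n = paste(ns, collapse = ","), significant = NA,
                   flag = "insufficient n")
  }
  test_row <- function(ep, comparison, scope, result) {
    tibble::tibble(endpoint = ep, comparison = comparison, scope = scope,
                   test = result$test, statistic = result$statistic,
                   p_value = result$p_value, n = result$n,
                   significant = result$p_value < config$alpha,
                   flag = "")
  }

  rows <- list()
  for (ep in endpoints) {
    # drop endpoints with no data at all (e.g. planar_pct absent)
    if (all(is.na(summaries[[ep]]))) next
    for (cond in conds_here) {
      if (length(groups_here) >= 3L) {
        vals <- lapply(groups_here, cell_values, ep = ep, cond = cond)
        cmp <- paste(groups_here, collapse = " vs ")
        scope <- paste0("condition:", cond)
        rows[[length(rows) + 1L]] <- if (any(lengths(vals) < 2L)) {
          skipped_row(ep, cmp, scope, "kruskal_wallis", lengths(vals))
        } else {
          test_row(ep, cmp, scope, kruskal_wallis(vals))
        }
      }
      if (length(groups_here) >= 2L) {
        pairs <- utils::combn(groups_here, 2L, simplify = FALSE)
        for (pr in pairs) {
          a <- cell_values(ep, pr[1L], cond)
          b <- cell_values(ep, pr[2L], cond)
          cmp <- paste(pr, collapse = " vs ")
          scope <- paste0("condition:", cond)
          rows[[length(rows) + 1L]] <- if (length(a) < 2L || length(b) < 2L) {
            skipped_row(ep, cmp, scope, "mann_whitney_u",
                        c(length(a), length(b)))
          } else {
            test_row(ep, cmp, scope, mann_whitney_u(a, b))
          }
        }
      }
    }
    if (length(conds_here) == 2L) {
      for (g in groups_here) {
        a <- cell_values(ep, g, conds_here[1L])
        b <- cell_values(ep, g, conds_here[2L])
        cmp <- paste(conds_here, collapse = " vs ")
        scope <- paste0("group:", g)
        rows[[length(rows) + 1L]] <- if (length(a) < 2L || length(b) < 2L) {
          skipped_row(ep, cmp, scope, "mann_whitney_u",
                      c(length(a), length(b)))
        } else {
          test_row(ep, cmp, scope, mann_whitney_u(a, b))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    rlang::abort("nothing to compare: fewer than 2 subjects in every cell",
                 class = "pitscan_validation_error")
  }
  class(out) <- c("pit_comparison", class(tibble::tibble()))
  attr(out, "alpha") <- config$alpha
  out
}
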