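test_that("Mann-Whitney U matches hand-checked exact cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 of the C(6,3) rank assignments
  expect_equal(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$statistic, 1)
  expect_equal(r2$p_value, 2 / 3)  # 2 * P(rank sum of x <= 4) = 4/6

  # identical constant samples cannot differ
  r3 <- mann_whitney_u(rep(5, 4), rep(5, 4))
  expect_equal(r3$p_value, 1)

  expect_error(mann_whitney_u(c(1, NA), c(2, 3)), "finite")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney is symmetric in its samples", {
  set.seed(51)
  for (rep in 1:10) {
    x <- sample(100, sample(3:8, 1))
    y <- sample(200:300, sample(3:8, 1))
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("exact p equals full enumeration for all n1, n2 <= 5", {
  set.seed(52)
  for (n1 in 2:5) {
    for (n2 in 2:5) {
      vals <- sample(1000, n1 + n2)  # no ties
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      got <- mann_whitney_u(x, y)
      expect_equal(got$statistic, enum_mw_u(x, y))
      expect_equal(got$p_value, enum_mw_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(53)
  x <- runif(8)
  y <- runif(10) + 0.3
  f <- function(v) exp(3 * v) + 1
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(f(x), f(y))$p_value)
  g1 <- list(runif(5), runif(6) + 0.2, runif(4) - 0.1)
  g2 <- lapply(g1, f)
  expect_equal(kruskal_wallis(g1)$statistic,
               kruskal_wallis(g2)$statistic)
})

test_that("Kruskal-Wallis matches the hand-evaluated H", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney deviate", {
  set.seed(54)
  x <- sample(1000, 7)
  y <- sample(2000:3000, 9)
  h <- kruskal_wallis(list(x, y))$statistic
  n1 <- length(x)
  n2 <- length(y)
  u1 <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- (u1 - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("chi-square matches the 2x2 closed form", {
  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  # the cohort's gender table: charcot 6:4 vs control 5:3
  gender <- matrix(c(6, 5, 4, 3), 2)
  r <- chi_square(gender)
  expect_equal(r$statistic, 72 / 6160, tolerance = 1e-12)
  expect_gt(r$p_value, 0.05)  # demographics not significantly different

  expect_equal(chi_square(matrix(c(10, 0, 0, 10), 2))$statistic, 20)

  set.seed(55)
  for (rep in 1:10) {
    m <- matrix(sample(1:30, 4), 2)
    expect_equal(chi_square(m)$statistic, chisq_2x2(m), tolerance = 1e-10)
  }
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("compare_groups covers the full factorial design", {
  set.seed(56)
  pits <- fake_pits(c(1, 1, 2, 3), widths = runif(4, 10, 30))
  rows <- list()
  for (g in c("charcot", "diabetic", "control")) {
    for (cond in c("rankl", "rankl_anti_tnf")) {
      for (s in 1:3) {
        p <- fake_pits(sample(1:3, 20, replace = TRUE),
                       widths = runif(20, 10, 30),
                       depths = runif(20, 1, 5),
                       fwhms = runif(20, 4, 15),
                       areas = runif(20, 10, 80))
        rows[[length(rows) + 1]] <- summarize_subject(
          p, sprintf("%s_%d", g, s), g, cond,
          planar_percent = runif(1, 5, 25)
        )
      }
    }
  }
  summaries <- dplyr::bind_rows(rows)
  cmp <- compare_groups(summaries)
  # 14 endpoints x (2 KW + 6 pairwise MW + 3 condition MW) rows
  expect_equal(nrow(cmp), 14 * 11)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
  expect_setequal(unique(cmp$test),
                  c("kruskal_wallis", "mann_whitney_u"))
  g <- generics::glance(cmp)
  expect_equal(g$n_rows, 154)
  expect_equal(g$alpha, 0.05)
})

test_that("identical cells yield p = 1 everywhere and cells of one are flagged", {
  base <- summarize_subject(fake_pits(c(1, 1, 2, 3)), "s", "g", "c")
  rows <- list()
  for (g in c("charcot", "diabetic", "control")) {
    for (cond in c("rankl", "rankl_anti_tnf")) {
      for (s in 1:2) {
        r <- base
        r$subject_id <- sprintf("%s_%d", g, s)
        r$group <- g
        r$condition <- cond
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  summaries <- dplyr::bind_rows(rows)
  cmp <- compare_groups(summaries)
  tested <- cmp[cmp$flag == "", ]
  expect_true(all(tested$p_value == 1))
  expect_true(all(!tested$significant))

  # single-subject cells are not tested
  cmp2 <- compare_groups(summaries[summaries$subject_id != "charcot_2", ])
  flagged <- cmp2[cmp2$flag == "insufficient n", ]
  expect_gt(nrow(flagged), 0)
  expect_true(all(is.na(flagged$p_value)))
})
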