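test_that("degenerate mixtures force the dent count", {
  set.seed(71)
  p1 <- synthetic_preset(dent_mixture = c(1, 0, 0))
  expect_true(all(replicate(50, sample_pit(p1)$dent_count) == 1))
  p2 <- synthetic_preset(dent_mixture = c(0, 1, 0))
  expect_true(all(replicate(50, sample_pit(p2)$dent_count) == 2))
})

test_that("internal ridges rise to the requested relief", {
  set.seed(72)
  p <- synthetic_preset(dent_mixture = c(0, 1, 0), ridge_relief = 0.05,
                        depth_log_sd = 0, width_log_sd = 0)
  for (rep in 1:10) {
    pit <- sample_pit(p)
    x <- seq(0, pit$extent, by = 0.01)
    d <- pit_deficit(pit, x)
    # the ridge is the interior local minimum between the two dent centres
    mid <- x > pit$centers[1] & x < pit$centers[2]
    ridge <- min(d[mid])
    # the sampled minimum sits within half a grid step of the kink
    expect_equal(ridge, 0.05 * min(pit$depths), tolerance = 0.01)
  }
})

test_that("mixture frequencies are recovered over many draws", {
  set.seed(73)
  p <- synthetic_preset(dent_mixture = c(0.5, 0.25, 0.25))
  draws <- replicate(10000, sample_pit(p)$dent_count)
  freq <- c(mean(draws == 1), mean(draws == 2), mean(draws >= 3))
  expect_true(all(abs(freq - c(0.5, 0.25, 0.25)) < 0.02))
  # 3+ resolved uniformly over 3 and 4
  expect_equal(mean(draws == 3) / mean(draws >= 3), 0.5, tolerance = 0.1)
})

test_that("zero density gives a flat noisy trace and empty truth", {
  g <- generate_trace(synthetic_preset(pits_per_mm = 0), seed = 74)
  expect_equal(nrow(g$truth), 0)
  expect_lt(diff(range(g$trace$height)), 10 * 0.02 * 2)
  expect_equal(nrow(generics::tidy(analyze_trace(g$trace))), 0)
})

test_that("a noiseless single pit round-trips through the analyzer", {
  set.seed(75)
  p <- synthetic_preset(dent_mixture = c(1, 0, 0), noise_sigma = 0,
                        pits_per_mm = 1, depth_log_sd = 0, width_log_sd = 0,
                        depth_median = 6, width_median = 30)
  # walk the seed forward until the Poisson draw places at least one pit
  g <- generate_trace(p, seed = 75)
  s <- 75
  while (nrow(g$truth) < 1) {
    s <- s + 1
    g <- generate_trace(p, seed = s)
  }
  pits <- generics::tidy(analyze_trace(g$trace))
  expect_equal(nrow(pits), nrow(g$truth))
  # raised-cosine of depth d, base width w: area = d*w/2, fwhm = w/2
  expect_equal(pits$depth[1], 6, tolerance = 1e-3)
  expect_equal(pits$width[1], 30, tolerance = 0.1)
  expect_equal(pits$fwhm[1], 15, tolerance = 0.1)
  expect_equal(pits$area[1], 6 * 30 / 2, tolerance = 0.5)
})

test_that("pit counts follow the Poisson budget over ten scans", {
  total <- 0
  for (s in 1:10) {
    g <- generate_trace(synthetic_preset(), seed = 760 + s)
    total <- total + nrow(g$truth)
  }
  expect_lt(abs(total - 75), 3 * sqrt(75))
})

test_that("infeasible densities error instead of thrashing", {
  p <- synthetic_preset(pits_per_mm = 60, width_median = 60,
                        width_log_sd = 0)
  expect_error(generate_trace(p, seed = 77), "infeasible",
               class = "pitscan_validation_error")
})

test_that("cohort generation is deterministic and correctly sized", {
  a <- generate_cohort(n_subjects = c(charcot = 2, control = 2),
                       scans_per_subject = 2, seed = 78,
                       scan = list(scan_length = 200,
                                   sample_interval = 0.056,
                                   vertical_range = 65.5))
  b <- generate_cohort(n_subjects = c(charcot = 2, control = 2),
                       scans_per_subject = 2, seed = 78,
                       scan = list(scan_length = 200,
                                   sample_interval = 0.056,
                                   vertical_range = 65.5))
  expect_equal(length(a$traces), 2 * 2 * 2 * 2)  # subjects x cond x scans
  expect_equal(nrow(a$manifest), 16)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  expect_identical(a$planar, b$planar)

  # the default design arithmetic: (10 + 8 + 9) x 2 x 10 = 540 rows
  default_manifest <- generate_cohort(seed = 1, traces = FALSE,
                                      masks = FALSE)$manifest
  expect_equal(nrow(default_manifest), 540)
})

test_that("zero jitter makes subjects in a cell identical", {
  a <- generate_cohort(n_subjects = c(charcot = 3), scans_per_subject = 1,
                       jitter_sd = 0, seed = 79, traces = FALSE,
                       masks = FALSE)
  st <- a$subject_truth
  for (col in c("pits_per_mm", "mix_unidented", "depth_median")) {
    expect_equal(length(unique(st[[col]][st$condition == "rankl"])), 1)
  }
})

test_that("missing preset cells are rejected by name", {
  p <- default_presets()
  p$diabetic$rankl_anti_tnf <- NULL
  expect_error(
    generate_cohort(p, n_subjects = c(charcot = 1, diabetic = 1),
                    scans_per_subject = 1, traces = FALSE, masks = FALSE),
    "diabetic / rankl_anti_tnf"
  )
})

test_that("masks hit their target fraction and agree with the area measure", {
  p0 <- synthetic_preset(planar_median = 0)
  m0 <- generate_surface_mask(p0, seed = 80)
  expect_equal(m0$fraction_percent, 0)
  expect_equal(resorbed_area_percent(m0$mask), 0)

  m1 <- generate_surface_mask(synthetic_preset(planar_median = 15),
                              seed = 81)
  expect_equal(resorbed_area_percent(m1$mask), m1$fraction_percent)
  expect_gte(m1$fraction_percent, 15)

  expect_error(generate_surface_mask(synthetic_preset(planar_median = 15),
                                     target_percent = 85),
               "80", class = "pitscan_validation_error")

  # sample median of realized fractions sits near the target
  set.seed(82)
  fr <- vapply(1:100, function(i) {
    generate_surface_mask(synthetic_preset(planar_median = 10),
                          grid_size = 256)$fraction_percent
  }, 0)
  expect_lt(abs(median(fr) - 10), 1.5)
})

test_that("deeper presets yield deeper recovered pits (paired seeds)", {
  shallow <- synthetic_preset(depth_median = 2)
  deep <- synthetic_preset(depth_median = 4)
  med_depth <- function(preset) {
    d <- numeric(0)
    for (s in 1:4) {
      g <- generate_trace(preset, seed = 8300 + s)
      d <- c(d, generics::tidy(analyze_trace(g$trace))$depth)
    }
    median(d)
  }
  expect_gt(med_depth(deep), med_depth(shallow))
})

test_that("seed derivation is stable and within integer range", {
  s1 <- derive_seed(1, 2, 3, 4, 5, 6)
  expect_identical(s1, derive_seed(1, 2, 3, 4, 5, 6))
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
})
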