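test_that("a triangular pit yields the analytic geometry", {
  # triangle width 20, depth 8 on a zero baseline: boundaries at 100 and
  # 120, fwhm = w/2 = 10, area = w*d/2 = 80
  tr <- triangle_trace(x0 = 100, width = 20, depth = 8, by = 0.1,
                       from = 0, to = 220)
  fit <- analyze_trace(tr)
  pits <- generics::tidy(fit)
  expect_equal(nrow(pits), 1L)
  expect_lt(abs(pits$start - 100), 0.1)
  expect_lt(abs(pits$end - 120), 0.1)
  expect_equal(pits$width, 20, tolerance = 0.01)
  expect_equal(pits$depth, 8, tolerance = 1e-9)
  expect_equal(pits$fwhm, 10, tolerance = 0.01)
  expect_equal(pits$area, 80, tolerance = 0.001)
  expect_equal(pits$dent_count, 1L)
  expect_equal(as.character(pits$shape_class), "unidented")
})

test_that("a flat-bottomed pit has fwhm equal to its width", {
  # rectangle width 12, depth 5 with one-sample ramps; fwhm ~ width,
  # area ~ w*d = 60
  v <- list(x = c(100, 100.1, 112 - 0.1, 112), y = c(0, -5, -5, 0))
  tr <- piecewise_trace(v, from = 50, to = 170, by = 0.1)
  pits <- generics::tidy(analyze_trace(tr))
  expect_equal(nrow(pits), 1L)
  expect_equal(pits$fwhm, 12, tolerance = 0.2)
  expect_equal(pits$width, 12, tolerance = 0.2)
  expect_equal(pits$area, 60, tolerance = 0.01)
  expect_equal(pits$depth, 5)
})

test_that("a Gaussian dent matches its closed-form FWHM and area", {
  pos <- seq(0, 400, by = 0.056)
  ctr <- 200
  sd_um <- 5
  h <- -10 * exp(-(pos - ctr)^2 / (2 * sd_um^2))
  tr <- pit_trace(pos, h)
  pits <- generics::tidy(analyze_trace(tr))
  expect_equal(nrow(pits), 1L)
  fwhm_true <- 2 * sd_um * sqrt(2 * log(2))  # 11.774
  area_true <- 10 * sd_um * sqrt(2 * pi)     # 125.33
  expect_lt(abs(pits$fwhm - fwhm_true), 2 * 0.056)
  expect_lt(abs(pits$area - area_true) / area_true, 0.01)
  # the grid does not sample the apex exactly
  expect_equal(pits$depth, 10, tolerance = 1e-4)
})

test_that("separated pits segment into ordered disjoint extents", {
  # two depth-6 triangles separated by 50 um of flat baseline
  v1 <- triangle_trace(x0 = 100, width = 20, depth = 6, by = 0.1,
                       from = 0, to = 300)
  h <- v1$height
  pos <- v1$position
  seg <- pos >= 170 & pos <= 190
  h[seg] <- approx(c(170, 180, 190), c(0, -6, 0), xout = pos[seg])$y
  tr <- pit_trace(pos, h)
  base <- estimate_baseline(tr)
  extents <- segment_pits(tr, base)
  expect_equal(nrow(extents), 2L)
  expect_true(all(diff(extents$start) > 0))
  expect_true(all(extents$end[-nrow(extents)] < extents$start[-1]))
  # agreement with the brute-force run scan on the noiseless profile
  bf <- brute_force_extents(pos, h, level = 0)
  expect_equal(extents$start, bf$start, tolerance = 0.15)
  expect_equal(extents$end, bf$end, tolerance = 0.15)
})

test_that("a flat trace yields no pits", {
  tr <- pit_trace(seq(0, 100, by = 0.1), rep(0, 1001))
  base <- estimate_baseline(tr)
  expect_equal(nrow(segment_pits(tr, base)), 0L)
  set.seed(31)
  trn <- pit_trace(seq(0, 1000, by = 0.056),
                   rnorm(17858, 3, 0.02))
  expect_equal(nrow(generics::tidy(analyze_trace(trn))), 0L)
})

test_that("dent counting splits on near-surface ridges only", {
  # W pit, lobes of depth 6, ridge rising to -0.1: ridge_tolerance is
  # max(2*sigma, 0.1 * 6) = 0.6, so the ridge separates two dents
  tr <- w_pit_trace(ridge_drop = 0.1, by = 0.1, from = 0, to = 220)
  pits <- generics::tidy(analyze_trace(tr))
  expect_equal(nrow(pits), 1L)
  expect_equal(pits$dent_count, 2L)
  expect_equal(as.character(pits$shape_class), "bidented")

  # same shape but the ridge only rises to -3.0: no separation
  tr2 <- w_pit_trace(ridge_drop = 3.0, by = 0.1, from = 0, to = 220)
  pits2 <- generics::tidy(analyze_trace(tr2))
  expect_equal(nrow(pits2), 1L)
  expect_equal(pits2$dent_count, 1L)
  expect_equal(as.character(pits2$shape_class), "unidented")

  # exhaustive local-maximum oracle agrees on both constructed profiles
  for (drop in c(0.1, 3.0)) {
    trx <- w_pit_trace(ridge_drop = drop, by = 0.1, from = 0, to = 220)
    inside <- trx$position > 100 & trx$position < 120
    oracle <- brute_force_dents(trx$height[inside], level = 0, tol = 0.6)
    got <- generics::tidy(analyze_trace(trx))$dent_count
    expect_equal(got, oracle)
  }
})

test_that("degenerate extents are rejected by count_dents", {
  tr <- triangle_trace(by = 0.1, from = 0, to = 220)
  base <- estimate_baseline(tr)
  expect_error(
    count_dents(tr, list(i1 = 10L, i2 = 12L), base),
    "degenerate", class = "pitscan_validation_error"
  )
})

test_that("composition matches per-pit measurement, with and without noise", {
  clean <- three_pit_trace(by = 0.056)
  fit <- analyze_trace(clean)
  pits <- generics::tidy(fit)
  expect_equal(nrow(pits), 3L)
  # triangle apexes fall between samples: depth error <= slope * dx / 2
  expect_equal(pits$depth, c(8, 4, 6), tolerance = 0.005)
  expect_equal(pits$width, c(20, 12, 24), tolerance = 0.01)
  expect_equal(pits$fwhm, c(10, 6, 12), tolerance = 0.01)
  expect_equal(pits$area, c(80, 24, 72), tolerance = 0.001)

  noisy <- three_pit_trace(by = 0.056, noise_sd = 0.05, seed = 7)
  pits_n <- generics::tidy(analyze_trace(noisy))
  expect_equal(nrow(pits_n), 3L)
  expect_equal(pits_n$dent_count, pits$dent_count)
  for (col in c("width", "depth", "fwhm", "area")) {
    expect_lt(max(abs(pits_n[[col]] - pits[[col]]) / pits[[col]]), 0.05)
  }
})

test_that("resorbed area percentage is the resorbed pixel fraction", {
  m0 <- planar_mask(matrix(FALSE, 100, 100))
  expect_equal(resorbed_area_percent(m0), 0)

  half <- matrix(FALSE, 100, 100)
  half[1:50, ] <- TRUE
  expect_equal(resorbed_area_percent(planar_mask(half)), 50)

  # disc of radius 50 px in a 500 x 500 grid: 100 * pi * 50^2 / 250000
  g <- 500
  xy <- expand.grid(x = 1:g, y = 1:g)
  disc <- matrix((xy$x - 250.5)^2 + (xy$y - 250.5)^2 <= 50^2, g, g)
  got <- resorbed_area_percent(planar_mask(disc))
  expect_lt(abs(got - 100 * pi * 50^2 / g^2), 0.05)

  expect_error(planar_mask(matrix(TRUE, 10, 10)), "unresorbed")
  expect_error(planar_mask(matrix(FALSE, 10, 10), pixel_size = 0),
               "pixel_size")
})
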