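test_that("zone boundaries solve the equal-area partition in closed form", {
  b <- zone_boundaries()
  expect_equal(b$b1, (1 - sqrt(2 / 3)) / 2, tolerance = 1e-12)
  expect_equal(b$b2, (1 - sqrt(1 / 3)) / 2, tolerance = 1e-12)
  # areas of the three concentric regions of the unit-diameter disc
  area_ring <- function(r_out, r_in) pi * (r_out^2 - r_in^2)
  a1 <- area_ring(0.5, 0.5 - b$b1)
  a2 <- area_ring(0.5 - b$b1, 0.5 - b$b2)
  a3 <- pi * (0.5 - b$b2)^2
  expect_lt(max(abs(c(a1, a2, a3) - pi * 0.25 / 3)), 1e-12)
  expect_lt(max(abs(c(a1 - a2, a2 - a3, a1 - a3))), 1e-9)
})

test_that("spot ratios are distance over diameter, with spots outside the nucleus rejected", {
  expect_equal(spot_ratio(0.2, 2.0), 0.10)
  expect_equal(spot_ratio(0.0, 2.0), 0.0)
  expect_equal(spot_ratio(1.0, 2.0), 0.5)
  expect_error(spot_ratio(1.1, 2.0), "outside nucleus")
  expect_error(spot_ratio(-0.1, 2.0))
  expect_error(spot_ratio(0.2, 0))
})

test_that("zone assignment uses half-open bins with boundary ties going inward", {
  b <- zone_boundaries()
  expect_identical(assign_zone(0.0), 1L)
  expect_identical(assign_zone(0.5), 3L)
  expect_identical(assign_zone(0.15), 2L) # b1 < 0.15 < b2
  expect_identical(assign_zone(b$b1), 2L)
  expect_identical(assign_zone(b$b2), 3L)
  expect_identical(assign_zone(b$b1 - 1e-12), 1L)
  expect_error(assign_zone(0.51), "out of range")
  expect_error(assign_zone(-0.01), "out of range")
})

test_that("zone tabulation counts one spot per zone and conserves n under grouping", {
  spots <- data.frame(
    cell_id = c("a", "b", "c"),
    stage = c("G1", "S", "G1"),
    distance_um = c(0.0, 0.3, 1.0),
    diameter_um = 2.0
  )
  tab <- tabulate_zones(spots)
  expect_equal(c(tab$z1, tab$z2, tab$z3), c(1L, 1L, 1L))
  expect_equal(tab$n, 3L)
  by_stage <- tabulate_zones(spots, group_by = "stage")
  expect_setequal(by_stage$group, c("G1", "S"))
  expect_equal(sum(by_stage$n), 3L)
})

test_that("measurements with distance beyond the radius are dropped with a warning, not clamped", {
  spots <- data.frame(
    cell_id = c("ok1", "bad", "ok2"),
    distance_um = c(0.2, 1.4, 0.9),
    diameter_um = 2.0
  )
  expect_warning(tab <- tabulate_zones(spots), "bad")
  expect_equal(tab$n, 2L)
  expect_error(suppressWarnings(
    tabulate_zones(data.frame(distance_um = 1.4, diameter_um = 2.0))
  ), "no valid measurements")
})

test_that("chi-squared vs the uniform null matches hand computation and the df-2 closed form", {
  r0 <- zone_test_random(c(100, 100, 100))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  r <- zone_test_random(c(60, 20, 20))
  expect_equal(r$chi2, 32.0, tolerance = 1e-12)
  expect_equal(r$p, exp(-16), tolerance = 1e-9)
  expect_equal(sum(r$percentages), 100)

  # closed form p = exp(-chi2/2) and agreement with stats::chisq.test,
  # across random count triples
  set.seed(11)
  for (i in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, sample(30:500, 1), c(0.5, 0.3, 0.2)))
    if (any(cnt == 0)) next
    z <- zone_test_random(cnt)
    expect_equal(z$p, exp(-z$chi2 / 2), tolerance = 1e-9)
    ref <- suppressWarnings(stats::chisq.test(cnt, p = rep(1 / 3, 3)))
    expect_equal(z$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(z$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(zone_test_random(c(0, 0, 0)), "n = 0")
})

test_that("between-group chi-squared detects a shifted distribution and is null on identical counts", {
  same <- zone_test_between(c(60, 20, 20), c(60, 20, 20))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_identical(same$df, 2L)

  diff <- zone_test_between(c(60, 20, 20), c(20, 40, 40))
  expect_lt(diff$p, 0.001)
  ref <- stats::chisq.test(rbind(c(60, 20, 20), c(20, 40, 40)),
                           correct = FALSE)
  expect_equal(diff$chi2, unname(ref$statistic), tolerance = 1e-12)

  expect_error(zone_test_between(c(0, 0, 0), c(1, 1, 1)), "n > 0")
  expect_error(zone_test_between(c(5, 5, 0), c(7, 3, 0)), "zero total")
  expect_warning(zone_test_between(c(3, 3, 3), c(2, 4, 3)), "below 5")
})

test_that("between-group test p-values are uniform when both groups share one distribution", {
  sp <- simulate_spots(spot_sim_config(n_cells = 400L * 500L,
                                       zone_probs = c(0.5, 0.3, 0.2),
                                       seed = 915L))
  zone <- assign_zone(spot_ratio(sp$distance_um, sp$diameter_um))
  zm <- matrix(zone, nrow = 400L)
  ps <- vapply(seq_len(ncol(zm)), function(j) {
    a <- tabulate(zm[1:200, j], nbins = 3)
    b <- tabulate(zm[201:400, j], nbins = 3)
    zone_test_between(a, b)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("exact binomial colocalization test reproduces the clustered-pore result and the enumeration oracle", {
  res <- coloc_test(72, 322, p0 = 0.09)
  expect_equal(res$percent, 22.4, tolerance = 0.05)
  expect_lt(res$p, 0.01)

  # observed equal to expectation: p near 1
  near <- coloc_test(round(322 * 0.09), 322, p0 = 0.09)
  expect_gt(near$p, 0.5)

  # brute-force oracle: two-sided p sums all outcomes no more probable
  # than the observed one
  k <- 3L; n <- 10L; p0 <- 0.09
  d <- stats::dbinom(0:n, n, p0)
  p_oracle <- sum(d[d <= d[k + 1L] * (1 + 1e-7)])
  expect_equal(coloc_test(k, n, p0)$p, p_oracle, tolerance = 1e-12)

  expect_error(coloc_test(5, 3), "k <= n")
  expect_error(coloc_test(-1, 3))
  expect_error(coloc_test(1, 10, p0 = 1), "p0")
})
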