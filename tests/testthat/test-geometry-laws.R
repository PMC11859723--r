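test_that("inscribed-polygon area fractions match closed forms and limits", {
  expect_equal(polygon_inside_fraction(4), 2 / pi, tolerance = 1e-12)
  expect_equal(polygon_inside_fraction(6), 3 * sqrt(3) / (2 * pi), tolerance = 1e-12)
  expect_equal(polygon_outside_fraction(3), 1 - 3 * sqrt(3) / (4 * pi), tolerance = 1e-12)
  expect_equal(polygon_outside_fraction(4), 1 - 2 / pi, tolerance = 1e-12)
  expect_equal(polygon_inside_fraction(1e6), 1, tolerance = 1e-10)

  n <- 3:50
  expect_equal(polygon_inside_fraction(n) + polygon_outside_fraction(n),
               rep(1, length(n)))
  expect_true(all(diff(polygon_inside_fraction(n)) > 0))
  expect_true(all(diff(polygon_outside_fraction(n)) < 0))
  # successive outside-area losses shrink monotonically from the square on
  expect_true(all(diff(diff(polygon_outside_fraction(4:30))) > 0))
})

test_that("degenerate polygons (monogon, digon) are rejected by name", {
  expect_error(polygon_inside_fraction(2), "digon")
  expect_error(polygon_outside_fraction(1), "monogon")
  expect_error(polygon_inside_fraction(3.5), "whole")
})

test_that("Monte-Carlo estimator agrees with the closed form and is reproducible", {
  # 1e5 samples: binomial SE ~ 0.0016; allow 4 SEs
  for (n in c(3L, 4L, 7L)) {
    p <- polygon_outside_fraction(n)
    se <- sqrt(p * (1 - p) / 1e5)
    est <- monte_carlo_outside_fraction(n, samples = 1e5, seed = 11)
    expect_lt(abs(est - p), 4 * se)
  }
  expect_identical(monte_carlo_outside_fraction(5, 1e4, seed = 3),
                   monte_carlo_outside_fraction(5, 1e4, seed = 3))
  # independent slow oracle: lattice-grid area fraction
  expect_equal(grid_outside_fraction(4), polygon_outside_fraction(4),
               tolerance = 5e-3)
})

test_that("outside-fraction series extrapolates the singular ranks monotonically", {
  s <- outside_fraction_series(12, "extrapolate")
  expect_identical(s$ranks, 1:12)
  expect_true(all(diff(s$values) < 0))
  expect_equal(s$values[3:12], polygon_outside_fraction(3:12))
  # the conjectural monogon/digon values sit near the printed 0.67 / 0.50
  expect_lt(abs(s$values[1] - 0.67), 0.15)
  expect_lt(abs(s$values[2] - 0.50), 0.15)

  omit <- outside_fraction_series(8, "omit")
  expect_identical(omit$ranks, 3:8)
  expect_error(outside_fraction_series(2), "max_rank")
})

test_that("rank-law values reproduce printed points and structural identities", {
  expect_equal(zipf_value(5), 0.20)
  expect_equal(zipf_value(1, a = 2.7), 1)
  expect_equal(round(caulokit:::round_half_up(zipf_value(8), 2), 2), 0.13)
  r <- 1:20
  expect_equal(r * zipf_value(r), rep(1, 20))

  expect_equal(metalaw_value(3), exp(-1), tolerance = 1e-12)
  ratios <- metalaw_value(r + 1L) / metalaw_value(r)
  expect_equal(ratios, rep(exp(-1 / 3), 20), tolerance = 1e-12)

  expect_equal(zipf_mandelbrot_value(2, shift = 0, exponent = 1), 0.5)
  expect_equal(zipf_mandelbrot_value(1, shift = 1, exponent = 1), 0.5)
  expect_true(all(diff(zipf_mandelbrot_value(1:10, shift = 2.5, exponent = 1.3)) < 0))
  expect_error(zipf_value(0), ">= 1")
})

test_that("trendline fits recover exact generating parameters", {
  meta <- rank_series(1:12, metalaw_value(1:12), "metalaw")
  fit <- fit_trendline(meta, "exponential")
  expect_equal(fit$rate_or_exponent, -1 / 3, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  zipf <- rank_series(1:12, zipf_value(1:12), "zipf")
  pfit <- fit_trendline(zipf, "power")
  expect_equal(pfit$rate_or_exponent, -1, tolerance = 1e-10)
  expect_equal(pfit$r_squared, 1, tolerance = 1e-12)

  # the exact geometric series is close to, but not exactly, either family;
  # frozen r-squared values computed from the same transformed-scale fits
  geo <- outside_fraction_series(12, "omit")
  expect_equal(fit_trendline(geo, "exponential")$r_squared, 0.9727, tolerance = 1e-3)
  expect_equal(fit_trendline(geo, "power")$r_squared, 0.9992, tolerance = 1e-3)

  expect_error(fit_trendline(rank_series(1:3, c(1, 0, 1)), "power"), "positive")
  expect_error(fit_trendline(rank_series(1:2, c(2, 1)), "power"), "at least 3")
})

test_that("fitted trendlines evaluate through predict()", {
  fit <- fit_trendline(rank_series(1:10, 2 * exp(-0.5 * (1:10))), "exponential")
  expect_equal(predict(fit, 1:10), 2 * exp(-0.5 * (1:10)), tolerance = 1e-8)
  pfit <- fit_trendline(rank_series(1:10, 3 / (1:10)^2), "power")
  expect_equal(predict(pfit, c(1L, 5L)), c(3, 3 / 25), tolerance = 1e-8)
})

test_that("curve comparison scores RMSE per law and picks the argmin", {
  cmp <- compare_to_laws(rank_series(1:12, printed_geometric, "geometric"))
  expect_equal(cmp$best_label, "metalaw")
  expect_lt(cmp$per_law_rmse[["metalaw"]], cmp$per_law_rmse[["zipf"]])

  self_z <- compare_to_laws(rank_series(1:10, zipf_value(1:10), "zipf"))
  expect_equal(self_z$per_law_rmse[["zipf"]], 0)
  expect_equal(self_z$best_label, "zipf")
  self_m <- compare_to_laws(rank_series(1:10, metalaw_value(1:10), "metalaw"))
  expect_equal(self_m$per_law_rmse[["metalaw"]], 0)

  expect_error(compare_to_laws(rank_series(3:6, 1 / (3:6))), "rank 1")
})

test_that("the comparison table carries exact and extrapolated geometric columns", {
  tab <- build_table1(12)
  expect_identical(names(tab),
                   c("rank", "outside_exact", "outside_extrapolated", "zipf", "metalaw"))
  expect_true(all(is.na(tab$outside_exact[1:2])))
  expect_equal(tab$outside_exact[3:12],
               caulokit:::round_half_up(polygon_outside_fraction(3:12), 2))
  expect_false(anyNA(tab$outside_extrapolated))
  expect_error(build_table1(2), "max_rank")
})
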