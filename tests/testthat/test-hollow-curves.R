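test_that("size histograms are dense, conservative and guard their domain", {
  d <- size_histogram(c(1, 1, 2, 5))
  expect_identical(unname(d$histogram), c(2L, 1L, 0L, 0L, 1L))
  expect_identical(names(d$histogram), as.character(1:5))
  expect_equal(sum(d$histogram), length(d$sizes))

  empty <- size_histogram(integer(0))
  expect_length(empty$sizes, 0)
  expect_length(empty$histogram, 0)

  expect_error(size_histogram(c(1, 0)), ">= 1")
})

test_that("fraction_at_most is a monotone CDF over sizes", {
  d <- size_histogram(c(rep(1, 8), 6, 6))
  expect_equal(fraction_at_most(d, 5), 0.8)
  expect_equal(fraction_at_most(size_histogram(c(1, 1, 2, 5)), 5), 1)
  fr <- vapply(1:10, function(k) fraction_at_most(d, k), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[10], 1)
  expect_true(is.nan(fraction_at_most(size_histogram(integer(0)), 5)))
})

test_that("hollow classification separates power, exponential and rising shapes", {
  sizes <- 1:8
  power_counts <- round(240 / sizes)
  d_pow <- size_histogram(rep(sizes, times = power_counts))
  cls <- classify_hollow(d_pow)
  expect_true(cls$is_hollow)
  expect_identical(cls$best_family, "power")

  exp_counts <- round(300 * exp(-sizes / 3))
  d_exp <- size_histogram(rep(sizes, times = exp_counts))
  cls2 <- classify_hollow(d_exp)
  expect_true(cls2$is_hollow)
  expect_identical(cls2$best_family, "exponential")
  # exact exponential counts fit their own family essentially perfectly
  expect_gt(cls2$fits$exponential$r_squared, 0.99)

  rising <- size_histogram(rep(1:5, times = 1:5))
  expect_false(classify_hollow(rising)$is_hollow)

  expect_error(classify_hollow(size_histogram(c(1, 1, 2))), ">= 3 distinct")
})

test_that("fractal dimension reproduces the 5:4 burst and simple identities", {
  expect_equal(round(fractal_dimension(5, 4), 2), 1.16)
  expect_equal(fractal_dimension(4, 4), 1)
  expect_equal(fractal_dimension(16, 4), 2)
  expect_error(fractal_dimension(5, 1), ">= 2")
  expect_error(fractal_dimension(3, 4), "must be >=")
})

test_that("rule-of-five probability matches closed form and the bracketing oracle", {
  expect_equal(rule_of_five_probability(5), 0.9375)
  expect_equal(rule_of_five_probability(1), 0)
  # Monte-Carlo bracketing at modest trials across n; 4 binomial SEs
  for (n in c(2L, 3L, 5L, 8L)) {
    p <- rule_of_five_probability(n)
    trials <- 2e5
    est <- mc_bracketing_probability(n, trials, seed = 40 + n)
    expect_lt(abs(est - p), 4 * sqrt(p * (1 - p) / trials) + 1e-9)
  }
  expect_error(rule_of_five_probability(0), ">= 1")
})

test_that("paraphyly summaries reproduce hand arithmetic", {
  rec <- data.frame(
    species_id = c("a", "b", "c"),
    race_count = c(2L, 4L, 6L),
    paraphyletic = c(TRUE, TRUE, FALSE),
    apophyletic_count = c(3L, 4L, 0L),
    max_node_distance = c(2L, 6L, 0L))
  s <- paraphyly_summary(rec)
  expect_equal(s$n_species, 3)
  expect_equal(s$total_races, 12)
  expect_equal(s$mean_races, 4)
  expect_equal(s$n_paraphyletic_species, 2)
  expect_equal(s$paraphyletic_fraction, 2 / 3)
  expect_equal(s$apophyletic_per_paraphyletic, 3.5)
  expect_equal(s$mean_node_distance, 4)

  solo <- paraphyly_summary(data.frame(
    species_id = "x", race_count = 3L, paraphyletic = FALSE,
    apophyletic_count = 0L, max_node_distance = 0L))
  expect_equal(solo$mean_races, 3)
  expect_equal(solo$n_paraphyletic_species, 0)
  expect_true(is.na(solo$apophyletic_per_paraphyletic))

  bad <- rec
  bad$apophyletic_count[3] <- 2L
  expect_error(paraphyly_summary(bad), "non-paraphyletic")
})

test_that("the synthetic moss record set carries the published marginal totals", {
  rec <- moss_paraphyly_records()
  expect_equal(nrow(rec), 46)
  s <- paraphyly_summary(rec)
  expect_equal(s$total_races, 208)
  expect_equal(s$n_paraphyletic_species, 22)
  expect_equal(s$n_apophyletic, 79)
  expect_equal(sum(rec$max_node_distance), 133)
})
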