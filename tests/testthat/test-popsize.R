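test_that("multi-locus probability is the plain power", {
  expect_equal(round(multi_locus_probability(0.46875, 2), 4), 0.2197)
  expect_identical(multi_locus_probability(0.37, 1), 0.37)
  expect_equal(multi_locus_probability(0.5, 4), 0.0625)
})

test_that("failure probability reproduces exact integer-arithmetic values", {
  # p = 1/2: lower tail as an integer count over 2^n
  expect_equal(failure_probability(32, 0.5, 1, 10), 43081973 / 2^32,
               tolerance = 1e-14)
  expect_equal(failure_probability(33, 0.5, 1, 10), 58115146 / 2^33,
               tolerance = 1e-14)
  expect_equal(failure_probability(32, 0.5, 1, 10),
               exact_cdf_dyadic(9, 32, 1, 2), tolerance = 1e-14)
  # R = 1 must agree with the closed form (1 - p^Q)^n
  for (p in c(0.1, 0.46875, 0.9)) for (n in c(0, 7, 40))
    expect_equal(failure_probability(n, p, 2, 1), (1 - p^2)^n,
                 tolerance = 1e-12)
  expect_equal(failure_probability(145, 0.5, 4, 5), 0.0477, tolerance = 1e-3)
})

test_that("n_at_least_one matches direct evaluation at the boundary", {
  res <- n_at_least_one(0.5, risk = 0.05, morgans = 0.01)
  expect_identical(res$n, 598L)
  expect_lte((1 - res$effective_p)^res$n, 0.05)
  expect_gt((1 - res$effective_p)^(res$n - 1), 0.05)
  expect_identical(n_at_least_one(1, risk = 0.05)$n, 1L)
  expect_identical(n_at_least_one(0.46875, risk = 0.01)$n, 8L)
  expect_error(n_at_least_one(0, risk = 0.05), "probability 0")
})

test_that("minimal sizes for R positives sit exactly on the risk boundary", {
  res <- population_size(0.5, 1, 10, 0.01)
  expect_identical(res$n, 33L)
  expect_lte(res$achieved_failure, 0.01)
  expect_gt(res$failure_at_n_minus_1, 0.01)
  expect_equal(res$achieved_failure, 0.006765, tolerance = 1e-3)

  bc <- population_size(0.5, 1, 2, 0.05, morgans = 0.01)
  expect_identical(bc$n, 947L)
  expect_equal(bc$effective_p, 0.005)
  expect_equal(bc$achieved_failure, 0.04998, tolerance = 1e-3)

  expect_identical(population_size(0.5, 4, 5, 0.05)$n, 144L)
})

test_that("recombinant sizing multiplies P by the map distance per locus", {
  expect_identical(recombinant_population_size(0.5, 1, 2, 0.05,
                                               morgans = 0.01)$n, 947L)
  expect_identical(recombinant_population_size(0.5, 1, 1, 0.05,
                                               morgans = 0.01)$n, 598L)
  # D = 1 Morgan leaves the probability unchanged
  expect_identical(recombinant_population_size(0.5, 2, 3, 0.05, morgans = 1)$n,
                   population_size(0.5, 2, 3, 0.05)$n)
  two <- recombinant_population_size(0.5, 2, 1, 0.05, morgans = c(0.01, 0.02))
  expect_equal(two$effective_p, 0.005 * 0.01)
  expect_error(recombinant_population_size(0.5, 1, 1, 0.05, morgans = 0),
               "Morgans")
  expect_error(recombinant_population_size(0.5, 1, 1, 0.05), "map distance")
})

test_that("naive Mendelian estimate rounds half away from zero", {
  expect_identical(naive_mendelian_n(0.46875, 2, 100), 455L)
  expect_identical(naive_mendelian_n(0.5, 1, 1), 2L)
  expect_identical(naive_mendelian_n(0.25, 1, 10), 40L)
})

test_that("expected positives is n times the effective probability", {
  expect_equal(expected_positives(145, 0.5, 4), 9.0625)
  expect_identical(round(expected_positives(145, 0.5, 4)), 9)
  expect_equal(expected_positives(455, 0.46875, 2), 100, tolerance = 1e-3)
  expect_identical(expected_positives(100, 0, 1), 0)
})

test_that("failure probability is monotone in n and in R", {
  p <- 0.3
  fail_n <- vapply(2:60, failure_probability, numeric(1),
                   p = p, n_loci = 2, n_required = 3)
  expect_true(all(diff(fail_n) < 0))
  fail_r <- vapply(1:12, function(r) failure_probability(40, p, 1, r),
                   numeric(1))
  expect_true(all(diff(fail_r) > 0))
})

test_that("R = 1 sizing coincides with the closed-form calculator on a random grid", {
  set.seed(42)
  for (i in 1:40) {
    p <- runif(1, 0.02, 0.98)
    q <- sample(1:4, 1)
    f <- runif(1, 0.001, 0.3)
    expect_identical(population_size(p, q, 1, f)$n,
                     n_at_least_one(p, q, f)$n,
                     label = sprintf("p=%.3f q=%d f=%.3f", p, q, f))
  }
})

test_that("sizing agrees with brute-force scan and dominates the naive estimate", {
  set.seed(7)
  for (i in 1:25) {
    p <- runif(1, 0.05, 0.95)
    r <- sample(1:8, 1)
    f <- runif(1, 0.005, 0.2)
    expect_identical(population_size(p, 1, r, f)$n,
                     as.integer(scan_min_n(p, r, f)),
                     label = sprintf("p=%.3f r=%d f=%.3f", p, r, f))
    expect_gte(population_size(p, 1, r, f)$n, naive_mendelian_n(p, 1, r))
  }
})

test_that("degenerate and invalid sizing inputs are handled explicitly", {
  expect_identical(population_size(1, 3, 7, 0.01)$n, 7L)
  expect_error(population_size(0, 1, 1, 0.05), "probability 0")
  expect_error(population_size(0.5, 1, 0, 0.05), ">= 1")
  expect_error(population_size(0.5, 1, 1, 1), "risk")
  expect_error(population_size(1.2, 1, 1, 0.05), "probability")
})
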