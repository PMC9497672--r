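force_bins <- function(n_bins) discretization_spec(n_bins = n_bins,
                                                   continuity_threshold = 1)

test_that("equal-frequency discretization splits at quantiles and keeps ties together", {
  s <- discretize_equal_frequency(1:10, force_bins(2))
  expect_equal(s$codes, rep(1:2, each = 5))

  const <- discretize_equal_frequency(c(7, 7, 7), force_bins(5))
  expect_equal(const$n_levels, 1L)
  expect_equal(const$codes, c(1L, 1L, 1L))

  # heavy ties: identical values never straddle a boundary
  x <- c(rep(1, 50), rep(2, 3), rep(3, 2))
  s <- discretize_equal_frequency(x, force_bins(2))
  expect_length(unique(s$codes[x == 1]), 1)
  expect_length(unique(s$codes[x == 2]), 1)

  set.seed(11)
  draws <- rnorm(100)
  s <- discretize_equal_frequency(draws, force_bins(5))
  expect_equal(s$n_levels, 5L)
  expect_true(all(tabulate(s$codes, 5) >= 18 & tabulate(s$codes, 5) <= 22))
  # deterministic: same input, same codes
  expect_identical(s$codes, discretize_equal_frequency(draws, force_bins(5))$codes)
})

test_that("discretization rejects bad input", {
  expect_error(discretize_equal_frequency(numeric(0)), "empty")
  expect_error(discretize_equal_frequency(c(1, NA, 3)), "non-finite")
  expect_error(discretize_equal_frequency(c(1, Inf)), "non-finite")
  expect_error(cat_series(integer(0)), "at least one")
  expect_error(cat_series(c(1, NA)), "missing")
})

test_that("columns below the continuity threshold pass through unbinned", {
  s <- discretize_equal_frequency(rep(1:4, 10), discretization_spec())
  expect_equal(s$n_levels, 4L)
})

test_that("entropy matches direct plug-in summation", {
  expect_equal(entropy(cat_series(c(0, 1))), 1.0)
  expect_equal(entropy(cat_series(c(0, 1, 2, 3))), 2.0)
  expect_equal(entropy(cat_series(c(0, 0, 0, 1))),
               -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4))
  # unobserved categories contribute nothing
  expect_equal(entropy(cat_series(c(5, 5, 5))), 0)
})

test_that("joint entropy and joint variables agree with enumeration of observed pairs", {
  x <- cat_series(c(0, 0, 1, 1)); y <- cat_series(c(0, 1, 0, 1))
  expect_equal(joint_entropy(x), entropy(x))
  expect_equal(joint_entropy(list(x, x)), entropy(x))
  expect_equal(joint_entropy(list(x, y)), 2.0)

  j <- joint_variable(x, y)
  expect_equal(j$n_levels, 4L)
  expect_equal(entropy(j), 2.0)
  expect_equal(joint_variable(cat_series(c(0, 1)), cat_series(c(0, 1)))$n_levels, 2L)
  b_const <- cat_series(c(1, 1, 1, 1))
  expect_equal(joint_variable(x, b_const)$codes, x$codes)
  expect_error(joint_variable(x, cat_series(0:2)), "lengths differ")
})

test_that("conditional entropy and MI follow their defining identities", {
  x <- cat_series(c(0, 0, 1, 1))
  expect_equal(conditional_entropy(x, x), 0)
  expect_equal(conditional_entropy(x, cat_series(rep(1, 4))), entropy(x))
  y <- cat_series(c(0, 1, 1, 1))
  expect_equal(conditional_entropy(x, y), brute_joint_entropy(x$codes, y$codes) -
                 brute_entropy(y$codes))

  expect_equal(mutual_information(x, x), entropy(x))
  expect_equal(mutual_information(x, cat_series(c(0, 1, 0, 1))), 0)
  expect_equal(mutual_information(x, y), brute_mi(x$codes, y$codes))
  expect_error(mutual_information(x, cat_series(0:4)), "lengths differ")
})

test_that("conditional MI matches the brute-force triple sum", {
  x <- cat_series(c(0, 0, 1, 1)); y <- cat_series(c(0, 1, 0, 1))
  z_const <- cat_series(rep(2, 4))
  expect_equal(conditional_mutual_information(x, y, z_const),
               mutual_information(x, y))
  expect_equal(conditional_mutual_information(x, y, y), 0)
  set.seed(5)
  for (rep in 1:5) {
    a <- random_codes(50, 2); b <- random_codes(50, 2); c <- random_codes(50, 2)
    expect_equal(conditional_mutual_information(cat_series(a), cat_series(b),
                                                cat_series(c)),
                 brute_cmi(a, b, c), tolerance = 1e-12)
  }
})

test_that("interaction information uses the I(X;Y) - I(X;Y|Z) convention", {
  x <- cat_series(c(0, 0, 1, 1))
  expect_equal(interaction_information(x, x, cat_series(rep(1, 4))), 0)
  one_bit <- cat_series(rep(c(0, 1), 4))
  expect_equal(interaction_information(one_bit, one_bit, one_bit), 1.0)
  # XOR triple: pure synergy
  xv <- rep(c(0L, 0L, 1L, 1L), 2); yv <- rep(c(0L, 1L, 0L, 1L), 2)
  zv <- bitwXor(xv, yv)
  expect_equal(interaction_information(cat_series(xv), cat_series(yv),
                                       cat_series(zv)), -1.0)
  # symmetric under permutations
  set.seed(9)
  a <- cat_series(random_codes(40, 3)); b <- cat_series(random_codes(40, 2))
  c <- cat_series(random_codes(40, 2))
  ii <- interaction_information(a, b, c)
  expect_equal(interaction_information(b, c, a), ii, tolerance = 1e-12)
  expect_equal(interaction_information(c, a, b), ii, tolerance = 1e-12)
})

test_that("estimators satisfy symmetry, chain rules, bounds and grouping on random tables", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- cat_series(random_codes(n, sample(2:4, 1)))
    y <- cat_series(random_codes(n, sample(2:4, 1)))
    z <- cat_series(random_codes(n, sample(2:4, 1)))
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    expect_equal(joint_entropy(list(x, y)),
                 entropy(y) + conditional_entropy(x, y), tolerance = 1e-12)
    expect_equal(mutual_information(x, y),
                 entropy(x) - conditional_entropy(x, y), tolerance = 1e-12)
    expect_equal(mutual_information(x, y),
                 entropy(y) - conditional_entropy(y, x), tolerance = 1e-12)
    expect_gte(mutual_information(x, y), -1e-12)
    expect_lte(mutual_information(x, y),
               min(entropy(x), entropy(y)) + 1e-12)
    expect_gte(entropy(x), 0)
    expect_lte(entropy(x), log2(x$n_levels) + 1e-12)
    # grouping identity behind the multivariate chain rule
    expect_equal(conditional_mutual_information(x, y, z),
                 mutual_information(x, joint_variable(y, z)) -
                   mutual_information(x, z), tolerance = 1e-12)
  }
})

test_that("every estimator matches brute-force joint-table summation", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    a <- random_codes(n, sample(2:4, 1)); b <- random_codes(n, sample(2:4, 1))
    c <- random_codes(n, sample(2:4, 1))
    expect_equal(entropy(cat_series(a)), brute_entropy(a), tolerance = 1e-12)
    expect_equal(joint_entropy(list(cat_series(a), cat_series(b))),
                 brute_joint_entropy(a, b), tolerance = 1e-12)
    expect_equal(mutual_information(cat_series(a), cat_series(b)),
                 brute_mi(a, b), tolerance = 1e-12)
    expect_equal(conditional_mutual_information(cat_series(a), cat_series(b),
                                                cat_series(c)),
                 brute_cmi(a, b, c), tolerance = 1e-12)
    expect_equal(interaction_information(cat_series(a), cat_series(b),
                                         cat_series(c)),
                 brute_interaction(a, b, c), tolerance = 1e-12)
  }
})

test_that("changing the logarithm base rescales all measures uniformly", {
  set.seed(3)
  x <- cat_series(random_codes(30, 3)); y <- cat_series(random_codes(30, 2))
  expect_equal(entropy(x, base = exp(1)), entropy(x) * log(2), tolerance = 1e-12)
  expect_equal(mutual_information(x, y, base = exp(1)),
               mutual_information(x, y) * log(2), tolerance = 1e-12)
})
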