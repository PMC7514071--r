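test_that("median-difference component, direction and weight", {
  x <- rnorm(50)
  expect_equal(ct_diff(x, x, gmd_pooled = 1.3), 0)
  # constant groups 1 vs 2: medians 1 and 2, pooled GMD 0.5
  expect_equal(ct_diff(rep(1, 100), rep(2, 100), 0.5), 2)
  expect_error(ct_diff(1:3, 1:3, 0), "positive")

  expect_identical(dir_ct(c(1, 2, 3), c(1, 2, 3)), 1)  # tie -> +1
  expect_identical(dir_ct(rep(1, 5), rep(2, 5)), 1)
  expect_identical(dir_ct(rep(-2.258, 5), rep(-3.645, 5)), -1)

  expect_equal(ct_weight(0), 0)
  expect_equal(ct_weight(1), 0.5)
  expect_equal(ct_weight(2.66), 1)  # clamps at the shape component's maximum
  expect_error(ct_weight(-0.1), "non-negative")
})

test_that("log-modulus transform and momentum ordering", {
  expect_identical(log_modulus(0), 0)
  expect_equal(log_modulus(exp(1) - 1), 1)
  expect_equal(log_modulus(-(exp(1) - 1)), -1)  # odd symmetry
  x <- rnorm(20)
  expect_equal(log_modulus(-x), -log_modulus(x))

  expect_equal(momentum(c(0, 0, 0)), 0)
  expect_equal(momentum(c(exp(1) - 1, -(exp(1) - 1))), 0)
  expect_equal(momentum(c(exp(1) - 1, exp(2) - 1)), 1.5)

  expect_identical(dir_morph(1:5, 1:5), 1)  # tie -> +1
  set.seed(3)
  x1 <- abs(rnorm(100)) + 1
  expect_identical(dir_morph(x1, x1 + 2), 1)  # right shift raises momentum
  expect_identical(dir_morph(x1, -x1), -1)    # momentum is odd under negation
})

test_that("KS gate fires on indistinguishable groups and only then", {
  g <- ks_gate(1:50, 1:50)
  expect_equal(g$pvalue, 1)
  expect_true(g$gated)
  set.seed(5)
  g2 <- ks_gate(rnorm(1000), rnorm(1000, 3, 1))
  expect_false(g2$gated)
  expect_lt(g2$pvalue, 1e-10)
})

test_that("impact composes its components and handles degenerate groups", {
  # identical groups: gated to exactly zero
  r0 <- impact(labeled_sample(rep(1:5, 20), rep(1:5, 20)))
  expect_identical(r0$impact, 0)
  expect_true(r0$gated_zero)

  # constant 1s vs constant 2s: weight clamps to 1, CTdiff = 2, and the
  # result is finite despite zero within-group variance
  r1 <- impact(labeled_sample(rep(1, 100), rep(2, 100)))
  expect_equal(r1$impact, 2)
  expect_equal(r1$ct_weight, 1)
  expect_equal(r1$morph_diff, 2)  # disjoint unit masses
  expect_false(r1$gated_zero)

  # N(0,1) vs N(3,1): saturated weight, impact ~ 3 / (2/sqrt(pi))
  set.seed(9)
  r2 <- impact(labeled_sample(rnorm(1000), rnorm(1000, 3, 1)))
  expect_equal(r2$impact, 3 * sqrt(pi) / 2, tolerance = 0.08)

  # reported components recompose the headline number
  set.seed(10)
  r3 <- impact(make_two_normals(10, n = 400, mean2 = 0.6))
  expect_false(r3$gated_zero)
  expect_equal(r3$impact,
               r3$ct_weight * r3$dir_ct * r3$ct_diff +
                 (1 - r3$ct_weight) * r3$dir_morph * r3$morph_diff,
               tolerance = 1e-12)

  expect_error(impact(1:10, rep(1, 10)), "2 distinct levels")
  expect_error(impact(1:10, rep(1:5, 2)), "2 distinct levels")
})

test_that("impact is antisymmetric under group swap", {
  for (seed in 1:5) {
    s <- make_two_normals(seed, n = 300, mean2 = 0.8, sd2 = 1.5)
    x1 <- s$value[s$group == 1]
    x2 <- s$value[s$group == 2]
    a <- impact(labeled_sample(x1, x2))
    b <- impact(labeled_sample(x2, x1))
    expect_equal(b$impact, -a$impact, tolerance = 1e-10)
    expect_equal(b$ct_diff, a$ct_diff, tolerance = 1e-10)
    expect_equal(b$morph_diff, a$morph_diff, tolerance = 1e-10)
  }
})

test_that("impact is invariant under positive rescaling of the data", {
  for (seed in 1:5) {
    s <- make_two_normals(seed, n = 300, mean2 = 1)
    s10 <- s
    s10$value <- 10 * s10$value
    a <- impact(s)$impact
    b <- impact(s10)$impact
    expect_false(impact(s)$gated_zero)
    expect_lt(abs(a - b), 0.05)
  }
})

test_that("no NaN or infinity in any zero-variance scenario", {
  for (s in make_dataset2(seed = 1)) {
    r <- impact(s)
    vals <- c(r$impact, r$ct_diff, r$morph_diff, r$gmd_pooled,
              r$ct_weight, r$gate_pvalue)
    expect_true(all(is.finite(vals)))
    expect_lte(r$morph_diff, 2)
    expect_gte(r$ct_weight, 0)
    expect_lte(r$ct_weight, 1)
  }
})

test_that("absolute_value option reports magnitudes only", {
  s <- make_two_normals(4, n = 300, mean2 = -1)
  r <- impact(s)
  ra <- impact(s, config = impact_config(absolute_value = TRUE))
  expect_lt(r$impact, 0)
  expect_equal(ra$impact, abs(r$impact))
})
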