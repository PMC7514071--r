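test_that("pareto radius is positive and robust to ties", {
  # single pairwise distance
  expect_gt(pareto_radius(c(0, 1)), 0)
  # distance multiset {0,0,0,1,1,1}: the 18th percentile is 0, so the
  # range fallback must engage
  r <- pareto_radius(c(1, 1, 1, 2))
  expect_gt(r, 0)
  expect_equal(r, 0.05 * 1)
  expect_error(pareto_radius(rep(1, 10)), "distinct")
  # radius is stable across subsample seeds when capped
  set.seed(21)
  x <- rnorm(1000)
  rs <- sapply(1:5, function(s) pareto_radius(x, cap = 400L, seed = s))
  expect_lt(diff(range(rs)) / mean(rs), 0.1)
})

test_that("shared grid spans the padded pooled range", {
  g <- shared_grid(c(0, 1), c(0, 1), radius = 0.5, n_points = 32L)
  expect_length(g, 32L)
  expect_equal(range(g), c(-0.5, 1.5))
  expect_true(all(diff(g) > 0))
  g10 <- shared_grid(c(0, 10), c(0, 10), radius = 5, n_points = 32L)
  expect_equal(g10, 10 * g)  # affine covariance
  expect_error(shared_grid(0:1, 0:1, 0.5, n_points = 16L), "at least 32")
})

test_that("estimated densities carry unit mass for both methods", {
  set.seed(31)
  cases <- list(
    list(x1 = rnorm(200), x2 = rnorm(300, 2)),
    list(x1 = rchisq(150, 2), x2 = runif(150)),
    list(x1 = rep(1, 50), x2 = rnorm(100))  # degenerate group
  )
  for (cs in cases) {
    for (m in c("pde", "kde")) {
      dp <- estimate_pdf_pair(cs$x1, cs$x2, method = m)
      expect_equal(pracma::trapz(dp$grid, dp$pdf1), 1, tolerance = 1e-6)
      expect_equal(pracma::trapz(dp$grid, dp$pdf2), 1, tolerance = 1e-6)
      expect_true(all(dp$pdf1 >= 0) && all(dp$pdf2 >= 0))
    }
  }
})

test_that("kde recovers the analytic standard normal density", {
  set.seed(41)
  x <- rnorm(2000)
  dp <- estimate_pdf_pair(x, x, method = "kde")
  expect_lt(max(abs(dp$pdf1 - dnorm(dp$grid))), 0.05)
})

test_that("morph difference honors its bounds and analytic oracle", {
  set.seed(51)
  x <- rnorm(500)
  dp <- estimate_pdf_pair(x, x)
  expect_equal(morph_diff(dp), 0)

  # disjoint unit masses integrate to 2
  dp2 <- estimate_pdf_pair(rep(1, 100), rep(2, 100))
  expect_equal(morph_diff(dp2), 2, tolerance = 1e-9)

  # N(0,1) vs equal-mean 50/50 bimodal mixture: compare against the
  # fine-grid integral of the analytic densities, stable across seeds
  oracle <- analytic_morph(function(x) dnorm(x), dmix5050(4), -10, 10)
  vals <- sapply(1:3, function(seed) {
    set.seed(seed)
    dp <- estimate_pdf_pair(rnorm(1000),
                            c(rnorm(500, -4), rnorm(500, 4)))
    morph_diff(dp)
  })
  expect_true(all(vals > 0 & vals < 2))
  expect_lt(max(abs(vals - oracle)), 0.25)
  expect_lt(diff(range(vals)), 0.15)

  bad <- dp
  bad$pdf1 <- bad$pdf1[-1]
  expect_error(morph_diff(bad), "mismatched")
  expect_error(morph_diff(list(grid = 1:3)), "density_pair")
})

test_that("densities are equivariant under affine maps with positive scale", {
  set.seed(61)
  x1 <- rnorm(400)
  x2 <- rnorm(400, 1, 2)
  a <- 7
  b <- -3
  m1 <- morph_diff(estimate_pdf_pair(x1, x2))
  m2 <- morph_diff(estimate_pdf_pair(a * x1 + b, a * x2 + b))
  expect_lt(abs(m1 - m2), 0.02)
})
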