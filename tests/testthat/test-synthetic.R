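test_that("generation is a pure function of the seed", {
  expect_identical(make_dataset1(5), make_dataset1(5))
  expect_identical(make_dataset2(5), make_dataset2(5))
  expect_identical(make_dataset3_variance_scan(5, sds = 1:10),
                   make_dataset3_variance_scan(5, sds = 1:10))
  expect_identical(make_dataset4(5, n = 100), make_dataset4(5, n = 100))
  expect_false(identical(make_dataset1(5), make_dataset1(6)))
})

test_that("equal-center benchmark has matched centers and mirrored subsets", {
  d1 <- make_dataset1(2)
  expect_named(d1, paste0("X", 1:6))
  # X3 is X2 negated elementwise
  expect_equal(d1$X3$value, -d1$X2$value)
  expect_identical(d1$X3$group, d1$X2$group)
  expect_equal(d1$X6$value, -d1$X5$value)
  # group means agree in every subset, to within 3 standard errors of the
  # mean difference (the mixtures have variance near 17, so the bound scales)
  for (s in d1) {
    g <- split(s$value, s$group)
    se <- sqrt(var(g[[1]]) / length(g[[1]]) + var(g[[2]]) / length(g[[2]]))
    expect_lt(abs(mean(g[[1]]) - mean(g[[2]])), 3 * se)
    expect_length(g[[1]], 1000L)
  }
  # subset 4: unit vs fourfold spread
  g4 <- split(d1$X4$value, d1$X4$group)
  expect_equal(sd(g4[[1]]), 1, tolerance = 0.1)
  expect_equal(sd(g4[[2]]), 4, tolerance = 0.4)
  # 50/50 mixture at modes +/-4 has sd sqrt(17); group 1 is moment-matched
  g1 <- split(d1$X1$value, d1$X1$group)
  expect_equal(sd(g1[[1]]), sqrt(17), tolerance = 0.3)
  expect_equal(sd(g1[[2]]), sqrt(17), tolerance = 0.3)
})

test_that("extreme-scenario benchmark matches its construction", {
  d2 <- make_dataset2(3)
  expect_true(all(d2$X1$value == 1))
  expect_equal(var(d2$X1$value), 0)
  g3 <- split(d2$X3$value, d2$X3$group)
  expect_identical(sort(g3[[1]]), sort(g3[[2]]))  # identical multisets
  expect_identical(d2$X5$value, 10 * d2$X4$value) # exact rescaling
  g6 <- split(d2$X6$value, d2$X6$group)
  expect_true(all(g6[[1]] == 1))
  expect_equal(mean(g6[[2]]), 2, tolerance = 0.7)
})

test_that("scans sweep one parameter with the other held fixed", {
  vs <- make_dataset3_variance_scan(4, sds = c(1, 10, 50))
  expect_length(vs, 3L)
  g <- split(vs[[3]]$value, vs[[3]]$group)
  expect_equal(sd(g[[1]]), 1, tolerance = 0.3)
  expect_equal(sd(g[[2]]), 50, tolerance = 15)
  ms <- make_dataset3_mean_scan(4, means = c(1, 5, 100))
  g2 <- split(ms[[3]]$value, ms[[3]]$group)
  expect_equal(mean(g2[[1]]), 5, tolerance = 1.6)
  expect_equal(mean(g2[[2]]), 100, tolerance = 1.6)
  # the middle step has identical generating distributions
  g5 <- split(ms[[2]]$value, ms[[2]]$group)
  expect_lt(abs(mean(g5[[1]]) - mean(g5[[2]])), 2.2)
})

test_that("feature-matrix benchmark has its three variable blocks", {
  d4 <- make_dataset4(6)
  expect_equal(dim(d4$data), c(2000L, 20L))
  expect_identical(names(d4$data)[c(1, 11, 20)],
                   c("var0001", "var0011", "var0020"))
  g2 <- d4$group == 2
  # location block: group-2 means 3..7
  for (i in seq_along(d4$blocks$location)) {
    expect_equal(mean(d4$data[[d4$blocks$location[i]]][g2]), 2 + i,
                 tolerance = 0.15)
  }
  # shape block: group-2 sample mean exactly zero by mirroring, with the
  # spread of a mixture at modes +/-(2+i)
  for (i in seq_along(d4$blocks$shape)) {
    col <- d4$data[[d4$blocks$shape[i]]][g2]
    expect_equal(mean(col), 0, tolerance = 1e-12)
    expect_equal(sd(col), sqrt(1 + (2 + i)^2), tolerance = 0.25)
  }
  expect_error(make_dataset4(1, n = 101), "even")
})

test_that("CSV writers emit byte-identical reproducible files", {
  dir <- withr::local_tempdir()
  p1 <- write_labeled_samples(make_dataset2(9), file.path(dir, "a"))
  p2 <- write_labeled_samples(make_dataset2(9), file.path(dir, "b"))
  expect_length(p1, 6L)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
})
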