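#' Construct a labeled two-group sample
#'
#' The universal input container: a data frame with numeric `value` and an
#' integer `group` column (levels 1 and 2 in the order given).
#'
#' @param x1,x2 Numeric vectors for group 1 and group 2.
#' @return A `labeled_sample` data frame.
#' @export
labeled_sample <- function(x1, x2) {
  structure(
    data.frame(value = c(x1, x2),
               group = rep(1:2, c(length(x1), length(x2)))),
    class = c("labeled_sample", "data.frame")
  )
}

# Two-component Gaussian mixture with unit-variance modes at -offset and
# +offset, weight `w` on the negative mode.
.bimodal <- function(n, w, offset) {
  mode_mean <- ifelse(stats::runif(n) < w, -offset, offset)
  stats::rnorm(n, mean = mode_mean, sd = 1)
}

#' Benchmark suite 1: equal central tendency, different shapes
#'
#' Six two-group subsets (n = 1000 per group by default) in which the groups
#' share the central tendency but differ clearly in distribution shape, so a
#' purely difference-based effect size reads near zero:
#' \describe{
#'   \item{X1}{moment-matched normal vs a 50/50 bimodal mixture with
#'     unit-variance modes at ±`mode_offset` (same mean and variance).}
#'   \item{X2}{moment-matched normal vs an 80/20 mixture (same mean and
#'     variance, medians differ between groups).}
#'   \item{X3}{X2 mirrored: `X3 = -X2` elementwise.}
#'   \item{X4}{N(0,1) vs N(0,4): same mean, different spread.}
#'   \item{X5}{chi-square (df = `chisq_df`, shifted to mean 2) vs N(2,2).}
#'   \item{X6}{X5 negated.}
#' }
#' The default mode offset of 4 reproduces group standard deviations near
#' `sqrt(1 + offset^2)` = 4.12 for the 50/50 mixture. Set
#' `matched_group1 = FALSE` to make group 1 a plain standard normal in
#' X1-X3 instead of the moment-matched normal.
#'
#' @param seed Integer seed; generation is a pure function of the arguments.
#' @param n Observations per group.
#' @param mode_offset Location of the mixture modes (±offset).
#' @param chisq_df Degrees of freedom of the chi-square group in X5/X6.
#' @param matched_group1 Moment-match group 1 to the mixture (default TRUE).
#' @return Named list of six `labeled_sample` objects.
#' @export
make_dataset1 <- function(seed = 1L, n = 1000L, mode_offset = 4,
                          chisq_df = 2, matched_group1 = TRUE) {
  with_seed(seed, {
    m <- mode_offset
    # 50/50 mixture: mean 0, var 1 + m^2
    g1_a <- if (matched_group1) stats::rnorm(n, 0, sqrt(1 + m^2))
            else stats::rnorm(n)
    s1 <- labeled_sample(g1_a, .bimodal(n, 0.5, m))
    # 80/20 mixture: mean (1 - 2w) m = -0.6 m, var 1 + m^2 - mean^2
    mu <- -0.6 * m
    g1_b <- if (matched_group1) stats::rnorm(n, mu, sqrt(1 + m^2 - mu^2))
            else stats::rnorm(n)
    s2 <- labeled_sample(g1_b, .bimodal(n, 0.8, m))
    s3 <- labeled_sample(-s2$value[s2$group == 1], -s2$value[s2$group == 2])
    s4 <- labeled_sample(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 4))
    s5 <- labeled_sample(stats::rchisq(n, df = chisq_df) + (2 - chisq_df),
                         stats::rnorm(n, 2, 2))
    s6 <- labeled_sample(-s5$value[s5$group == 1], -s5$value[s5$group == 2])
    list(X1 = s1, X2 = s2, X3 = s3, X4 = s4, X5 = s5, X6 = s6)
  })
}

#' Benchmark suite 2: extreme and degenerate scenarios
#'
#' Six subsets (n = 100 per group) probing numerical stability and scale
#' invariance, including cases where Cohen's d is undefined:
#' \describe{
#'   \item{X1}{all values 1 in both groups (zero pooled variance).}
#'   \item{X2}{constant 1 vs constant 2 (zero within-group variance).}
#'   \item{X3}{both groups the sequence 1..5 repeated 20 times (identical).}
#'   \item{X4}{independent sampling with replacement from 1..100 per group.}
#'   \item{X5}{`10 * X4` exactly (scale-invariance probe).}
#'   \item{X6}{constant 1 vs a sample from N(2, 2).}
#' }
#'
#' @param seed Integer seed (used for X4-X6).
#' @param n Observations per group.
#' @return Named list of six `labeled_sample` objects.
#' @export
make_dataset2 <- function(seed = 1L, n = 100L) {
  with_seed(seed, {
    x4g1 <- sample(1:100, n, replace = TRUE)
    x4g2 <- sample(1:100, n, replace = TRUE)
    list(
      X1 = labeled_sample(rep(1, n), rep(1, n)),
      X2 = labeled_sample(rep(1, n), rep(2, n)),
      X3 = labeled_sample(rep(1:5, times = n / 5),
                          rep(1:5, times = n / 5)),
      X4 = labeled_sample(x4g1, x4g2),
      X5 = labeled_sample(10 * x4g1, 10 * x4g2),
      X6 = labeled_sample(rep(1, n), stats::rnorm(n, 2, 2))
    )
  })
}

#' Benchmark suite 3: variance scan (shape component in isolation)
#'
#' 100 two-group subsets (n = 100 per group) with identical means (1) in
#' which group 1 keeps sd 1 while group 2's sd sweeps 1..100, so only the
#' shape component of the effect size can respond.
#'
#' @param seed Integer seed.
#' @param n Observations per group.
#' @param sds Vector of group-2 standard deviations (default 1:100).
#' @return List of `labeled_sample` objects, one per sd.
#' @export
make_dataset3_variance_scan <- function(seed = 1L, n = 100L, sds = 1:100) {
  with_seed(seed, {
    lapply(sds, function(s) {
      labeled_sample(stats::rnorm(n, 1, 1), stats::rnorm(n, 1, s))
    })
  })
}

#' Benchmark suite 3: mean scan (location component in isolation)
#'
#' 100 two-group subsets (n = 100 per group) with common sd 5 in which group
#' 1 keeps mean 5 while group 2's mean sweeps 1..100, so the effect size
#' should scale with the standardized mean difference.
#'
#' @param seed Integer seed.
#' @param n Observations per group.
#' @param means Vector of group-2 means (default 1:100).
#' @return List of `labeled_sample` objects, one per mean.
#' @export
make_dataset3_mean_scan <- function(seed = 1L, n = 100L, means = 1:100) {
  with_seed(seed, {
    lapply(means, function(m) {
      labeled_sample(stats::rnorm(n, 5, 5), stats::rnorm(n, m, 5))
    })
  })
}

#' Benchmark suite 4: 20-variable feature matrix
#'
#' Two groups of n = 1000 cases described by 20 variables:
#' \describe{
#'   \item{var0001-var0010}{standard normal in both groups (pure noise).}
#'   \item{var0011-var0015}{N(0,1) vs N(m,1) with m = 3..7 (increasing mean
#'     shifts).}
#'   \item{var0016-var0020}{N(0,1) vs a symmetric bimodal mixture with
#'     unit-variance modes at ±3..±7 whose sample mean is exactly zero
#'     (half the draws are mirrored), so only the distribution shape
#'     changes.}
#' }
#'
#' @param seed Integer seed.
#' @param n Observations per group (must be even for the mirrored block).
#' @param shift_means Group-2 means of the location block (default 3:7).
#' @param mode_offsets Mode locations of the shape block (default 3:7).
#' @return List with `data` (data frame of 2n rows, columns var0001..),
#'   `group` (integer vector 1/2) and `blocks` (named list of column
#'   indices: noise, location, shape).
#' @export
make_dataset4 <- function(seed = 1L, n = 1000L, shift_means = 3:7,
                          mode_offsets = 3:7) {
  if (n %% 2L != 0L) stop_input("'n' must be even")
  with_seed(seed, {
    cols <- vector("list", 10L + length(shift_means) + length(mode_offsets))
    for (i in 1:10) {
      cols[[i]] <- c(stats::rnorm(n), stats::rnorm(n))
    }
    for (i in seq_along(shift_means)) {
      cols[[10L + i]] <- c(stats::rnorm(n), stats::rnorm(n, shift_means[i], 1))
    }
    for (i in seq_along(mode_offsets)) {
      half <- stats::rnorm(n / 2, mode_offsets[i], 1)
      g2 <- sample(c(half, -half)) # mirrored: sample mean exactly 0
      cols[[10L + length(shift_means) + i]] <- c(stats::rnorm(n), g2)
    }
    d <- as.data.frame(cols, col.names = sprintf("var%04d", seq_along(cols)))
    list(data = d,
         group = rep(1:2, each = n),
         blocks = list(noise = 1:10,
                       location = 10L + seq_along(shift_means),
                       shape = 10L + length(shift_means) +
                         seq_along(mode_offsets)))
  })
}

#' Write labeled samples as CSV files
#'
#' One file per sample (columns `value`, `group`), named
#' `<prefix><name>.csv`; byte-identical across runs for identical inputs.
#'
#' @param samples Named list of `labeled_sample` objects.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_labeled_samples <- function(samples, dir, prefix = "subset_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- names(samples)
  if (is.null(nm)) nm <- sprintf("%03d", seq_along(samples))
  paths <- file.path(dir, paste0(prefix, nm, ".csv"))
  for (i in seq_along(samples)) {
    utils::write.csv(as.data.frame(samples[[i]]), paths[i], row.names = FALSE)
  }
  invisible(paths)
}
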