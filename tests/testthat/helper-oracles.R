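# Independent oracles used across the suite.

# O(n^2) double loop over all ordered pairs, including the zero self-terms.
gmd_brute <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + abs(x[i] - x[j])
    }
  }
  s / n^2
}

# Total variation style integral between two analytic densities on a fine
# grid: integral of |f2 - f1|.
analytic_morph <- function(f1, f2, lower, upper, n = 20001L) {
  g <- seq(lower, upper, length.out = n)
  pracma::trapz(g, abs(f2(g) - f1(g)))
}

# Density of a 50/50 mixture of N(-m,1) and N(m,1).
dmix5050 <- function(m) {
  function(x) 0.5 * stats::dnorm(x, -m, 1) + 0.5 * stats::dnorm(x, m, 1)
}

make_two_normals <- function(seed, n = 300L, mean2 = 1, sd2 = 1) {
  set.seed(seed)
  labeled_sample(stats::rnorm(n), stats::rnorm(n, mean2, sd2))
}
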