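#' Cohen's d (reference implementation, two pooling variants)
#'
#' Standardized mean difference `(mean(x2) - mean(x1)) / SDpooled`.
#' `pooling = "rms"` (default) uses the sample-size-independent
#' root-mean-square pooling `sqrt((SD1^2 + SD2^2)/2)`, the variant whose
#' dispersion pooling the Impact measure mimics with the Gini mean
#' difference. `pooling = "n_weighted"` uses the classical
#' `sqrt(((n1-1) SD1^2 + (n2-1) SD2^2) / (n1 + n2 - 2))`, which lets the
#' larger group dominate.
#'
#' When the pooled standard deviation is zero (e.g. both groups constant)
#' the statistic is undefined: the function returns `NA_real_` with a
#' warning rather than silently coercing to a number.
#'
#' @param x1,x2 Numeric group vectors.
#' @param pooling `"rms"` or `"n_weighted"`.
#' @return Scalar, or `NA_real_` (with a warning) when undefined.
#' @export
cohens_d <- function(x1, x2, pooling = c("rms", "n_weighted")) {
  pooling <- match.arg(pooling)
  if (length(x1) == 0L || length(x2) == 0L) {
    stop_input("both groups must be non-empty")
  }
  s1sq <- var0(x1)
  s2sq <- var0(x2)
  n1 <- length(x1)
  n2 <- length(x2)
  sp <- switch(pooling,
    rms = sqrt((s1sq + s2sq) / 2),
    n_weighted = sqrt(((n1 - 1) * s1sq + (n2 - 1) * s2sq) / (n1 + n2 - 2))
  )
  if (!is.finite(sp) || sp <= 0) {
    warning("pooled standard deviation is zero; Cohen's d is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(x2) - mean(x1)) / sp
}
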