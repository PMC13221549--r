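## Paired nonparametric cohort statistics: median (IQR) summaries, the
## two-sided Wilcoxon signed-rank test and relative differences.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics with
#' quantile `q` at position `(n - 1) * q` (R's type-7 convention), fixed
#' and documented because reporting conventions differ across software.
#'
#' @param values non-empty numeric vector.
#' @return named vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))  # 3, 2, 4
median_iqr <- function(values) {
  if (length(values) == 0L || any(is.na(values)))
    stop_format("median_iqr needs a non-empty vector without NAs")
  q <- quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded (the classic test); ties in the absolute
#' differences are mid-ranked. The `exact` method uses the exact signed-rank
#' null distribution when the non-zero absolute differences are tie-free,
#' and otherwise falls back to a seeded Monte-Carlo null (`n_mc` random
#' sign assignments of the observed ranks). `normal_approx` uses the
#' normal approximation with tie correction and a continuity correction.
#' When every difference is zero the test is degenerate and `p = 1` is
#' returned with `degenerate = TRUE`.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param method `"exact"` or `"normal_approx"`.
#' @param n_mc Monte-Carlo sign flips used when ties prevent the exact
#'   null.
#' @param mc_seed seed for the Monte-Carlo fallback.
#' @return a list with `p_value`, the signed-rank statistic `V` (sum of
#'   positive ranks), `n_effective`, `method_used` and `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))$p_value  # exact 0.25
wilcoxon_signed_rank <- function(a, b, method = c("exact", "normal_approx"),
                                 n_mc = 1e5, mc_seed = 20211101) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1.0, V = NA_real_, n_effective = 0L,
                method_used = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4

  if (method == "exact") {
    if (!anyDuplicated(abs(d))) {
      # tie-free: exact null distribution of the signed-rank statistic
      lower <- psignrank(V, n)
      upper <- 1 - psignrank(V - 1, n)
      p <- min(1, 2 * min(lower, upper))
      return(list(p_value = p, V = V, n_effective = n,
                  method_used = "exact", degenerate = FALSE))
    }
    # ties: Monte-Carlo null over random sign assignments of the mid-ranks
    p <- with_seed(mc_seed, {
      signs <- matrix(runif(n_mc * n) < 0.5, n_mc, n)
      vsim <- as.vector(signs %*% r)
      (1 + sum(abs(vsim - mu) >= abs(V - mu) - 1e-12)) / (1 + n_mc)
    })
    return(list(p_value = p, V = V, n_effective = n,
                method_used = "monte_carlo", degenerate = FALSE))
  }

  # normal approximation with tie and continuity corrections
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
  list(p_value = min(1, 2 * pnorm(-abs(z))), V = V, n_effective = n,
       method_used = "normal_approx", degenerate = FALSE)
}

#' Relative difference in percent
#'
#' `100 * (a - b_reference) / b_reference`. Rounding to one decimal happens
#' only at the reporting layer.
#'
#' @param a value to compare.
#' @param b_reference non-zero reference value.
#' @return signed percentage.
#' @export
#' @examples
#' relative_difference(2.07, 2.06)  # +0.485..., reported as 0.5
relative_difference <- function(a, b_reference) {
  if (any(b_reference == 0))
    stop_format("relative difference against a zero reference is undefined")
  100 * (a - b_reference) / b_reference
}
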