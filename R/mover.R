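# Method of variance estimates recovery (MOVER) intervals for the
# difference and ratio of two Poisson rates, built from single-rate
# intervals (Jeffreys by default, exact tail-inversion selectable).

#' Confidence interval for a single Poisson rate
#'
#' @param x Observed count.
#' @param n Exposure (person-denominator).
#' @param level Confidence level.
#' @param method `"jeffreys"` (Gamma(x + 1/2) posterior quantiles, the
#'   default component interval) or `"exact"` (Garwood tail inversion).
#' @return Numeric vector `c(lo, hi)` on the rate scale.
#' @export
poisson_rate_ci <- function(x, n = 1, level = 0.95,
                            method = c("jeffreys", "exact")) {
  method <- match.arg(method)
  if (x < 0 || n <= 0) abort("need x >= 0 and n > 0")
  a <- 1 - level
  if (method == "jeffreys") {
    lo <- if (x == 0) 0 else qgamma(a / 2, x + 0.5) / n
    hi <- qgamma(1 - a / 2, x + 0.5) / n
  } else {
    lo <- if (x == 0) 0 else qgamma(a / 2, x) / n
    hi <- qgamma(1 - a / 2, x + 1) / n
  }
  c(lo, hi)
}

#' MOVER interval for a difference of two Poisson rates
#'
#' For rates `p1 = x1/n1` and `p2 = x2/n2` with component intervals
#' `(l1, u1)` and `(l2, u2)`, the recovered interval for `p1 - p2` is
#' `d - sqrt((p1-l1)^2 + (u2-p2)^2)` to `d + sqrt((u1-p1)^2 + (p2-l2)^2)`.
#'
#' @param x1,n1 Count and exposure in group 1 (e.g. probands).
#' @param x2,n2 Count and exposure in group 2 (e.g. fathers).
#' @param level Confidence level.
#' @param method Component interval family, see [poisson_rate_ci()].
#' @return `c(lo, hi)` for the rate difference.
#' @export
mover_rate_diff_ci <- function(x1, n1, x2, n2, level = 0.95,
                               method = c("jeffreys", "exact")) {
  method <- match.arg(method)
  p1 <- x1 / n1
  p2 <- x2 / n2
  c1 <- poisson_rate_ci(x1, n1, level, method)
  c2 <- poisson_rate_ci(x2, n2, level, method)
  c(
    p1 - p2 - sqrt((p1 - c1[1])^2 + (c2[2] - p2)^2),
    p1 - p2 + sqrt((c1[2] - p1)^2 + (p2 - c2[1])^2)
  )
}

#' MOVER interval for a ratio of two Poisson rates
#'
#' Donner–Zou construction: the interval for `p1/p2` is recovered from the
#' component intervals by treating `p1 - theta * p2` as the difference whose
#' limits cross zero.
#'
#' @inheritParams mover_rate_diff_ci
#' @return `c(lo, hi)` for the rate ratio. When both counts are zero the
#'   interval is the degenerate `(0, Inf)` with a warning.
#' @export
mover_rate_ratio_ci <- function(x1, n1, x2, n2, level = 0.95,
                                method = c("jeffreys", "exact")) {
  method <- match.arg(method)
  if (x1 == 0 && x2 == 0) {
    warn("both counts zero: rate-ratio interval is degenerate (0, Inf)")
    return(c(0, Inf))
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  c1 <- poisson_rate_ci(x1, n1, level, method)
  c2 <- poisson_rate_ci(x2, n2, level, method)
  l1 <- c1[1]; u1 <- c1[2]; l2 <- c2[1]; u2 <- c2[2]
  lo_den <- u2 * (2 * p2 - u2)
  hi_den <- l2 * (2 * p2 - l2)
  disc_lo <- (p1 * p2)^2 - l1 * u2 * (2 * p1 - l1) * (2 * p2 - u2)
  disc_hi <- (p1 * p2)^2 - u1 * l2 * (2 * p1 - u1) * (2 * p2 - l2)
  # when u2 > 2 * p2 the denominator is negative but the same root is the
  # valid (positive) limit: numerator and denominator change sign together
  lo <- if (lo_den == 0) 0 else (p1 * p2 - sqrt(max(disc_lo, 0))) / lo_den
  hi <- if (hi_den <= 0) Inf else (p1 * p2 + sqrt(max(disc_hi, 0))) / hi_den
  c(max(lo, 0), hi)
}
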