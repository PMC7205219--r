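#' The inverse-gamma distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the inverse-gamma distribution with shape \code{a} and scale \code{b},
#' whose density over \code{x > 0} is
#' \deqn{f(x) = \frac{b^a}{\Gamma(a)} x^{-(a+1)} e^{-b/x}.}
#' If \eqn{X \sim \mathrm{Gamma}(a, \mathrm{rate} = b)} then \eqn{1/X} is
#' inverse-gamma with these parameters; all four functions are thin wrappers
#' over the corresponding gamma functions in \pkg{stats}.
#'
#' The mode is \code{b / (a + 1)} and the mean, defined for \code{a > 1}, is
#' \code{b / (a - 1)}.
#'
#' @param x,q vector of quantiles (positive).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param a shape parameter, > 0.
#' @param b scale parameter, > 0 (same units as \code{x}).
#' @param log,log.p logical; if TRUE, probabilities/densities are given on
#'   the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return \code{dinvgamma} gives the density, \code{pinvgamma} the
#'   distribution function, \code{qinvgamma} the quantile function and
#'   \code{rinvgamma} random draws.
#' @examples
#' dinvgamma(0.5, a = 4, b = 2)
#' qinvgamma(c(0.05, 0.95), a = 4, b = 2)
#' @name invgamma
NULL

#' @rdname invgamma
#' @export
dinvgamma <- function(x, a, b, log = FALSE) {
  stopifnot(all(a > 0), all(b > 0))
  ld <- ifelse(x > 0,
               a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x,
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname invgamma
#' @export
pinvgamma <- function(q, a, b, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(all(a > 0), all(b > 0))
  # P(X <= q) = P(1/G <= q) = P(G >= 1/q)
  stats::pgamma(1 / q, shape = a, rate = b,
                lower.tail = !lower.tail, log.p = log.p)
}

#' @rdname invgamma
#' @export
qinvgamma <- function(p, a, b, lower.tail = TRUE) {
  stopifnot(all(a > 0), all(b > 0))
  1 / stats::qgamma(p, shape = a, rate = b, lower.tail = !lower.tail)
}

#' @rdname invgamma
#' @export
rinvgamma <- function(n, a, b) {
  stopifnot(all(a > 0), all(b > 0))
  1 / stats::rgamma(n, shape = a, rate = b)
}
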