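## Zero-truncated Poisson distribution: the versatility response family.
## pmf(k; lambda) = lambda^k exp(-lambda) / (k! (1 - exp(-lambda))), k >= 1.

## log(1 - exp(-x)) computed stably over the whole positive range.
log1mexp <- function(x) {
  big <- x > log(2)
  if (all(big)) return(log1p(-exp(-x)))
  out <- numeric(length(x))
  out[big] <- log1p(-exp(-x[big]))
  out[!big] <- log(-expm1(-x[!big]))
  out
}

#' Zero-truncated Poisson distribution
#'
#' `ztpoisson_logpmf()` evaluates the log probability mass of a Poisson
#' distribution conditioned on being at least 1, stably down to very small
#' rates (as `lambda -> 0` the mass concentrates on `k = 1`).
#' `rztpois()` draws variates by inverse transform restricted to the
#' truncated support, which is exact for any rate.
#'
#' @param k positive integer outcome(s).
#' @param lambda positive Poisson rate(s).
#' @return `ztpoisson_logpmf()`: log-probabilities; `dztpois()`:
#'   probabilities; `rztpois()`: integer draws `>= 1`.
#' @examples
#' exp(ztpoisson_logpmf(1, 1)) # exp(-1)/(1 - exp(-1)) = 0.581977...
#' @export
ztpoisson_logpmf <- function(k, lambda) {
  if (any(k < 1 | k != floor(k)))
    stop("domain error: zero-truncated Poisson support is k >= 1")
  if (any(lambda <= 0)) stop("domain error: lambda must be positive")
  small <- lambda < 1e-8
  denom <- numeric(length(lambda))
  # log(1 - e^-lam) ~ log(lam) - lam/2 for tiny lam; avoids log(0)
  lam <- pmax(lambda, .Machine$double.xmin)
  denom[!small] <- log1mexp(lam[!small])
  denom[small] <- log(lam[small]) - lam[small] / 2
  k * log(lam) - lam - lgamma(k + 1) - denom
}

#' @rdname ztpoisson_logpmf
#' @export
dztpois <- function(k, lambda) exp(ztpoisson_logpmf(k, lambda))

#' @rdname ztpoisson_logpmf
#' @param n number of draws.
#' @export
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, p0, 1)
  out <- stats::qpois(pmin(u, 1 - 1e-16), lambda)
  pmax(out, 1L)
}
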