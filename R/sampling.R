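#' Draw areas from the default log-normal area model
#'
#' Samples raw areas whose mean-normalized values follow the log-normal form
#' used throughout the package, \eqn{\ln x \sim N(\mu, \sigma^2)} with
#' defaults \eqn{\mu = -0.05} and \eqn{2\sigma^2 = 0.19}.
#'
#' @param n Number of areas to draw.
#' @param mu,sigma2 Mean and variance of \eqn{\ln x}.
#' @param mean_area Physical scale (square micrometres) multiplying the
#'   dimensionless draw.
#' @return Numeric vector of `n` positive areas.
#' @export
#' @examples
#' set.seed(1)
#' a <- sample_areas(5000)
#' var(log(a / mean(a)))  # close to 0.095
sample_areas <- function(n, mu = -0.05, sigma2 = 0.19 / 2, mean_area = 1) {
  n <- check_count(n, "n", 1L)
  check_number(mu, "mu")
  check_number(sigma2, "sigma2", lower = 1e-12)
  check_number(mean_area, "mean_area", lower = 1e-12)
  mean_area * rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
}

#' Draw aspect ratios from the default gamma aspect-ratio model
#'
#' Samples aspect ratios whose rescaled form
#' \eqn{x = (AR - 1)/(\langle AR\rangle - 1)} follows the unit-mean gamma
#' distribution \eqn{k^k x^{k-1} e^{-kx}/\Gamma(k)} with shape `k`.
#'
#' @param n Number of aspect ratios to draw.
#' @param k Gamma shape parameter (default 2.43).
#' @param mean_ar Population mean aspect ratio (> 1).
#' @return Numeric vector of `n` aspect ratios, all >= 1.
#' @export
#' @examples
#' set.seed(1)
#' ar <- sample_aspect_ratios(5000)
#' mean(ar)  # close to 1.4
sample_aspect_ratios <- function(n, k = 2.43, mean_ar = 1.4) {
  n <- check_count(n, "n", 1L)
  check_number(k, "k", lower = 1e-6)
  check_number(mean_ar, "mean_ar", lower = 1 + 1e-9)
  1 + (mean_ar - 1) * rgamma(n, shape = k, rate = k)
}
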