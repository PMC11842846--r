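#' Normalize areas to unit mean
#'
#' Divides each area by the population mean so distributions measured at
#' different densities or in different model systems can be overlaid on a
#' common axis.
#'
#' @param areas Numeric vector of positive areas, length >= 2.
#' @return Numeric vector with mean exactly 1 (up to floating point).
#' @export
#' @examples
#' normalize_areas(c(2, 4, 6))
normalize_areas <- function(areas) {
  check_numeric_vec(areas, "areas", min_len = 2L)
  bad <- which(areas <= 0)
  if (length(bad) > 0) {
    abort(sprintf("`areas` must be positive; offending index: %d (value %g).",
                  bad[1], areas[bad[1]]))
  }
  areas / mean(areas)
}

#' Rescale aspect ratios to the universal form
#'
#' Applies the rescaling \eqn{x = (AR - 1)/(\langle AR\rangle - 1)}, which
#' maps aspect-ratio distributions from different systems onto a common
#' unit-mean axis on which they collapse to a gamma curve.
#'
#' @param ar_values Numeric vector of aspect ratios, all >= 1, mean > 1.
#' @return Numeric vector of rescaled values, all >= 0 with mean 1.
#' @export
#' @examples
#' rescale_ar(c(1.2, 1.4))
rescale_ar <- function(ar_values) {
  check_numeric_vec(ar_values, "ar_values", min_len = 2L)
  if (any(ar_values < 1 - 1e-9)) {
    abort("aspect ratios must be >= 1.")
  }
  m <- mean(ar_values)
  if (m <= 1 + 1e-12) {
    abort("mean aspect ratio is 1 (all circles); rescaling is undefined.")
  }
  pmax(ar_values - 1, 0) / (m - 1)
}

new_dist_fit <- function(family, params, n, log_likelihood, ks) {
  structure(
    list(
      family = family, params = params, n = n,
      log_likelihood = log_likelihood,
      ks_statistic = unname(ks$statistic), ks_p = unname(ks$p.value)
    ),
    class = "dist_fit"
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit: %s>\n", x$family))
  cat("  params:",
      paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
      "\n")
  cat(sprintf("  n = %d, logLik = %.2f, KS D = %.4f (p = %.3g)\n",
              x$n, x$log_likelihood, x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Fit a log-normal distribution by maximum likelihood
#'
#' Estimates \eqn{\hat\mu = \mathrm{mean}(\ln x)} and
#' \eqn{\hat\sigma^2 = \mathrm{var}(\ln x)} (population form, the MLE) and
#' reports a Kolmogorov-Smirnov goodness-of-fit test against the fitted
#' distribution.
#'
#' @param x Positive numeric vector, length >= 10, not all equal.
#' @return A `dist_fit` object with `params = c(mu, sigma2)`.
#' @seealso [tidy.dist_fit()], [glance.dist_fit()]
#' @export
#' @examples
#' set.seed(1)
#' fit_lognormal(rlnorm(500, -0.05, sqrt(0.095)))
fit_lognormal <- function(x) {
  check_numeric_vec(x, "x", min_len = 10L)
  if (any(x <= 0)) abort("`x` must be positive.")
  lx <- log(x)
  n <- length(x)
  mu <- mean(lx)
  sigma2 <- mean((lx - mu)^2)  # population (1/n) estimator = MLE
  if (sigma2 < 1e-12) {
    abort("`x` is degenerate (all values equal); sigma^2 = 0.")
  }
  ll <- sum(stats::dlnorm(x, mu, sqrt(sigma2), log = TRUE))
  ks <- suppressWarnings(
    ks.test(x, stats::plnorm, mu, sqrt(sigma2), exact = n < 30)
  )
  new_dist_fit("lognormal", c(mu = mu, sigma2 = sigma2), n, ll, ks)
}

#' Fit the unit-mean gamma distribution by maximum likelihood
#'
#' Fits the one-parameter gamma family
#' \eqn{\mathrm{PDF}(x; k) = k^k x^{k-1} e^{-kx}/\Gamma(k)} (mean fixed at
#' 1). The input is rescaled to unit mean first, after which the score
#' equation is \eqn{\ln k - \psi(k) = -\overline{\ln x}} with \eqn{\psi}
#' the digamma function; it is solved by safeguarded Newton iteration over
#' \eqn{k \in (10^{-3}, 10^{3})}.
#'
#' @param x Positive numeric vector, length >= 10.
#' @return A `dist_fit` object with `params = c(k)`.
#' @export
#' @examples
#' set.seed(1)
#' fit_unit_mean_gamma(rgamma(5000, 2.43, rate = 2.43))
fit_unit_mean_gamma <- function(x) {
  check_numeric_vec(x, "x", min_len = 10L)
  if (any(x <= 0)) abort("`x` must be positive.")
  x <- x / mean(x)
  n <- length(x)
  s <- -mean(log(x))  # = ln(mean x) - mean(ln x) >= 0 by Jensen
  if (s < 1e-12) {
    abort("`x` is degenerate (all values equal); shape is unidentified.")
  }
  # g(k) = ln k - digamma(k) - s is decreasing in k; bracket then Newton
  g <- function(k) log(k) - digamma(k) - s
  lo <- 1e-3; hi <- 1e3
  if (g(lo) < 0 || g(hi) > 0) {
    abort("no root for the gamma shape in (1e-3, 1e3).")
  }
  k <- max(min((3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s), hi), lo)
  for (iter in 1:100) {
    gk <- g(k)
    if (gk > 0) lo <- k else hi <- k
    step <- gk / (1 / k - trigamma(k))
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi) {
      k_new <- (lo + hi) / 2  # bisection safeguard
    }
    if (abs(k_new - k) < 1e-10 * (1 + k)) {
      k <- k_new
      break
    }
    k <- k_new
  }
  ll <- sum(stats::dgamma(x, shape = k, rate = k, log = TRUE))
  ks <- suppressWarnings(
    ks.test(x, stats::pgamma, k, k, exact = n < 30)
  )
  new_dist_fit("unit_mean_gamma", c(k = k), n, ll, ks)
}

#' Pairwise collapse test between normalized distributions
#'
#' Quantifies how well several normalized distributions collapse on a
#' master curve: every pair of groups is compared with a two-sample
#' Kolmogorov-Smirnov test, and the collapse is summarized by the maximum
#' pairwise KS statistic.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 10),
#'   already normalized (e.g. with [normalize_areas()] or [rescale_ar()]).
#' @return A tibble of class `collapse_test` with one row per unordered
#'   pair: `group1`, `group2`, `n1`, `n2`, `ks_statistic`, `ks_p`. The
#'   summary statistic is in `attr(, "max_ks")`.
#' @export
#' @examples
#' set.seed(1)
#' g <- list(a = rlnorm(200), b = rlnorm(200))
#' collapse_test(lapply(g, function(x) x / mean(x)))
collapse_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two numeric vectors.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  purrr::walk2(groups, names(groups), function(g, nm) {
    check_numeric_vec(g, nm, min_len = 10L)
  })
  pairs <- utils::combn(names(groups), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ks <- suppressWarnings(ks.test(groups[[a]], groups[[b]]))
    tibble(
      group1 = a, group2 = b,
      n1 = length(groups[[a]]), n2 = length(groups[[b]]),
      ks_statistic = unname(ks$statistic), ks_p = unname(ks$p.value)
    )
  })
  attr(out, "max_ks") <- max(out$ks_statistic)
  class(out) <- c("collapse_test", class(out))
  out
}
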