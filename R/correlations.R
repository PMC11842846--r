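#' Correlation report with permutation inference
#'
#' Computes the Pearson correlation (covariance over the product of standard
#' deviations), the Spearman correlation (Pearson on average ranks), the
#' Fisher-z 95% confidence interval, the least-squares line, and a Monte
#' Carlo permutation p-value obtained by permuting `y` against `x`:
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + B)}.
#'
#' @param x,y Equal-length finite numeric vectors, n >= 3, each with
#'   non-zero variance.
#' @param n_permutations Number of random permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @param names Optional character vector of length 2 naming the variables.
#' @return An object of class `correlation_report`: a list with fields
#'   `x_name`, `y_name`, `n`, `pearson_r`, `spearman_rho`, `ci95_low`,
#'   `ci95_high`, `slope`, `intercept`, `permutation_p`, `n_permutations`,
#'   `seed`, and the raw `x`, `y` (kept for family-level FDR).
#' @seealso [fisher_ci()], [fdr_monte_carlo()], [tidy.correlation_report()]
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' correlate(x, y, n_permutations = 500, seed = 2)
correlate <- function(x, y, n_permutations = 10000, seed = 1L,
                      conf_level = 0.95, names = NULL) {
  check_numeric_vec(x, "x", min_len = 3L)
  check_numeric_vec(y, "y", min_len = 3L)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  seed <- check_count(seed, "seed", 0L)
  n <- length(x)
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined: zero variance in `x` or `y`.")
  }
  r <- pearson_r(x, y)
  rho <- pearson_r(rank(x), rank(y))  # average ranks on ties
  fit <- lm_line(x, y)
  ci <- if (abs(r) < 1) fisher_ci(r, n, conf_level) else c(NA_real_, NA_real_)
  # permutation null: one vector shuffled against the other; arguments are
  # ordered canonically first so the p-value is exactly swap-invariant
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  ab <- canonical_pair(x, y)
  r_null <- permuted_r(ab[[1]], ab[[2]], n_permutations)
  p <- (1 + sum(abs(r_null) >= abs(r) - 1e-12)) / (1 + n_permutations)
  nm <- names %||% c(deparse(substitute(x))[1], deparse(substitute(y))[1])
  structure(
    list(
      x_name = nm[1], y_name = nm[2], n = n,
      pearson_r = r, spearman_rho = rho,
      ci95_low = ci[1], ci95_high = ci[2],
      slope = fit["slope"], intercept = fit["intercept"],
      permutation_p = p, n_permutations = n_permutations, seed = seed,
      x = x, y = y
    ),
    class = "correlation_report"
  )
}

# direct covariance / sd-product form
pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

lm_line <- function(x, y) {
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# deterministic symmetric ordering of two vectors (first differing element)
canonical_pair <- function(x, y) {
  i <- which(x != y)
  if (length(i) > 0 && x[i[1]] > y[i[1]]) list(y, x) else list(x, y)
}

permuted_r <- function(x, y, B) {
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  vapply(seq_len(B), function(b) {
    yp <- y[sample.int(length(y))]
    yc <- yp - mean(yp)
    sum(xc * yc) / (sx * sqrt(sum(yc^2)))
  }, numeric(1))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report: %s ~ %s>\n", x$y_name, x$x_name))
  cat(sprintf("  n = %d, Pearson r = %.3f [%.3f, %.3f], Spearman rho = %.3f\n",
              x$n, x$pearson_r, x$ci95_low, x$ci95_high, x$spearman_rho))
  cat(sprintf("  permutation p = %.3g (%d permutations)\n",
              x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' Transforms \eqn{z = \mathrm{atanh}(r)}, whose sampling distribution is
#' approximately normal with standard error \eqn{1/\sqrt{n-3}}, and maps the
#' interval back with \eqn{\tanh}.
#'
#' @param r Observed correlation, |r| < 1.
#' @param n Sample size, >= 4.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' fisher_ci(0.637, 124)  # c(0.519, 0.731)
fisher_ci <- function(r, n, level = 0.95) {
  check_number(r, "r", lower = -1, upper = 1)
  n <- check_count(n, "n", 4L)
  check_number(level, "level", lower = 0.5, upper = 1 - 1e-9)
  if (abs(r) >= 1 - 1e-12) {
    abort("|r| = 1: the Fisher-z interval is degenerate.")
  }
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Monte Carlo permutation FDR for a family of correlations
#'
#' Estimates an empirical false discovery rate for each correlation in a
#' family from a pooled permutation null: each report's stored data are
#' permuted `n_permutations` times, the null |r| values are pooled across
#' the family, and for report i
#' \deqn{FDR_i = \frac{E[\#\{null\ |r| \ge |r_i|\}]}{\#\{observed\ |r_j| \ge |r_i|\}}}
#' where the numerator is the pooled null exceedance scaled to one family.
#' Values are capped at 1 and made monotone decreasing in |r|.
#'
#' @param reports List of `correlation_report` objects (with raw data).
#' @param n_permutations Permutations per report (default 1000).
#' @param seed RNG seed.
#' @return A tibble with columns `x_name`, `y_name`, `pearson_r`,
#'   `permutation_p`, `fdr`, in the input order.
#' @export
#' @examples
#' set.seed(1)
#' reps <- lapply(1:3, function(i) {
#'   x <- rnorm(40); correlate(x, x + rnorm(40), 200, seed = i)
#' })
#' fdr_monte_carlo(reps, n_permutations = 200, seed = 9)
fdr_monte_carlo <- function(reports, n_permutations = 1000, seed = 1L) {
  if (inherits(reports, "correlation_report")) reports <- list(reports)
  if (!is.list(reports) || length(reports) < 1 ||
      !all(vapply(reports, inherits, logical(1), "correlation_report"))) {
    abort("`reports` must be a list of `correlation_report` objects.")
  }
  missing_raw <- vapply(reports, function(r) is.null(r$x) || is.null(r$y),
                        logical(1))
  if (any(missing_raw)) {
    abort("cannot permute: raw data missing from some reports.")
  }
  n_permutations <- check_count(n_permutations, "n_permutations", 1L)
  seed <- check_count(seed, "seed", 0L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  m <- length(reports)
  r_obs <- abs(vapply(reports, function(r) r$pearson_r, numeric(1)))
  null_pool <- unlist(lapply(reports, function(rep) {
    ab <- canonical_pair(rep$x, rep$y)
    abs(permuted_r(ab[[1]], ab[[2]], n_permutations))
  }))
  fdr <- vapply(seq_len(m), function(i) {
    # expected null exceedances in a family of m tests
    e_false <- m * (1 + sum(null_pool >= r_obs[i] - 1e-12)) /
      (1 + length(null_pool))
    observed <- sum(r_obs >= r_obs[i] - 1e-12)
    min(e_false / observed, 1)
  }, numeric(1))
  # enforce monotonicity: a stronger |r| never has a larger FDR
  ord <- order(r_obs, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  tibble(
    x_name = vapply(reports, function(r) r$x_name, character(1)),
    y_name = vapply(reports, function(r) r$y_name, character(1)),
    n = vapply(reports, function(r) r$n, numeric(1)),
    pearson_r = vapply(reports, function(r) r$pearson_r, numeric(1)),
    permutation_p = vapply(reports, function(r) r$permutation_p, numeric(1)),
    fdr = fdr
  )
}

#' Spatial autocorrelation of a per-cell value
#'
#' Computes the distance-binned spatial autocorrelation of a scalar value
#' measured at cell centroids: for each distance bin the mean product of
#' mean-centered values over all unordered pairs in the bin, normalized by
#' the variance. The zero-distance bin contains the self-pairs and is 1 by
#' construction.
#'
#' @param values Numeric vector of per-cell values.
#' @param centroids Two-column matrix or data frame of centroid coordinates
#'   (same length as `values`), in micrometres.
#' @param bin_width Width of the distance bins (micrometres).
#' @param max_distance Largest pair distance retained (default: half the
#'   maximum observed distance).
#' @return A tibble of class `autocorrelation_curve` with columns
#'   `distance` (bin center), `correlation`, `n_pairs`, and `flagged`
#'   (TRUE for bins with fewer than 10 pairs).
#' @export
#' @examples
#' set.seed(1)
#' xy <- matrix(runif(200) * 100, ncol = 2)
#' spatial_autocorrelation(rnorm(100), xy, bin_width = 10)
spatial_autocorrelation <- function(values, centroids, bin_width,
                                    max_distance = NULL) {
  check_numeric_vec(values, "values", min_len = 2L)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(values) || ncol(centroids) != 2) {
    abort("`centroids` must be a 2-column matrix matching `values`.")
  }
  check_number(bin_width, "bin_width", lower = 1e-12)
  n <- length(values)
  v <- values - mean(values)
  s2 <- mean(v^2)
  if (s2 == 0) abort("`values` has zero variance.")
  d <- as.vector(dist(centroids))
  ij <- utils::combn(n, 2)
  prod_pairs <- v[ij[1, ]] * v[ij[2, ]] / s2
  if (is.null(max_distance)) max_distance <- max(max(d) / 2, min(d))
  # whole bins only: a truncated final bin would carry too few pairs
  n_bins <- max(1L, floor(max_distance / bin_width))
  keep <- d < n_bins * bin_width
  if (!any(keep)) {
    out <- tibble(distance = 0, correlation = 1, n_pairs = n,
                  flagged = FALSE)
    class(out) <- c("autocorrelation_curve", class(out))
    return(out)
  }
  bins <- floor(d[keep] / bin_width) + 1L
  sums <- tapply(prod_pairs[keep], bins, sum)
  counts <- table(factor(bins, levels = seq_len(n_bins)))
  corr <- rep(NA_real_, n_bins)
  corr[as.integer(names(sums))] <- sums / as.integer(counts[names(sums)])
  out <- tibble(
    distance = c(0, (seq_len(n_bins) - 0.5) * bin_width),
    correlation = c(1, corr),
    n_pairs = c(n, as.integer(counts)),
    flagged = c(FALSE, as.integer(counts) < 10)
  )
  class(out) <- c("autocorrelation_curve", class(out))
  out
}
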