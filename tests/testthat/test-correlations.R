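test_that("perfect linear relation gives r = 1 at the permutation floor", {
  x <- as.numeric(1:10)
  rep <- correlate(x, 2 * x + 1, n_permutations = 500, seed = 1)
  expect_equal(rep$pearson_r, 1.0)
  expect_equal(rep$spearman_rho, 1.0)
  expect_equal(rep$permutation_p, 1 / 501)
  expect_equal(unname(rep$slope), 2)
  expect_equal(unname(rep$intercept), 1)
})

test_that("Pearson matches the covariance/sd-product oracle to 1e-12", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:1000, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    rep <- correlate(x, y, n_permutations = 10, seed = 1)
    expect_equal(rep$pearson_r, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(rep$spearman_rho, oracle_pearson(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
})

test_that("permutation p is seed-deterministic and swap-invariant", {
  set.seed(9)
  x <- rnorm(80); y <- 0.2 * x + rnorm(80)
  a <- correlate(x, y, n_permutations = 300, seed = 42)
  b <- correlate(x, y, n_permutations = 300, seed = 42)
  swapped <- correlate(y, x, n_permutations = 300, seed = 42)
  expect_identical(a$permutation_p, b$permutation_p)
  expect_identical(a$permutation_p, swapped$permutation_p)
  expect_error(correlate(rep(1, 10), rnorm(10), 100, 1), "zero variance")
})

test_that("permutation p is approximately uniform under independence", {
  ps <- vapply(1:150, function(i) {
    set.seed(1000 + i)
    correlate(rnorm(60), rnorm(60), n_permutations = 200,
              seed = i)$permutation_p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.10)
  expect_gt(min(ps), 0)
})

test_that("a strong correlation at the study scale is highly significant", {
  # construct r ~ 0.637 at n = 124, the subconfluent-timepoint geometry
  set.seed(17)
  n <- 124
  x <- rnorm(n)
  y <- 0.637 * x + sqrt(1 - 0.637^2) * rnorm(n)
  y <- y + (0.637 - cor(x, y)) * x  # nudge toward the target r
  rep <- correlate(x, y, n_permutations = 2000, seed = 3)
  expect_gt(abs(rep$pearson_r), 0.5)
  expect_lt(rep$permutation_p, 0.001)
})

test_that("Fisher-z interval reproduces the printed nucleus-cell CI", {
  ci <- fisher_ci(0.637, 124)
  expect_equal(round(ci[2], 3), 0.731)
  expect_lt(abs(ci[1] - 0.519), 0.001)
  # null case: symmetric, half-width z_crit/sqrt(n-3)
  ci0 <- fisher_ci(0, 10003)
  expect_equal(ci0[1], -ci0[2])
  expect_equal(round(ci0[2], 4), 0.0196)
  expect_error(fisher_ci(1, 50), "degenerate")
  # reconstruction: r inside its own interval
  set.seed(1)
  for (r in c(-0.8, -0.2, 0.3, 0.9)) {
    ci <- fisher_ci(r, 60)
    expect_true(ci[1] < r && r < ci[2])
  }
})

test_that("FDR of a single perfect correlation sits at the resolution
           floor", {
  x <- as.numeric(1:20)
  rep <- correlate(x, 3 * x, n_permutations = 200, seed = 1)
  out <- fdr_monte_carlo(list(rep), n_permutations = 200, seed = 2)
  expect_equal(out$fdr, 1 / 201)
})

test_that("strong correlations receive uniformly lower FDR than null
           pairs", {
  set.seed(8)
  n <- 100
  reports <- c(
    lapply(1:10, function(i) {
      x <- rnorm(n)
      correlate(x, 0.8 * x + 0.6 * rnorm(n), n_permutations = 100,
                seed = i, names = c("x", paste0("strong", i)))
    }),
    lapply(1:10, function(i) {
      correlate(rnorm(n), rnorm(n), n_permutations = 100,
                seed = 100 + i, names = c("x", paste0("null", i)))
    })
  )
  out <- fdr_monte_carlo(reports, n_permutations = 100, seed = 5)
  strong <- out$fdr[1:10]
  null <- out$fdr[11:20]
  expect_lt(max(strong), min(null))
  # FDR is monotone in |r|
  ord <- order(-abs(out$pearson_r))
  expect_true(all(diff(out$fdr[ord]) >= 0))
})

test_that("null families rarely produce FDR discoveries", {
  hits <- vapply(1:40, function(rep_i) {
    set.seed(3000 + rep_i)
    reports <- lapply(1:10, function(i) {
      correlate(rnorm(60), rnorm(60), n_permutations = 60, seed = i)
    })
    sum(fdr_monte_carlo(reports, n_permutations = 60,
                        seed = rep_i)$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(hits), 1)
})

test_that("spatial autocorrelation separates random from smooth fields", {
  set.seed(4)
  n <- 600
  xy <- matrix(runif(2 * n) * 300, ncol = 2)
  curve_rand <- spatial_autocorrelation(rnorm(n), xy, bin_width = 15)
  expect_equal(curve_rand$correlation[1], 1)
  expect_equal(curve_rand$distance[1], 0)
  off <- curve_rand[-1, ]
  expect_true(all(abs(off$correlation[!off$flagged]) < 0.1))

  smooth_v <- sin(xy[, 1] / 80) + cos(xy[, 2] / 80)
  curve_smooth <- spatial_autocorrelation(smooth_v, xy, bin_width = 15)
  expect_gt(curve_smooth$correlation[2], 0.5)
})

test_that("two points yield a single off-zero pair", {
  curve <- spatial_autocorrelation(c(1, 2), rbind(c(0, 0), c(3, 4)),
                                   bin_width = 10)
  expect_equal(nrow(curve), 2)
  expect_equal(curve$n_pairs[2], 1)
})
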