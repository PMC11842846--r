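make_regression_data <- function(n = 500, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
    n4 = rnorm(n), n5 = rnorm(n)
  )
  d$y_exact <- 3 * d$f1 - d$f2
  d$y_noisy <- d$f1 + rnorm(n, 0, 0.5)
  d$y_sine <- sin(2 * pi * d$f1) + rnorm(n, 0, 0.1)
  d
}

test_that("a noiseless linear target is recovered exactly", {
  d <- make_regression_data()
  pr <- predict_target(d, "y_exact", c("f1", "f2", "f3"), "linear",
                       seed = 2)
  expect_gte(pr$prediction_r, 0.999)
})

test_that("single-predictor linear CV reproduces the direct Pearson r", {
  feats <- fixture_features("default")
  pr <- predict_target(feats, "nucleus_area", "cell_area", "linear",
                       seed = 4)
  direct <- cor(feats$cell_area, feats$nucleus_area)
  expect_lt(abs(pr$prediction_r - direct), 0.05)
})

test_that("the SE-kernel model captures nonlinearity the linear model
           misses", {
  d <- make_regression_data(n = 400, seed = 3)
  pl <- predict_target(d, "y_sine", c("f1", "f2"), "linear", seed = 5)
  pk <- predict_target(d, "y_sine", c("f1", "f2"), "se_kernel", seed = 5)
  expect_gte(pk$prediction_r - pl$prediction_r, 0.2)
})

test_that("cross-validation is deterministic given the seed and robust to
           noise predictors", {
  d <- make_regression_data(n = 600, seed = 6)
  a <- predict_target(d, "y_noisy", c("f1", "f2"), "linear", seed = 11)
  b <- predict_target(d, "y_noisy", c("f1", "f2"), "linear", seed = 11)
  expect_identical(a$prediction_r, b$prediction_r)
  expect_identical(a$fold_id, b$fold_id)
  with_noise <- predict_target(
    d, "y_noisy", c("f1", "f2", "n1", "n2", "n3", "n4", "n5"),
    "linear", seed = 11
  )
  expect_lt(abs(with_noise$prediction_r - a$prediction_r), 0.05)
})

test_that("constant targets and missing columns are rejected", {
  d <- make_regression_data(n = 50)
  d$const <- 1
  expect_error(predict_target(d, "const", "f1"), "constant target")
  expect_error(predict_target(d, "y_exact", "nope"), "not found")
  expect_error(predict_target(d[1:10, ], "y_exact", "f1"), "at least 30")
})

test_that("DAPI intensity statistics are auto-excluded for histone
           targets", {
  feats <- fixture_features("default")
  pr <- predict_target(
    feats, "H3K27me3_norm",
    c("nucleus_area", "DAPI_mean", "DAPI_sd", "DAPI_cv"),
    "linear", seed = 1
  )
  expect_identical(pr$predictors, "nucleus_area")
})

test_that("dropout importance finds the informative predictor", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    n <- 150
    d <- data.frame(sig = rnorm(n), matrix(rnorm(n * 5), ncol = 5))
    names(d)[2:6] <- paste0("z", 1:5)
    d$y <- d$sig + rnorm(n, 0, 0.5)
    imp <- dropout_importance(d, "y", c("sig", paste0("z", 1:5)),
                              "linear", seed = s)
    imp$feature[imp$rank == 1] == "sig"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("duplicated predictors compensate for each other in dropout", {
  set.seed(4)
  n <- 400
  d <- data.frame(a = rnorm(n))
  d$b <- d$a
  d$c <- rnorm(n)
  d$y <- 2 * d$a + rnorm(n, 0, 0.3)
  imp <- dropout_importance(d, "y", c("a", "b", "c"), "linear", seed = 2)
  expect_lt(abs(imp$delta_r[imp$feature == "a"]), 0.02)
  expect_lt(abs(imp$delta_r[imp$feature == "b"]), 0.02)
})

test_that("pure-noise predictors have near-zero dropout importance", {
  set.seed(9)
  n <- 500
  d <- as.data.frame(matrix(rnorm(n * 4), ncol = 4))
  d$y <- rnorm(n)
  imp <- dropout_importance(d, "y", paste0("V", 1:4), "linear", seed = 3)
  expect_true(all(abs(imp$delta_r) < 0.05))
  expect_setequal(imp$rank, 1:4)
})

test_that("CCA recovers identical, independent, and latent-factor
           structure", {
  set.seed(21)
  X <- matrix(rnorm(1000 * 3), ncol = 3)
  ident <- cca_predict(X, X + 0)
  expect_equal(ident$correlations[1], 1.0, tolerance = 1e-9)

  Y <- matrix(rnorm(1000 * 3), ncol = 3)
  indep <- cca_predict(X, Y)
  expect_lt(indep$correlations[1], 0.15)

  # one shared latent factor, three unit-noise indicators per block:
  # best combo correlates sqrt(3)/2 with the factor, so the first
  # canonical correlation is (sqrt(3)/2)^2 = 0.75
  n <- 2000
  f <- rnorm(n)
  Xb <- matrix(f, n, 3) + matrix(rnorm(n * 3), n, 3)
  Yb <- matrix(f, n, 3) + matrix(rnorm(n * 3), n, 3)
  lat <- cca_predict(Xb, Yb)
  expect_lt(abs(lat$correlations[1] - 0.75), 0.05)
  expect_lt(abs(lat$first_variate_r - lat$correlations[1]), 1e-9)
})

test_that("PCA biplot data behaves on degenerate and isotropic panels", {
  set.seed(31)
  base <- rnorm(300)
  d2 <- data.frame(a = base, b = 2 * base)
  p2 <- pca_biplot_data(d2)
  expect_equal(p2$variance_fraction[1], 1.0, tolerance = 1e-12)

  iso <- as.data.frame(matrix(rnorm(5000 * 3), ncol = 3))
  pi3 <- pca_biplot_data(iso)
  expect_true(all(abs(pi3$variance_fraction - 1 / 3) < 0.03))
  expect_equal(sum(pi3$variance_fraction), 1.0)

  iso$flat <- 1
  expect_warning(pf <- pca_biplot_data(iso), "constant")
  expect_equal(length(pf$features_used), 3)
})

test_that("tidiers return well-formed tibbles", {
  d <- make_regression_data(n = 100)
  pr <- predict_target(d, "y_noisy", c("f1", "f2"), "linear", seed = 1)
  g <- generics::glance(pr)
  expect_equal(g$n, 100)
  expect_equal(g$prediction_r, pr$prediction_r)
  t <- generics::tidy(pr)
  expect_equal(nrow(t), 100)
})
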