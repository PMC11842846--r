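# predictor groups mirroring the morphological feature panel
CELL_MORPH_FEATURES <- c(
  "cell_area", "cell_perimeter", "cell_major_axis", "cell_minor_axis",
  "cell_aspect_ratio", "cell_shape_index", "cell_solidity",
  "cell_circularity", "cell_roundness"
)
NUCLEUS_MORPH_FEATURES <- c(
  "nucleus_area", "nucleus_perimeter", "nucleus_major_axis",
  "nucleus_minor_axis", "nucleus_aspect_ratio", "nucleus_shape_index",
  "nucleus_solidity", "nucleus_circularity", "nucleus_roundness"
)
NC_RATIO_FEATURES <- c("nc_area_ratio", "nc_ar_ratio")

# DAPI intensity statistics are never allowed to predict DAPI-normalized
# histone levels (their correlation is arithmetic, not biological)
DAPI_EXCLUDED <- c("DAPI_mean", "DAPI_sd", "DAPI_cv")

is_histone_target <- function(target) {
  grepl("_norm$", target) || grepl("^H3K", target)
}

#' Cross-validated prediction of one feature from others
#'
#' Fits either an ordinary least-squares linear model or a
#' squared-exponential kernel (Gaussian process) regression to predict
#' `target` from `predictors`, using seeded k-fold cross-validation;
#' predicted values come only from held-out folds. Prediction accuracy is
#' the Pearson correlation between out-of-fold predictions and measured
#' values. For DAPI-normalized histone targets the DAPI mean/sd/CV columns
#' are removed from the predictor list automatically.
#'
#' Predictors (and the target, for the kernel model) are z-scored inside
#' each training fold. Kernel hyperparameters (length scale around the
#' median heuristic, noise level) are chosen by an inner grid search on the
#' training folds.
#'
#' @param features Feature table (one row per cell).
#' @param target Name of the column to predict.
#' @param predictors Character vector of predictor column names.
#' @param model `"linear"` or `"se_kernel"`.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @return An object of class `prediction_result` with fields `target`,
#'   `predictors`, `model`, `n`, `folds`, `seed`, `prediction_r`,
#'   `predicted`, `measured`, `fold_id`.
#' @seealso [dropout_importance()], [tidy.prediction_result()]
#' @export
predict_target <- function(features, target, predictors,
                           model = c("linear", "se_kernel"),
                           folds = 5, seed = 1L) {
  model <- match.arg(model)
  folds <- check_count(folds, "folds", 2L)
  seed <- check_count(seed, "seed", 0L)
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  if (!target %in% names(features)) {
    abort(sprintf("target `%s` not found.", target))
  }
  if (is_histone_target(target)) {
    dropped <- intersect(predictors, DAPI_EXCLUDED)
    if (length(dropped) > 0) {
      predictors <- setdiff(predictors, DAPI_EXCLUDED)
    }
  }
  missing_p <- setdiff(predictors, names(features))
  if (length(missing_p) > 0) {
    abort(sprintf("predictors not found: %s",
                  paste(missing_p, collapse = ", ")))
  }
  if (length(predictors) < 1) abort("no predictors left.")
  dat <- features[c(target, predictors)]
  dat <- dat[complete.cases(dat), ]
  n <- nrow(dat)
  if (n < 30) abort("need at least 30 complete records.")
  y <- dat[[target]]
  if (var(y) == 0) abort("constant target; prediction undefined.")
  X <- as.matrix(dat[predictors])

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdev, "/")
    if (model == "linear") {
      # least squares via pseudoinverse; tolerant of rank deficiency
      A <- cbind(1, Xtr)
      fit <- qr(A, LAPACK = TRUE)
      if (fit$rank < ncol(A)) {
        warn("rank-deficient predictor matrix; using pseudoinverse.")
        co <- MASS_ginv(A) %*% y[tr]
      } else {
        co <- qr.coef(fit, y[tr])
        co[is.na(co)] <- 0
      }
      pred[te] <- cbind(1, Xte) %*% co
    } else {
      pred[te] <- se_kernel_predict(Xtr, y[tr], Xte)
    }
  }
  r <- pearson_r(pred, y)
  structure(
    list(
      target = target, predictors = predictors, model = model,
      n = n, folds = folds, seed = seed,
      prediction_r = r, predicted = pred, measured = y, fold_id = fold_id
    ),
    class = "prediction_result"
  )
}

# minimal pseudoinverse (SVD); avoids importing MASS for one call
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# SE-kernel GP regression with inner-CV hyperparameter grid:
# length scale = median heuristic x {0.25, 1, 4}, noise in {1e-3, 1e-2, 1e-1}
se_kernel_predict <- function(Xtr, ytr, Xte) {
  ymu <- mean(ytr); ysd <- sd(ytr)
  if (ysd == 0) return(rep(ymu, nrow(Xte)))
  yz <- (ytr - ymu) / ysd
  d2 <- as.matrix(dist(Xtr))^2
  med <- median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  grid <- expand.grid(
    ell = med * c(0.25, 1, 4),
    noise = c(1e-3, 1e-2, 1e-1)
  )
  n <- nrow(Xtr)
  inner <- rep(seq_len(3), length.out = n)[sample.int(n)]
  score <- vapply(seq_len(nrow(grid)), function(g) {
    ell <- grid$ell[g]; noise <- grid$noise[g]
    sse <- 0
    for (f in 1:3) {
      tr <- inner != f
      K <- exp(-d2[tr, tr, drop = FALSE] / (2 * ell^2))
      Ks <- exp(-d2[!tr, tr, drop = FALSE] / (2 * ell^2))
      alpha <- solve(K + diag(noise, sum(tr)), yz[tr])
      sse <- sse + sum((yz[!tr] - Ks %*% alpha)^2)
    }
    sse
  }, numeric(1))
  best <- grid[which.min(score), ]
  kp <- kernlab::gausspr(
    x = Xtr, y = yz, kernel = "rbfdot",
    kpar = list(sigma = 1 / (2 * best$ell^2)),
    var = max(best$noise, 1e-4), scaled = FALSE
  )
  as.vector(kernlab::predict(kp, Xte)) * ysd + ymu
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result: %s ~ %d predictors, %s>\n",
              x$target, length(x$predictors), x$model))
  cat(sprintf("  n = %d, %d-fold CV, prediction r = %.3f\n",
              x$n, x$folds, x$prediction_r))
  invisible(x)
}

#' Single-feature dropout importance ranking
#'
#' Quantifies each predictor's importance as the drop in cross-validated
#' prediction accuracy (Pearson r between predicted and measured) when
#' that predictor alone is removed and the model is refit on the same
#' folds. Ties in the ranking are broken by predictor name order.
#'
#' @inheritParams predict_target
#' @return A tibble of class `importance_ranking` with columns `feature`,
#'   `delta_r` (full-model r minus reduced-model r), `rank`; the
#'   full-model r is in `attr(, "full_r")`.
#' @export
dropout_importance <- function(features, target, predictors,
                               model = c("linear", "se_kernel"),
                               folds = 5, seed = 1L) {
  model <- match.arg(model)
  if (is_histone_target(target)) {
    predictors <- setdiff(predictors, DAPI_EXCLUDED)
  }
  if (length(predictors) < 2) {
    abort("need at least 2 predictors for a dropout analysis.")
  }
  full <- predict_target(features, target, predictors, model, folds, seed)
  delta <- vapply(predictors, function(p) {
    red <- predict_target(features, target, setdiff(predictors, p),
                          model, folds, seed)
    full$prediction_r - red$prediction_r
  }, numeric(1))
  ord <- order(-delta, predictors)
  out <- tibble(
    feature = predictors,
    delta_r = delta,
    rank = match(predictors, predictors[ord])
  )
  attr(out, "full_r") <- full$prediction_r
  attr(out, "model") <- model
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Canonical correlation between cell and nucleus feature blocks
#'
#' Runs canonical correlation analysis between two standardized feature
#' blocks, reporting the canonical correlations in descending order, the
#' variate loadings, and the first-variate prediction correlation for the
#' nucleus block. A near-singular within-block covariance is regularized
#' with a small logged ridge term.
#'
#' @param cell_features,nucleus_features Data frames (or matrices) with the
#'   same number of rows; each column is one feature.
#' @return A list of class `cca_result` with `correlations`, `x_loadings`,
#'   `y_loadings`, `x_scores`, `y_scores`, `first_variate_r`, `n`,
#'   `ridge_used`.
#' @export
cca_predict <- function(cell_features, nucleus_features) {
  X <- as.matrix(cell_features)
  Y <- as.matrix(nucleus_features)
  if (nrow(X) != nrow(Y)) abort("blocks must have the same rows.")
  if (ncol(X) < 2 || ncol(Y) < 2) abort("each block needs >= 2 features.")
  n <- nrow(X)
  if (n <= ncol(X) + ncol(Y)) abort("need n > total feature count.")
  zscore <- function(M) {
    s <- apply(M, 2, sd)
    if (any(s == 0)) abort("constant feature in a CCA block.")
    sweep(sweep(M, 2, colMeans(M)), 2, s, "/")
  }
  X <- zscore(X); Y <- zscore(Y)
  ridge_used <- 0
  cc <- tryCatch(
    cancor(X, Y),
    error = function(e) NULL
  )
  if (is.null(cc) || min(svd(crossprod(X) / (n - 1))$d) < 1e-8 ||
      min(svd(crossprod(Y) / (n - 1))$d) < 1e-8) {
    ridge_used <- 1e-6
    warn("near-singular within-block covariance; ridge term 1e-6 added.")
    X <- rbind(X, diag(sqrt(ridge_used * (n - 1)), ncol(X),
                       ncol(X)))
    Y <- rbind(Y, matrix(0, ncol(X), ncol(Y)))
    X <- rbind(X, matrix(0, ncol(Y), ncol(X)))
    Y <- rbind(Y, diag(sqrt(ridge_used * (n - 1)), ncol(Y), ncol(Y)))
    cc <- cancor(X, Y)
    X <- X[seq_len(n), , drop = FALSE]
    Y <- Y[seq_len(n), , drop = FALSE]
  }
  xs <- X %*% cc$xcoef[, 1, drop = FALSE]
  ys <- Y %*% cc$ycoef[, 1, drop = FALSE]
  structure(
    list(
      correlations = cc$cor,
      x_loadings = cc$xcoef,
      y_loadings = cc$ycoef,
      x_scores = X %*% cc$xcoef,
      y_scores = Y %*% cc$ycoef,
      first_variate_r = pearson_r(as.vector(xs), as.vector(ys)),
      n = n,
      ridge_used = ridge_used
    ),
    class = "cca_result"
  )
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result>\n")
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Principal component decomposition of a feature panel
#'
#' Standardizes (z-scores) the selected features and decomposes them with
#' PCA, returning the biplot ingredients: loadings, scores, and explained
#' variance fractions (which sum to 1). Constant features are dropped with
#' a warning.
#'
#' @param features Feature table.
#' @param include Character vector of columns to include (default: all
#'   numeric columns).
#' @return A list of class `pca_result` with `loadings`, `scores`,
#'   `variance_fraction`, `features_used`, `dropped`.
#' @export
pca_biplot_data <- function(features, include = NULL) {
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  include <- include %||%
    names(features)[vapply(features, is.numeric, logical(1))]
  missing_f <- setdiff(include, names(features))
  if (length(missing_f) > 0) {
    abort(sprintf("features not found: %s",
                  paste(missing_f, collapse = ", ")))
  }
  M <- as.matrix(features[include])
  M <- M[complete.cases(M), , drop = FALSE]
  if (nrow(M) <= ncol(M)) abort("need n > number of features.")
  s <- apply(M, 2, sd)
  dropped <- include[s == 0]
  if (length(dropped) > 0) {
    warn(sprintf("dropping constant features: %s",
                 paste(dropped, collapse = ", ")))
    M <- M[, s > 0, drop = FALSE]
    include <- include[s > 0]
  }
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      loadings = pc$rotation,
      scores = pc$x,
      variance_fraction = vf,
      features_used = include,
      dropped = dropped
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", head(x$variance_fraction, 5)), collapse = ", "),
      if (length(x$variance_fraction) > 5) "..." else "", "\n")
  invisible(x)
}
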