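# Brute-force oracles, written independently of the package internals:
# plain loops and direct formula evaluation on small inputs.

# mask builders -----------------------------------------------------------

disk_mask <- function(r, n = 2 * r + 21) {
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

square_mask <- function(s, pad = 4) {
  n <- s + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- TRUE
  m
}

rect_mask <- function(h, w, pad = 4) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

ellipse_mask <- function(a, b, theta = 0, n = 2 * max(a, b) + 11) {
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) {
    u <- (i - cx) * cos(theta) + (j - cx) * sin(theta)
    v <- -(i - cx) * sin(theta) + (j - cx) * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

# random blob: union of a few overlapping ellipses (connected, irregular)
blob_mask <- function(seed, n = 48) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  cx0 <- n / 2 + runif(1, -4, 4)
  cy0 <- n / 2 + runif(1, -4, 4)
  for (k in 1:3) {
    a <- runif(1, 5, 11); b <- runif(1, 4, 9); th <- runif(1, 0, pi)
    cx <- cx0 + runif(1, -4, 4); cy <- cy0 + runif(1, -4, 4)
    m <- m | outer(seq_len(n), seq_len(n), function(i, j) {
      u <- (i - cx) * cos(th) + (j - cx) * sin(th)
      v <- -(i - cy) * sin(th) + (j - cy) * cos(th)
      (u / a)^2 + (v / b)^2 <= 1
    })
  }
  m
}

# per-pixel feature oracle -------------------------------------------------

# direct-summation moments and crack/weighted perimeter, all plain loops
oracle_features <- function(mask, pixel_size = 1,
                            perimeter_method = "weighted") {
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  cx <- sum(px[, 1]) / n
  cy <- sum(px[, 2]) / n
  mxx <- sum((px[, 1] - cx)^2) / n
  myy <- sum((px[, 2] - cy)^2) / n
  mxy <- sum((px[, 1] - cx) * (px[, 2] - cy)) / n
  tr <- mxx + myy
  dp <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  major <- 4 * sqrt((tr + dp) / 2 + 1 / 12)
  minor <- 4 * sqrt(max((tr - dp) / 2, 0) + 1 / 12)

  at <- function(i, j) {
    i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) && mask[i, j]
  }
  per <- 0
  for (k in seq_len(n)) {
    i <- px[k, 1]; j <- px[k, 2]
    up <- !at(i - 1, j); down <- !at(i + 1, j)
    left <- !at(i, j - 1); right <- !at(i, j + 1)
    nb <- up + down + left + right
    if (perimeter_method == "crack") {
      per <- per + nb
    } else {
      adj <- (up && left) || (up && right) || (down && left) ||
        (down && right)
      per <- per + if (nb == 1) 1.02
      else if (nb == 2 && adj) 1.22
      else if (nb == 2) 2 * 1.02
      else if (nb == 3) 1.02 + 1.22
      else if (nb == 4) 2 * sqrt(pi)
      else 0
    }
  }
  xs <- c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5)
  ys <- c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  ha <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2

  area <- n * pixel_size^2
  perim <- per * pixel_size
  major <- major * pixel_size
  minor <- minor * pixel_size
  list(
    area = area, perimeter = perim, major_axis = major, minor_axis = minor,
    aspect_ratio = major / minor, shape_index = perim / sqrt(area),
    solidity = n / ha, circularity = area / perim^2,
    roundness = area / major^2
  )
}

# exact Euclidean distance transform by direct minimization
oracle_edt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, nr, nc)
  fg <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    i <- fg[k, 1]; j <- fg[k, 2]
    d[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  d
}

# sort-based radial split: exact bottom quantile of the distance transform
oracle_radial_split <- function(mask, split_fraction) {
  d <- oracle_edt(mask)
  idx <- which(mask)
  n <- length(idx)
  n_per <- round(split_fraction * n)
  ord <- order(d[mask], seq_len(n))
  list(
    periphery = sort(idx[ord[seq_len(n_per)]]),
    center = sort(idx[ord[seq.int(n_per + 1L, n)]])
  )
}

# statistics oracles -------------------------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  covxy <- sum((x - mean(x)) * (y - mean(y))) / n
  covxy / (sx * sy)
}

# grid search MLE for the unit-mean gamma shape
oracle_gamma_grid <- function(x, ks = seq(0.1, 20, by = 0.001)) {
  x <- x / mean(x)
  n <- length(x)
  slx <- sum(log(x)); sx <- sum(x)
  ll <- n * (ks * log(ks) - lgamma(ks)) + (ks - 1) * slx - ks * sx
  ks[which.max(ll)]
}

# Monte-Carlo oracle for the variance growth of the division process:
# resamples the same multiplicative split chain directly
oracle_division_var_slope <- function(sd_f, n_draws = 2e5) {
  f <- rnorm(n_draws, 0.5, sd_f)
  bad <- which(f <= 0.05 | f >= 0.95)
  while (length(bad) > 0) {
    f[bad] <- rnorm(length(bad), 0.5, sd_f)
    bad <- bad[f[bad] <= 0.05 | f[bad] >= 0.95]
  }
  var(log(f))  # variance added to ln(area) per generation
}
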