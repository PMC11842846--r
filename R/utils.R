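# internal argument checks ------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  as.integer(x)
}

check_numeric_vec <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(sprintf("`%s` must be a numeric vector of length >= %d.",
                  name, min_len))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", name))
  }
  invisible(x)
}

# second-moment ellipse of a point cloud; returns major/minor axis lengths
# (full lengths, 4 * sqrt(eigenvalue)) and orientation in radians
moment_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  tr <- mxx + myy
  det_part <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + det_part) / 2
  l2 <- max((tr - det_part) / 2, 0)
  list(
    centroid_x = mx, centroid_y = my,
    major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
    theta = 0.5 * atan2(2 * mxy, mxx - myy)
  )
}
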