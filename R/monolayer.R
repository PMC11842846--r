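# Anisotropic capacity-constrained tessellation.
#
# Seeds sit on a jittered square lattice, one per lattice cell, so every
# pixel only needs to inspect the 5x5 block of neighbouring lattice cells.
# Each seed carries an elliptical (unit-determinant) metric whose axis
# ratio is drawn from the gamma aspect-ratio model; the metric is scaled by
# (spacing^2 / target_area)^gamma and additive capacity weights are
# iterated on a coarse grid until realized areas track the log-normal
# targets. gamma = 0.85 is the null point at which the tessellation's
# geometric coupling between cell area and elongation vanishes, so the
# rendered field reproduces the sampling model's independence of area and
# aspect ratio.
assign_tessellation <- function(sx, sy, qa, qb, qc, w, nx, ny, spacing,
                                px, py) {
  cgx <- pmin(pmax(ceiling(px / spacing), 1L), nx)
  cgy <- pmin(pmax(ceiling(py / spacing), 1L), ny)
  bestd <- rep(Inf, length(px))
  bestl <- integer(length(px))
  for (dx in -2:2) {
    for (dy in -2:2) {
      ix <- cgx + dx; iy <- cgy + dy
      ok <- which(ix >= 1L & ix <= nx & iy >= 1L & iy <= ny)
      if (length(ok) == 0) next
      si <- (ix[ok] - 1L) * ny + iy[ok]
      ddx <- px[ok] - sx[si]; ddy <- py[ok] - sy[si]
      d <- qa[si] * ddx^2 + 2 * qb[si] * ddx * ddy + qc[si] * ddy^2 - w[si]
      upd <- d < bestd[ok]
      iu <- ok[upd]
      bestd[iu] <- d[upd]
      bestl[iu] <- si[upd]
    }
  }
  bestl
}

# periphery/center split of a connected mask: pixels below the distance
# quantile closest to the requested area fraction form the periphery
radial_split_indices <- function(mask, split_fraction) {
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- dm@.Data[mask]
  idx <- which(mask)
  n <- length(idx)
  n_per <- round(split_fraction * n)
  if (n_per <= 0) {
    return(list(periphery = integer(0), center = idx, distance = d))
  }
  if (n_per >= n) {
    return(list(periphery = idx, center = integer(0), distance = d))
  }
  ord <- order(d, seq_len(n))  # ties: scan order
  list(
    periphery = idx[ord[seq_len(n_per)]],
    center = idx[ord[(n_per + 1L):n]],
    distance = d
  )
}

#' Generate a synthetic labeled epithelial monolayer
#'
#' Renders a co-registered cell label mask, nucleus label mask, and
#' intensity channels with the statistical structure of a crowded
#' epithelial monolayer: cell areas follow the default log-normal
#' (mean-normalized \eqn{\ln x \sim N(-0.05, 0.095)}), aspect ratios follow
#' the rescaled unit-mean gamma (shape 2.43), nucleus areas couple to cell
#' areas through the NC ratio with multiplicative noise, per-nucleus
#' DAPI-normalized mark levels depend linearly on relative nucleus area,
#' and each mark's nuclear radial profile carries a periphery/center
#' contrast that varies with nucleus area.
#'
#' Cells partition the field (an anisotropic capacity-constrained
#' tessellation of a jittered lattice); nuclei are filled ellipses at the
#' cell centroid, oriented along the cell's long axis and clipped to their
#' cell. Everything is deterministic given `params$seed`.
#'
#' @param params A [monolayer_params()] object.
#' @return An object of class `labeled_monolayer`: a list with
#'   `cell_labels`, `nucleus_labels` (integer matrices sharing ids),
#'   `channels` (named list of non-negative matrices, `"DAPI"` first),
#'   `pixel_size`, `params`, `n_clipped` (nuclei clipped to their cell),
#'   and `ground_truth` (tibble of the sampled per-cell quantities used by
#'   generator/oracle equivalence tests).
#' @export
#' @examples
#' mono <- generate_monolayer(monolayer_params(n_cells = 25,
#'                                             field_size = 128, seed = 2))
#' table(mono$cell_labels > 0)
generate_monolayer <- function(params) {
  if (!inherits(params, "monolayer_params")) {
    abort("`params` must be created with `monolayer_params()`.")
  }
  set.seed(params$seed)
  nx <- max(round(sqrt(params$n_cells)), 2L)
  ny <- nx
  n <- nx * ny
  W <- params$field_size
  spacing <- W / nx
  if (spacing < 6) {
    abort("infeasible geometry: fewer than 6 px per cell diameter; ",
          "increase `field_size` or decrease `n_cells`.")
  }

  gx <- rep(seq_len(nx), each = ny)
  gy <- rep(seq_len(ny), times = nx)
  jit <- params$lattice_jitter * spacing
  sx <- (gx - 0.5) * spacing + runif(n, -jit, jit)
  sy <- (gy - 0.5) * spacing + runif(n, -jit, jit)

  mean_area_px <- W * W / n
  s_i <- rlnorm(n, params$area_lognormal_mu,
                sqrt(params$area_lognormal_sigma2))
  s_i <- s_i / mean(s_i)
  target <- s_i * mean_area_px

  cell_ar <- sample_aspect_ratios(n, params$ar_gamma_k, params$mean_ar)
  theta <- runif(n, 0, pi)
  e1 <- 1 / cell_ar; e2 <- cell_ar
  scale_fac <- (spacing^2 / target)^params$metric_size_exponent
  qa <- (e1 * cos(theta)^2 + e2 * sin(theta)^2) * scale_fac
  qc <- (e1 * sin(theta)^2 + e2 * cos(theta)^2) * scale_fac
  qb <- ((e1 - e2) * sin(theta) * cos(theta)) * scale_fac

  # capacity iteration on a coarse grid, then one full-resolution pass
  w <- (s_i - 1) * spacing^2 * 0.35
  cf <- params$coarse_factor
  if (params$capacity_iters > 0 && cf >= 1) {
    cs <- seq(cf / 2, W, by = cf)
    pxc <- rep(cs, times = length(cs))
    pyc <- rep(cs, each = length(cs))
    for (it in seq_len(params$capacity_iters)) {
      bl <- assign_tessellation(sx, sy, qa, qb, qc, w, nx, ny, spacing,
                                pxc, pyc)
      a <- tabulate(bl, n) * cf^2
      w <- w + params$capacity_eta * (target - a)
      w <- w - mean(w)
    }
  }
  px <- rep(seq_len(W) - 0.5, times = W)
  py <- rep(seq_len(W) - 0.5, each = W)
  bestl <- assign_tessellation(sx, sy, qa, qb, qc, w, nx, ny, spacing,
                               px, py)
  cell_labels <- matrix(as.integer(bestl), W, W)

  # nuclei: ellipse at the cell centroid, oriented along the cell long
  # axis, area = nc_ratio * cell_area * exp(eps), clipped to the cell
  areas_px <- tabulate(bestl, n)
  cx <- rowsum(px, factor(bestl, levels = seq_len(n)))[, 1] / pmax(areas_px, 1)
  cy <- rowsum(py, factor(bestl, levels = seq_len(n)))[, 1] / pmax(areas_px, 1)

  eps <- rnorm(n, 0, params$nc_noise_sd)
  nuc_target <- params$nc_ratio * areas_px * exp(eps)
  nuc_ar <- sample_aspect_ratios(n, params$ar_gamma_k, params$mean_ar)

  # cell orientation from second moments (per cell, on its pixel set)
  sxx <- rowsum(px^2, factor(bestl, levels = seq_len(n)))[, 1]
  syy <- rowsum(py^2, factor(bestl, levels = seq_len(n)))[, 1]
  sxy <- rowsum(px * py, factor(bestl, levels = seq_len(n)))[, 1]
  mxx <- sxx / pmax(areas_px, 1) - cx^2
  myy <- syy / pmax(areas_px, 1) - cy^2
  mxy <- sxy / pmax(areas_px, 1) - cx * cy
  cell_theta <- 0.5 * atan2(2 * mxy, mxx - myy)

  nucleus_labels <- matrix(0L, W, W)
  n_clipped <- 0L
  nuc_area_real <- numeric(n)
  for (i in seq_len(n)) {
    if (areas_px[i] == 0 || nuc_target[i] < 1) next
    a_half <- sqrt(nuc_target[i] * nuc_ar[i] / pi)
    b_half <- sqrt(nuc_target[i] / (pi * nuc_ar[i]))
    ext <- ceiling(a_half) + 1L
    r0 <- max(floor(cx[i] - ext), 1L); r1 <- min(ceiling(cx[i] + ext), W)
    c0 <- max(floor(cy[i] - ext), 1L); c1 <- min(ceiling(cy[i] + ext), W)
    rr <- seq(r0, r1); cc <- seq(c0, c1)
    dx <- rep(rr - 0.5, times = length(cc)) - cx[i]
    dy <- rep(cc - 0.5, each = length(rr)) - cy[i]
    ct <- cos(cell_theta[i]); st <- sin(cell_theta[i])
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    inside <- (u / a_half)^2 + (v / b_half)^2 <= 1
    sub_cell <- cell_labels[rr, cc, drop = FALSE]
    own <- sub_cell == i
    sel <- inside & as.vector(own)
    if (any(inside & !as.vector(own))) n_clipped <- n_clipped + 1L
    if (!any(sel)) {
      # degenerate: claim the centroid pixel so the pair exists
      rc <- pmin(pmax(round(cx[i]), 1L), W)
      cc2 <- pmin(pmax(round(cy[i]), 1L), W)
      if (cell_labels[rc, cc2] == i) {
        nucleus_labels[rc, cc2] <- i
        nuc_area_real[i] <- 1
      }
      next
    }
    idx_local <- which(sel)
    lr <- ((idx_local - 1L) %% length(rr)) + 1L
    lc <- ((idx_local - 1L) %/% length(rr)) + 1L
    nucleus_labels[cbind(rr[lr], cc[lc])] <- i
    nuc_area_real[i] <- length(idx_local)
  }
  if (n_clipped > 0) {
    warn(sprintf("%d nuclei clipped to their cell boundary.", n_clipped))
  }

  # channels -----------------------------------------------------------
  nuc_mean <- mean(nuc_area_real[nuc_area_real > 0])
  rel_area <- (nuc_area_real - nuc_mean) / nuc_mean
  level0 <- params$dapi_level
  channels <- list()
  gt_levels <- list()

  nuc_idx <- which(nucleus_labels > 0L)
  nuc_lab <- nucleus_labels[nuc_idx]

  dapi <- matrix(0, W, W)
  dapi[nuc_idx] <- level0
  channels[["DAPI"]] <- dapi

  # per-nucleus periphery/center split reused across mark channels
  split_cache <- vector("list", n)
  for (i in unique(nuc_lab)) {
    ids <- nuc_idx[nuc_lab == i]
    rr <- range(((ids - 1L) %% W) + 1L)
    cc <- range(((ids - 1L) %/% W) + 1L)
    sub <- matrix(FALSE, rr[2] - rr[1] + 3L, cc[2] - cc[1] + 3L)
    lr <- ((ids - 1L) %% W) + 1L - rr[1] + 2L
    lc <- ((ids - 1L) %/% W) + 1L - cc[1] + 2L
    sub[cbind(lr, lc)] <- TRUE
    sp <- radial_split_indices(sub, 0.20)
    to_global <- function(loc) {
      glr <- ((loc - 1L) %% nrow(sub)) + 1L + rr[1] - 2L
      glc <- ((loc - 1L) %/% nrow(sub)) + 1L + cc[1] - 2L
      (glc - 1L) * W + glr
    }
    split_cache[[i]] <- list(
      periphery = to_global(sp$periphery),
      center = to_global(sp$center)
    )
  }

  for (j in seq_len(nrow(params$channels))) {
    ch <- params$channels$name[j]
    slope <- params$channels$slope[j]
    coupling <- params$channels$coupling[j]
    lev <- 1 + slope * rel_area + rnorm(n, 0, params$mark_noise_sd)
    lev <- pmax(lev, 0.05)
    ratio <- pmax(1 + coupling * rel_area, 0.05)
    img <- matrix(0, W, W)
    for (i in unique(nuc_lab)) {
      sp <- split_cache[[i]]
      n_per <- length(sp$periphery); n_cen <- length(sp$center)
      frac_per <- n_per / (n_per + n_cen)
      b <- 1 / (frac_per * ratio[i] + (1 - frac_per))
      a <- ratio[i] * b
      img[sp$periphery] <- lev[i] * level0 * a
      img[sp$center] <- lev[i] * level0 * b
    }
    channels[[ch]] <- img
    gt_levels[[paste0(ch, "_level")]] <- lev
    gt_levels[[paste0(ch, "_ratio")]] <- ratio
  }

  # additive pixel noise inside nuclei, clipped at zero
  if (params$pixel_noise_sd > 0) {
    for (ch in names(channels)) {
      noise <- rnorm(length(nuc_idx), 0, params$pixel_noise_sd * level0)
      channels[[ch]][nuc_idx] <-
        pmax(channels[[ch]][nuc_idx] + noise, 0)
    }
  }

  ground_truth <- dplyr::bind_cols(
    tibble(
      label_id = seq_len(n),
      target_area_px = target,
      cell_area_px = areas_px,
      cell_metric_ar = cell_ar,
      cell_theta = theta,
      nucleus_target_px = nuc_target,
      nucleus_area_px = nuc_area_real,
      nucleus_ar = nuc_ar,
      nc_factor = params$nc_ratio * exp(eps)
    ),
    as_tibble(gt_levels)
  )

  structure(
    list(
      cell_labels = cell_labels,
      nucleus_labels = nucleus_labels,
      channels = channels,
      pixel_size = params$pixel_size,
      params = params,
      n_clipped = n_clipped,
      ground_truth = ground_truth
    ),
    class = "labeled_monolayer"
  )
}

#' @export
print.labeled_monolayer <- function(x, ...) {
  cat(sprintf(
    "<labeled_monolayer: %d x %d px, %d cells, %d nuclei, channels: %s>\n",
    nrow(x$cell_labels), ncol(x$cell_labels),
    length(unique(x$cell_labels[x$cell_labels > 0])),
    length(unique(x$nucleus_labels[x$nucleus_labels > 0])),
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}
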