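# perimeter weights: calibrated on digital disks (r = 20-60) and
# axis-aligned squares; straight-edge and corner boundary pixels
PERIM_W_STRAIGHT <- 1.02
PERIM_W_CORNER <- 1.22

# Per-pixel exposure maps: for every labeled pixel, whether each 4-neighbour
# belongs to a different label (or lies outside the image).
label_exposures <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  obj <- labels > 0L
  list(
    up = obj & (pad[1:nr, 2:(nc + 1)] != labels),
    down = obj & (pad[3:(nr + 2), 2:(nc + 1)] != labels),
    left = obj & (pad[2:(nr + 1), 1:nc] != labels),
    right = obj & (pad[2:(nr + 1), 3:(nc + 2)] != labels)
  )
}

# Weighted boundary-crack perimeter per label. "crack" counts exposed pixel
# edges (exact for axis-aligned shapes); "weighted" applies the isotropy
# correction: straight-edge pixels 1.02, corner pixels 1.22, which keeps
# digital disks within ~1% of the true circumference.
label_perimeters <- function(labels, ids,
                             method = c("weighted", "crack")) {
  method <- match.arg(method)
  ex <- label_exposures(labels)
  obj <- which(labels > 0L)
  lab <- labels[obj]
  f <- factor(lab, levels = ids)
  up <- ex$up[obj]; down <- ex$down[obj]
  left <- ex$left[obj]; right <- ex$right[obj]
  n4 <- up + down + left + right
  if (method == "crack") {
    return(unname(rowsum(as.numeric(n4), f)[, 1]))
  }
  adj2 <- (up & left) | (up & right) | (down & left) | (down & right)
  w <- numeric(length(lab))
  w[n4 == 1] <- PERIM_W_STRAIGHT
  corner <- n4 == 2 & adj2
  w[corner] <- PERIM_W_CORNER
  w[n4 == 2 & !adj2] <- 2 * PERIM_W_STRAIGHT  # 1-px-wide strip
  w[n4 == 3] <- PERIM_W_STRAIGHT + PERIM_W_CORNER
  w[n4 == 4] <- 2 * sqrt(pi)  # isolated pixel: circumference of unit-area disk
  unname(rowsum(w, f)[, 1])
}

# convex hull area of a pixel set, using the pixel-square corners so the
# hull always contains the full pixel area (solidity <= 1 by construction)
hull_area <- function(rows, cols) {
  x <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  y <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Morphometric features of every object in a label mask
#'
#' Computes, for each labeled object, the area, perimeter, second-moment
#' ellipse axes and orientation, and the derived dimensionless shape
#' features, using the literal definitions: shape index
#' \eqn{P/\sqrt{A}}, solidity \eqn{A/A_{convex}}, circularity \eqn{A/P^2},
#' roundness \eqn{A/\mathrm{major}^2}, aspect ratio
#' \eqn{\mathrm{major}/\mathrm{minor}}. `conventional = TRUE` switches
#' circularity and roundness to their 4\eqn{\pi}- and 4/\eqn{\pi}-scaled
#' textbook versions.
#'
#' @param labels Integer matrix; 0 is background, positive values are
#'   object ids (a logical mask is treated as a single object).
#' @param pixel_size Micrometres per pixel; lengths scale linearly and
#'   areas quadratically with it.
#' @param perimeter_method `"weighted"` (isotropy-corrected boundary-crack
#'   length, the default) or `"crack"` (raw crack length, exact for
#'   axis-aligned shapes).
#' @param conventional Use 4\eqn{\pi}A/P\eqn{^2} and
#'   4A/(\eqn{\pi} major\eqn{^2}) instead of the literal ratios.
#' @return A tibble with one row per label id: `label_id`, `area`,
#'   `perimeter`, `major_axis`, `minor_axis`, `aspect_ratio`,
#'   `shape_index`, `solidity`, `circularity`, `roundness`, `orientation`,
#'   `centroid_row`, `centroid_col`, `touches_border`.
#' @export
#' @examples
#' m <- matrix(0L, 12, 12); m[4:9, 4:9] <- 1L
#' mask_features(m, perimeter_method = "crack")$shape_index  # 4
mask_features <- function(labels, pixel_size = 1,
                          perimeter_method = c("weighted", "crack"),
                          conventional = FALSE) {
  perimeter_method <- match.arg(perimeter_method)
  if (is.logical(labels)) {
    labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  }
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  idx <- which(labels > 0L)
  if (length(idx) == 0) abort("`labels` contains no objects.")
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)

  npx <- as.numeric(table(f))
  sx <- unname(rowsum(as.numeric(rows), f)[, 1])
  sy <- unname(rowsum(as.numeric(cols), f)[, 1])
  sxx <- unname(rowsum(as.numeric(rows)^2, f)[, 1])
  syy <- unname(rowsum(as.numeric(cols)^2, f)[, 1])
  sxy <- unname(rowsum(as.numeric(rows) * cols, f)[, 1])
  cx <- sx / npx; cy <- sy / npx
  mxx <- sxx / npx - cx^2
  myy <- syy / npx - cy^2
  mxy <- sxy / npx - cx * cy
  tr <- mxx + myy
  dpart <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- pmax((tr + dpart) / 2, 0)
  l2 <- pmax((tr - dpart) / 2, 0)
  # full axis lengths of the equal-moment ellipse; the 1/12 term accounts
  # for the finite pixel footprint so a 1-px object has nonzero axes
  major <- 4 * sqrt(l1 + 1 / 12)
  minor <- 4 * sqrt(l2 + 1 / 12)
  orientation <- 0.5 * atan2(2 * mxy, mxx - myy)

  per <- label_perimeters(labels, ids, perimeter_method)

  hull <- vapply(seq_along(ids), function(i) {
    sel <- lab == ids[i]
    hull_area(rows[sel], cols[sel])
  }, numeric(1))

  border_ids <- unique(c(
    labels[1, ], labels[nr, ], labels[, 1], labels[, ncol(labels)]
  ))
  touches <- ids %in% border_ids[border_ids > 0L]

  area <- npx * pixel_size^2
  per <- per * pixel_size
  major <- major * pixel_size
  minor <- minor * pixel_size
  circ <- if (conventional) 4 * pi * area / per^2 else area / per^2
  round_ <- if (conventional) 4 * area / (pi * major^2) else area / major^2
  tibble(
    label_id = ids,
    area = area,
    perimeter = per,
    major_axis = major,
    minor_axis = minor,
    aspect_ratio = major / minor,
    shape_index = per / sqrt(area),
    solidity = npx / hull,
    circularity = circ,
    roundness = round_,
    orientation = orientation,
    centroid_row = cx * pixel_size,
    centroid_col = cy * pixel_size,
    touches_border = touches
  )
}

#' Extract per-cell morphological and intensity features
#'
#' Produces one record per matched cell/nucleus pair from a labeled
#' monolayer: the full morphometric feature set for both masks
#' (see [mask_features()]), the nucleus/cell area and aspect-ratio ratios,
#' per-channel nuclear intensity statistics (mean, sd, coefficient of
#' variation), and DAPI-normalized mark levels (ratio of mean mark
#' intensity to mean DAPI intensity over the nucleus mask).
#'
#' Cells and nuclei are matched by shared label id; when the two masks
#' share no ids, each nucleus is matched to the cell containing its
#' centroid. Unmatched objects are dropped and counted in the
#' reconciliation report stored in `attr(, "reconciliation")`.
#'
#' @param monolayer A `labeled_monolayer` (from [generate_monolayer()] or
#'   [read_monolayer()]).
#' @inheritParams mask_features
#' @return A tibble with one row per matched pair; cell and nucleus
#'   feature columns are prefixed `cell_` / `nucleus_`, channel statistics
#'   are `<channel>_mean`, `<channel>_sd`, `<channel>_cv`, and each
#'   non-DAPI channel gets `<channel>_norm` (mark mean / DAPI mean).
#'   `edge_flag` marks objects touching the image border; `mitotic_flag`
#'   is initialized to `FALSE` (see [match_and_filter()]).
#' @export
extract_features <- function(monolayer,
                             perimeter_method = c("weighted", "crack"),
                             conventional = FALSE) {
  check_monolayer(monolayer)
  perimeter_method <- match.arg(perimeter_method)
  ps <- monolayer$pixel_size
  cellf <- mask_features(monolayer$cell_labels, ps, perimeter_method,
                         conventional)
  nucf <- mask_features(monolayer$nucleus_labels, ps, perimeter_method,
                        conventional)

  shared <- intersect(cellf$label_id, nucf$label_id)
  if (length(shared) == 0) {
    # match each nucleus to the cell containing its centroid
    rc <- round(nucf$centroid_row / ps)
    cc <- round(nucf$centroid_col / ps)
    rc <- pmin(pmax(rc, 1), nrow(monolayer$cell_labels))
    cc <- pmin(pmax(cc, 1), ncol(monolayer$cell_labels))
    host <- monolayer$cell_labels[cbind(rc, cc)]
    nucf$cell_id <- host
    nucf <- nucf[host > 0L, ]
  } else {
    nucf$cell_id <- nucf$label_id
  }

  dup <- nucf$cell_id[duplicated(nucf$cell_id)]
  ambiguous <- unique(dup)
  nucf_m <- nucf[nucf$cell_id %in% cellf$label_id &
                   !(nucf$cell_id %in% ambiguous), ]

  n_cells_in <- nrow(cellf)
  n_nuc_in <- nrow(nucf)

  ren <- function(df, prefix) {
    keep <- setdiff(names(df), c("label_id", "cell_id"))
    stats::setNames(df[keep], paste0(prefix, keep))
  }
  out <- dplyr::bind_cols(
    tibble(label_id = nucf_m$cell_id),
    ren(cellf[match(nucf_m$cell_id, cellf$label_id), ], "cell_"),
    ren(nucf_m, "nucleus_")
  )
  out <- dplyr::mutate(
    out,
    nc_area_ratio = .data$nucleus_area / .data$cell_area,
    nc_ar_ratio = .data$nucleus_aspect_ratio / .data$cell_aspect_ratio,
    centroid_x = .data$cell_centroid_row,
    centroid_y = .data$cell_centroid_col,
    edge_flag = .data$cell_touches_border | .data$nucleus_touches_border,
    mitotic_flag = FALSE
  )

  # nuclear intensity statistics per channel
  if (length(monolayer$channels) > 0) {
    nl <- monolayer$nucleus_labels
    idx <- which(nl > 0L)
    lab <- nl[idx]
    # map nucleus label -> matched record via original nucleus label ids
    f <- factor(lab, levels = nucf_m$label_id)
    keep <- !is.na(f)
    f <- f[keep]; idx <- idx[keep]
    npx <- as.numeric(table(f))
    for (ch in names(monolayer$channels)) {
      v <- monolayer$channels[[ch]][idx]
      s1 <- rowsum(v, f)[, 1]
      s2 <- rowsum(v^2, f)[, 1]
      mu <- s1 / npx
      sdv <- sqrt(pmax(s2 / npx - mu^2, 0))
      out[[paste0(ch, "_mean")]] <- mu
      out[[paste0(ch, "_sd")]] <- sdv
      out[[paste0(ch, "_cv")]] <- ifelse(mu > 0, sdv / mu, NA_real_)
    }
    if ("DAPI" %in% names(monolayer$channels)) {
      for (ch in setdiff(names(monolayer$channels), "DAPI")) {
        out[[paste0(ch, "_norm")]] <-
          out[[paste0(ch, "_mean")]] / out[["DAPI_mean"]]
      }
    }
  }

  attr(out, "reconciliation") <- list(
    n_cells_in = n_cells_in,
    n_nuclei_in = n_nuc_in,
    n_matched = nrow(out),
    n_cells_unmatched = n_cells_in - nrow(out),
    n_nuclei_unmatched = n_nuc_in - nrow(nucf_m),
    n_ambiguous = length(ambiguous),
    ambiguous_cell_ids = ambiguous
  )
  out
}

#' Apply the exclusion rules to a feature table
#'
#' Removes records whose cell or nucleus touches the image border (their
#' morphology cannot be measured) and records flagged as actively dividing.
#' Mitotic cells can be flagged explicitly via `mitotic_ids`, or by the
#' optional DAPI-intensity outlier rule (nuclear DAPI mean above
#' median + 3 MAD), since condensed mitotic chromatin shows atypical DAPI
#' intensity.
#'
#' @param records Feature table from [extract_features()].
#' @param mitotic_ids Optional vector of `label_id`s to exclude as mitotic.
#' @param dapi_rule If `TRUE`, additionally flag records with
#'   `DAPI_mean > median + 3 * mad`.
#' @param dapi_channel Channel name used by the rule.
#' @return The filtered tibble; exclusion counts are stored in
#'   `attr(, "exclusions")`.
#' @export
match_and_filter <- function(records, mitotic_ids = NULL,
                             dapi_rule = FALSE, dapi_channel = "DAPI") {
  if (!is.data.frame(records) || !"label_id" %in% names(records)) {
    abort("`records` must be a feature table with a `label_id` column.")
  }
  n_in <- nrow(records)
  mit <- records$mitotic_flag %||% rep(FALSE, n_in)
  if (!is.null(mitotic_ids)) {
    mit <- mit | records$label_id %in% mitotic_ids
  }
  if (isTRUE(dapi_rule)) {
    colname <- paste0(dapi_channel, "_mean")
    if (!colname %in% names(records)) {
      abort(sprintf("column `%s` required for the DAPI rule.", colname))
    }
    v <- records[[colname]]
    mit <- mit | v > median(v) + 3 * mad(v)
  }
  edge <- records$edge_flag %||% rep(FALSE, n_in)
  keep <- !edge & !mit
  out <- records[keep, ]
  out$mitotic_flag <- FALSE
  attr(out, "exclusions") <- list(
    n_in = n_in,
    n_out = nrow(out),
    n_edge = sum(edge),
    n_mitotic = sum(mit & !edge),
    reconciliation = attr(records, "reconciliation")
  )
  out
}

check_monolayer <- function(x) {
  if (!inherits(x, "labeled_monolayer")) {
    abort("expected a `labeled_monolayer` object.")
  }
  invisible(x)
}
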