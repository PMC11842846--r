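test_that("a square has shape index exactly 4 under crack perimeter", {
  for (s in c(10, 20, 64)) {
    f <- mask_features(square_mask(s), perimeter_method = "crack")
    expect_equal(f$shape_index, 4.0, tolerance = 1e-12)
    expect_equal(f$area, s^2)
  }
})

test_that("a digital disk is round: AR ~ 1 and circularity ~ 1/(4pi)", {
  f <- mask_features(disk_mask(40))
  expect_gte(f$aspect_ratio, 1.0)
  expect_lte(f$aspect_ratio, 1.02)
  expect_lt(abs(f$circularity - 1 / (4 * pi)) / (1 / (4 * pi)), 0.03)
  # boundary pixel squares bow the hull out by ~pi*r/2 px^2
  expect_gt(f$solidity, 0.97)
  expect_lte(f$solidity, 1)
  # conventional scaling restores ~1 for a circle
  fc <- mask_features(disk_mask(40), conventional = TRUE)
  expect_lt(abs(fc$circularity - 1), 0.03)
})

test_that("rectangle roundness matches the pixel-summation oracle", {
  m <- rect_mask(20, 10)
  f <- mask_features(m)
  o <- oracle_features(m)
  expect_lt(abs(f$roundness - o$roundness) / o$roundness, 0.05)
  expect_equal(f$major_axis, o$major_axis, tolerance = 1e-12)
  expect_equal(f$aspect_ratio, o$aspect_ratio, tolerance = 1e-12)
})

test_that("every feature agrees with the brute-force oracle on small
           masks", {
  shapes <- list(
    disk = disk_mask(12), square = square_mask(15),
    rect = rect_mask(24, 9), ellipse = ellipse_mask(14, 7, pi / 5),
    blob1 = blob_mask(31), blob2 = blob_mask(77)
  )
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    f <- mask_features(m)
    o <- oracle_features(m)
    expect_equal(f$area, o$area, info = nm)           # exact
    expect_equal(f$solidity, o$solidity, tolerance = 1e-12, info = nm)
    expect_lt(abs(f$perimeter - o$perimeter) / o$perimeter, 0.01)
    for (feat in c("shape_index", "circularity", "roundness",
                   "aspect_ratio", "major_axis", "minor_axis")) {
      expect_lt(abs(f[[feat]] - o[[feat]]) / abs(o[[feat]]), 0.01)
    }
    fc <- mask_features(m, perimeter_method = "crack")
    oc <- oracle_features(m, perimeter_method = "crack")
    expect_equal(fc$perimeter, oc$perimeter, info = nm)  # exact
  }
})

test_that("features transform correctly under pixel-size changes", {
  m <- blob_mask(5)
  f1 <- mask_features(m, pixel_size = 1)
  f2 <- mask_features(m, pixel_size = 2)
  expect_equal(f2$area, 4 * f1$area)
  expect_equal(f2$perimeter, 2 * f1$perimeter)
  expect_equal(f2$major_axis, 2 * f1$major_axis)
  for (feat in c("aspect_ratio", "shape_index", "solidity",
                 "circularity", "roundness")) {
    expect_equal(f2[[feat]], f1[[feat]], tolerance = 1e-12)
  }
})

test_that("extract_features returns one matched record per pair with
           intensity statistics", {
  mono <- fixture_monolayer("default")
  feats <- extract_features(mono)
  expect_true(all(c("cell_area", "nucleus_area", "nc_area_ratio",
                    "DAPI_mean", "H3K27me3_norm", "H3K9ac_norm",
                    "edge_flag") %in% names(feats)))
  expect_true(all(feats$nc_area_ratio > 0 & feats$nc_area_ratio <= 1))
  expect_true(all(feats$cell_aspect_ratio >= 1))
  expect_true(all(feats$nucleus_solidity > 0 & feats$nucleus_solidity <= 1))
  rec <- attr(feats, "reconciliation")
  expect_equal(rec$n_matched, nrow(feats))
})

test_that("border exclusion matches a direct label scan", {
  mono <- fixture_monolayer("default")
  feats <- extract_features(mono)
  filt <- match_and_filter(feats)
  lb <- mono$cell_labels
  nb <- mono$nucleus_labels
  border_ids <- unique(c(
    lb[1, ], lb[nrow(lb), ], lb[, 1], lb[, ncol(lb)],
    nb[1, ], nb[nrow(nb), ], nb[, 1], nb[, ncol(nb)]
  ))
  border_ids <- border_ids[border_ids > 0]
  expected <- sum(!(feats$label_id %in% border_ids))
  expect_equal(nrow(filt), expected)
  expect_equal(attr(filt, "exclusions")$n_edge,
               nrow(feats) - expected)
  expect_false(any(filt$edge_flag))
})

test_that("interior-only fields pass through the filter unchanged", {
  # hand-built: 9 square cells, none touching the border
  lab <- matrix(0L, 30, 30)
  k <- 0L
  for (i in 0:2) for (j in 0:2) {
    k <- k + 1L
    lab[(3 + i * 9):(8 + i * 9), (3 + j * 9):(8 + j * 9)] <- k
  }
  nuc <- matrix(0L, 30, 30)
  for (i in 0:2) for (j in 0:2) {
    id <- lab[5 + i * 9, 5 + j * 9]
    nuc[(5 + i * 9):(6 + i * 9), (5 + j * 9):(6 + j * 9)] <- id
  }
  mono <- make_monolayer(lab, nuc)
  filt <- match_and_filter(extract_features(mono))
  expect_equal(nrow(filt), 9)
  expect_equal(attr(filt, "exclusions")$n_edge, 0)
})

test_that("objects touching any border are excluded, counted exactly", {
  lab <- matrix(0L, 40, 40)
  # 8 interior squares + 2 that touch row 1
  ids <- 0L
  for (j in 0:1) {
    ids <- ids + 1L
    lab[1:6, (5 + j * 12):(10 + j * 12)] <- ids  # touches top border
  }
  for (i in 0:1) for (j in 0:3) {
    ids <- ids + 1L
    lab[(12 + i * 12):(17 + i * 12), (3 + j * 9):(8 + j * 9)] <- ids
  }
  nuc <- matrix(0L, 40, 40)
  for (id in 1:ids) {
    px <- which(lab == id, arr.ind = TRUE)
    ctr <- round(colMeans(px))
    nuc[ctr[1] + 0:1, ctr[2] + 0:1] <- id
  }
  mono <- make_monolayer(lab, nuc)
  filt <- match_and_filter(extract_features(mono))
  expect_equal(attr(filt, "exclusions")$n_edge, 2)
  expect_equal(nrow(filt), 8)
})

test_that("nuclei are matched by centroid when label ids differ, and
           ambiguous matches are excluded", {
  lab <- matrix(0L, 24, 24)
  lab[3:10, 3:10] <- 1L
  lab[3:10, 13:20] <- 2L
  lab[13:20, 3:20] <- 3L
  nuc <- matrix(0L, 24, 24)
  nuc[5:7, 5:7] <- 101L    # inside cell 1
  nuc[5:7, 15:17] <- 102L  # inside cell 2
  nuc[15:17, 5:7] <- 103L  # inside cell 3 ...
  nuc[15:17, 15:17] <- 104L  # ... and a second nucleus also in cell 3
  mono <- make_monolayer(lab, nuc)
  feats <- extract_features(mono)
  expect_setequal(feats$label_id, c(1L, 2L))
  rec <- attr(feats, "reconciliation")
  expect_equal(rec$n_ambiguous, 1)
  expect_equal(rec$ambiguous_cell_ids, 3L)
})

test_that("mitotic records are excluded by explicit ids or the DAPI
           outlier rule", {
  mono <- fixture_monolayer("default")
  feats <- extract_features(mono)
  filt0 <- match_and_filter(feats)
  ids <- filt0$label_id[1:3]
  filt1 <- match_and_filter(feats, mitotic_ids = ids)
  expect_equal(nrow(filt1), nrow(filt0) - 3)
  expect_equal(attr(filt1, "exclusions")$n_mitotic, 3)

  # plant one bright DAPI outlier
  feats2 <- feats
  feats2$DAPI_mean[7] <- feats2$DAPI_mean[7] * 10
  filt2 <- match_and_filter(feats2, dapi_rule = TRUE)
  expect_true(feats2$label_id[7] %in%
                setdiff(feats$label_id, filt2$label_id))
})

test_that("measured NC area ratio is tight when the coupling is
           noise-free", {
  mono <- fixture_monolayer("noiseless")
  feats <- match_and_filter(extract_features(mono))
  ratio <- feats$nc_area_ratio
  expect_lt(sd(ratio) / mean(ratio), 0.05)
})
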