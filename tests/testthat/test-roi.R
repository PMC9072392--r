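# ROI selection: distance map, feasibility rules, non-overlap, determinism,
# counts against brute-force enumeration.

test_that("vessel distance map is exact Euclidean distance in micrometres", {
  m <- matrix(0, 8, 8); m[1, 1] <- 1
  d <- vessel_distance_map(m, pixel_size_um = 1)
  expect_equal(d[1, 1], 0)
  expect_equal(d[4, 5], 5)       # 3-4-5 triangle
  expect_equal(d[1, 2], 1)       # 4-neighbour of the mask
  expect_equal(d[2, 2], sqrt(2))
  d2 <- vessel_distance_map(m, pixel_size_um = 0.5)
  expect_equal(d2[4, 5], 2.5)
  expect_true(all(vessel_distance_map(matrix(1, 5, 5), 1) == 0))
  expect_error(vessel_distance_map(matrix(0, 5, 5), 1), "no vessel")
})

test_that("ROI side larger than the image is an error", {
  img <- image_patch(matrix(1, 100, 100), pixel_size_um = 0.15)
  expect_error(select_rois(img, side_um = 150, seed = 1), "exceeds")
})

test_that("whole-image tiling respects the exhaustive grid bound", {
  img <- matrix(0, 3000, 3000)
  rs <- select_rois(img, vessel_mask = NULL, side_um = 1000,
                    max_distance_um = 500, min_count = 1, max_count = 80,
                    seed = 5, pixel_size_um = 1)
  # oracle: at most floor(3000/1000)^2 = 9 disjoint 1000-px squares fit
  expect_lte(nrow(rs$rois), 9)
  expect_gte(nrow(rs$rois), 4)  # greedy on the half-stride grid packs >= 4
  r <- rs$rois
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r))) {
    if (i < j) {
      expect_true(abs(r$row[i] - r$row[j]) >= 1000 ||
                    abs(r$col[i] - r$col[j]) >= 1000)
    }
  }
})

test_that("selection is deterministic in the seed", {
  img <- matrix(0, 500, 500)
  a <- select_rois(img, side_um = 100, min_count = 1, seed = 3,
                   pixel_size_um = 1)
  b <- select_rois(img, side_um = 100, min_count = 1, seed = 3,
                   pixel_size_um = 1)
  expect_identical(a$rois, b$rois)
})

test_that("count equals brute-force enumeration when feasible sites are disjoint", {
  # two vertical vessel bands; the distance and lumen rules leave exactly two
  # candidate origins on the half-stride grid, far apart hence non-overlapping
  nr <- 140; nc <- 480; side <- 100; maxd <- 85
  mask <- matrix(0, nr, nc)
  mask[, 1:20] <- 1; mask[, 461:480] <- 1
  img <- matrix(10, nr, nc)

  # independent brute force over the documented candidate grid
  stride <- side %/% 2
  cand_r <- seq(1, nr - side + 1, by = stride)
  cand_c <- seq(1, nc - side + 1, by = stride)
  lumen_cols <- c(1:20, 461:480)
  feas <- list()
  for (r in cand_r) for (c in cand_c) {
    ctr_c <- round(c + (side - 1) / 2)
    dist <- min(abs(ctr_c - lumen_cols))  # bands span all rows
    roi_cols <- c:(c + side - 1)
    if (dist <= maxd && !any(roi_cols %in% lumen_cols)) {
      feas[[length(feas) + 1]] <- c(r, c)
    }
  }
  k <- length(feas)
  expect_equal(k, 2)  # geometry designed for exactly two disjoint sites

  rs <- select_rois(img, vessel_mask = mask, side_um = side,
                    max_distance_um = maxd, min_count = 1, max_count = 80,
                    seed = 21, pixel_size_um = 1)
  expect_equal(nrow(rs$rois), min(k, 80))
  expect_setequal(rs$rois$col, vapply(feas, `[`, numeric(1), 2))
})

test_that("infeasible geometry yields an empty set plus a warning", {
  mask <- matrix(0, 120, 120); mask[55:65, 55:65] <- 1  # lumen blocks center
  img <- matrix(1, 120, 120)
  expect_warning(
    rs <- select_rois(img, vessel_mask = mask, side_um = 110,
                      max_distance_um = 500, min_count = 1, max_count = 10,
                      seed = 2, pixel_size_um = 1),
    "only 0 ROIs")
  expect_equal(nrow(rs$rois), 0)
})

test_that("returned ROIs satisfy all constraints when re-checked independently", {
  sc <- generate_vessel_scene(shape_px = c(700, 700), vessel_radius_px = 60,
                              wall_thickness_px = 30, pixel_size_um = 1.5,
                              seed = 31)
  rs <- suppressWarnings(
    select_rois(sc$image, sc$truth$vessel_mask, side_um = 150,
                max_distance_um = 500, min_count = 1, max_count = 80,
                seed = 32))
  r <- rs$rois
  expect_gt(nrow(r), 0)
  lumen_pts <- which(sc$truth$vessel_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(r))) {
    # size: 150 um side at 1.5 um/px = 100 px
    expect_equal(r$side_px[i], 100)
    expect_equal(r$side_um[i], 150)
    # inside image
    expect_lte(r$row[i] + r$side_px[i] - 1, 700)
    expect_lte(r$col[i] + r$side_px[i] - 1, 700)
    # center within 500 um of the wall, by direct distance to lumen pixels
    d <- min(sqrt((lumen_pts[, 1] - round(r$center_row[i]))^2 +
                    (lumen_pts[, 2] - round(r$center_col[i]))^2)) * 1.5
    expect_lte(d, 500)
    # lumen exclusion
    rows <- r$row[i]:(r$row[i] + 99); cols <- r$col[i]:(r$col[i] + 99)
    expect_equal(sum(sc$truth$vessel_mask[rows, cols]), 0)
    # pairwise non-overlap
    for (j in seq_len(nrow(r))) {
      if (i < j) {
        expect_true(abs(r$row[i] - r$row[j]) >= 100 ||
                      abs(r$col[i] - r$col[j]) >= 100)
      }
    }
  }
})

test_that("extract_roi returns the exact sub-image", {
  img <- image_patch(matrix(1:10000, 100, 100), pixel_size_um = 1)
  roi <- data.frame(id = "r1", row = 11, col = 21, side_px = 10)
  sub <- extract_roi(img, roi)
  expect_identical(sub$pixels, img$pixels[11:20, 21:30])
  expect_equal(sub$pixel_size_um, 1)
})
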