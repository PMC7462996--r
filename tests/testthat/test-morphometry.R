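cfg1 <- morphometry_config(pixel_area = 1)

test_that("disk descriptors match their closed forms", {
  d <- compute_shape_descriptors(make_disk_mask(20), cfg1)
  expect_gt(d$compactness, 0.95)
  expect_lt(d$compactness, 1.05)
  expect_lt(abs(d$inner_radius_um - 20), 1)
  expect_lt(abs(d$outer_radius_um - 20), 1)
  expect_lt(rel_err(d$perimeter_um, 2 * pi * 20), 0.05)
  expect_lt(rel_err(d$area_um2, pi * 400), 0.02)
  expect_lt(d$lw_ratio, 1.05)
})

test_that("the 10x40 rectangle yields its analytic descriptors", {
  d <- compute_shape_descriptors(make_rect_mask(40, 10), cfg1)
  expect_equal(d$area_px, 400)
  expect_equal(d$length_um, 40)
  expect_equal(d$width_um, 10)
  expect_equal(d$lw_ratio, 4)
  expect_lt(abs(d$inner_radius_um - 5), 0.5)
  expect_lt(rel_err(d$outer_radius_um, sqrt(20^2 + 5^2)), 0.02)
})

test_that("a rectangle rotated 45 degrees keeps its side lengths", {
  ax <- compute_shape_descriptors(make_rect_mask(120, 60), cfg1)
  rot <- compute_shape_descriptors(make_rot_rect_mask(120, 60), cfg1)
  expect_lt(rel_err(rot$length_um, ax$length_um), 0.05)
  expect_lt(rel_err(rot$width_um, ax$width_um), 0.05)
})

test_that("inscribed radius equals the exhaustive distance oracle", {
  for (seed in 1:20) {
    mask <- random_polyomino(n_px = 120, seed = seed)
    d <- compute_shape_descriptors(mask, cfg1)
    expect_equal(d$inner_radius_um, brute_inner_radius(mask),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and multi-component masks are rejected", {
  expect_error(compute_shape_descriptors(matrix(FALSE, 5, 5), cfg1),
               "no foreground")
  two <- matrix(FALSE, 8, 8)
  two[2, 2] <- TRUE; two[6, 6] <- TRUE
  expect_error(compute_shape_descriptors(two, cfg1), "4-connected")
})

test_that("per-cell tables are label-invariant and scale-consistent", {
  sheet <- small_sheet(seed = 6, n_cells = 60, field = c(320, 320))
  cells <- extract_cell_morphologies(sheet, morphometry_config())
  expect_equal(nrow(cells), n_cells(sheet))
  expect_identical(cells$cell_id, seq_len(n_cells(sheet)))

  # permute label ids: same multiset of feature vectors
  perm <- withr::with_seed(1, sample(n_cells(sheet)))
  relabeled <- sheet
  pos <- relabeled$labels > 0
  relabeled$labels[pos] <- perm[relabeled$labels[pos]]
  cells2 <- extract_cell_morphologies(relabeled, morphometry_config())
  key <- function(df) sort(apply(round(df[, rpe_features], 9), 1, paste,
                                 collapse = "|"))
  expect_identical(key(cells), key(cells2))

  # 2x nearest-neighbour upscale with pixel_area / 4
  big <- sheet
  big$labels <- sheet$labels[rep(seq_len(nrow(sheet$labels)), each = 2),
                             rep(seq_len(ncol(sheet$labels)), each = 2)]
  big$pixel_area <- sheet$pixel_area / 4
  cells_big <- extract_cell_morphologies(big, morphometry_config())
  expect_lt(median(rel_err(cells_big$compactness, cells$compactness)), 0.03)
  expect_lt(median(rel_err(cells_big$lw_ratio, cells$lw_ratio)), 0.03)
  expect_lt(median(rel_err(cells_big$area_um2, cells$area_um2)), 0.02)
})

test_that("shape invariants hold across a synthetic sheet", {
  sheet <- small_sheet(seed = 8, heterogeneity = 0.9, elongation = 0.8)
  cells <- extract_cell_morphologies(sheet, morphometry_config())
  expect_true(all(cells$width_um <= cells$length_um + 1e-9))
  expect_true(all(cells$lw_ratio >= 1 - 1e-9))
  expect_true(all(cells$inner_radius_um <= cells$outer_radius_um + 1e-9))
  expect_true(all(cells$compactness > 0 & cells$compactness <= 1.1))
  expect_equal(cells$area_um2, cells$area_px * sheet$pixel_area)
})

test_that("the minimum-size filter deletes strictly-below-threshold cells", {
  # strips of exactly 499, 500 and 501 pixels in one label image
  labels <- matrix(0L, 40, 120)
  labels[2:6, 2:101] <- 1L; labels[6, 101] <- 0L          # 499 px
  labels[12:16, 2:101] <- 2L                              # 500 px
  labels[22:26, 2:101] <- 3L; labels[27, 2] <- 3L         # 501 px
  sheet <- rpeqc:::new_labeled_sheet(labels, 0.61)
  cells <- extract_cell_morphologies(sheet, morphometry_config())
  expect_equal(cells$area_px, c(499, 500, 501))
  kept <- filter_small_cells(cells, morphometry_config())
  expect_identical(kept$cell_id, c(2L, 3L))
  expect_equal(attr(kept, "n_deleted"), 1)
  expect_equal(nrow(kept) + attr(kept, "n_deleted"), nrow(cells))

  expect_identical(filter_small_cells(kept, morphometry_config())$cell_id,
                   kept$cell_id)
  expect_warning(
    empty <- filter_small_cells(cells, morphometry_config(min_area_px = 1000)),
    "size filter")
  expect_equal(nrow(empty), 0)
})

test_that("traced polygons rasterize with clipping against earlier cells", {
  square <- function(x0, y0, side) {
    cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
  }
  one <- rasterize_traced_cells(list(square(10, 10, 30)), c(64, 64), 1)
  cells <- extract_cell_morphologies(one, cfg1)
  expect_equal(nrow(cells), 1)
  expect_lt(rel_err(cells$area_px, 900), 0.07)

  two <- rasterize_traced_cells(list(square(5, 5, 20), square(35, 35, 20)),
                                c(70, 70), 1)
  expect_equal(n_cells(two), 2)

  # 50% overlap: second cell keeps only pixels outside the first square
  ov <- rasterize_traced_cells(list(square(10, 10, 20), square(20, 10, 20)),
                               c(64, 64), 1)
  cells_ov <- extract_cell_morphologies(ov, cfg1)
  # oracle for axis-aligned squares: half-open boxes (a raster pixel
  # belongs to the square whose left/top edges it sits on)
  inside <- function(x0, side) {
    function(px) px >= x0 & px < x0 + side
  }
  grid <- expand.grid(x = 0:63, y = 0:63)
  in1 <- inside(10, 20)(grid$x) & inside(10, 20)(grid$y)
  in2 <- inside(20, 20)(grid$x) & inside(10, 20)(grid$y)
  expect_equal(cells_ov$area_px[2], sum(in2 & !in1))

  sliver <- cbind(c(12.1, 12.4, 12.2), c(12.1, 12.1, 12.4))
  expect_warning(
    skipped <- rasterize_traced_cells(list(square(30, 30, 10), sliver),
                                      c(64, 64), 1),
    "0 pixels")
  expect_equal(attr(skipped, "n_skipped"), 1)
})
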