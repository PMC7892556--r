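test_that("pixel inclusion follows the center-in-polygon, even-odd convention", {
  # axis-aligned square with corners at pixel centers (0,0)-(10,10):
  # strictly interior centers are the 9 x 9 block
  sq <- rect_contour(0, 0, 10, 10)
  px <- pixels_in_contour(sq, c(16, 16))
  expect_equal(nrow(px), 81)
  expect_true(all(px[, 1] %in% 1:9) && all(px[, 2] %in% 1:9))

  # orientation invariance
  px_rev <- pixels_in_contour(sq[nrow(sq):1, ], c(16, 16))
  expect_equal(px[order(px[, 1], px[, 2]), ],
               px_rev[order(px_rev[, 1], px_rev[, 2]), ])

  # a sub-pixel triangle between centers encloses nothing
  tri <- cbind(x = c(0.2, 0.8, 0.5), y = c(0.2, 0.2, 0.8))
  expect_error(pixels_in_contour(tri, c(4, 4)), "empty pixel set")

  # zero-area polygon is rejected
  expect_error(pixels_in_contour(cbind(c(1, 2, 3), c(1, 2, 3)), c(8, 8)),
               "degenerate")
})

test_that("pixel inclusion agrees with a winding-angle oracle on random polygons", {
  set.seed(42)
  for (rep in 1:20) {
    # random star-shaped polygon around (8, 8)
    nv <- sample(5:12, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 7)
    contour <- cbind(x = 8 + rad * cos(ang), y = 8 + rad * sin(ang))
    px <- tryCatch(pixels_in_contour(contour, c(16, 16)),
                   error = function(e) NULL)
    got <- matrix(FALSE, 16, 16)
    if (!is.null(px)) got[px[, 1] * 16 + px[, 2] + 1] <- TRUE
    want <- matrix(FALSE, 16, 16)
    for (x in 0:15) for (y in 0:15) {
      want[x * 16 + y + 1] <- bf_inside_winding(x, y, contour)
    }
    expect_identical(got, want, info = sprintf("polygon rep %d", rep))
  }
})

test_that("barycenter is the pixel-set centroid and translates with the ROI", {
  d <- disk_contour(10, 10, 6)
  roi <- tumor_roi(d, c(24, 24))
  expect_lt(max(abs(barycenter(roi) - c(10, 10))), 0.5)

  shifted <- tumor_roi(cbind(d[, 1] + 3, d[, 2] + 2), c(24, 24))
  expect_equal(barycenter(shifted), barycenter(roi) + c(x = 3, y = 2),
               tolerance = 1e-12)
})

test_that("tumor area scales with spacing and matches the analytic ellipse", {
  sq <- rect_contour(0, 0, 10, 10)
  roi <- tumor_roi(sq, c(16, 16))
  expect_equal(tumor_area(roi, 0.1), 81 * 0.01)
  expect_equal(tumor_area(roi, 0.2), 4 * tumor_area(roi, 0.1))

  g <- generate_stiffness_map(swe_preset("mesenchymal_stiff"), 10, seed = 5)
  expect_lt(abs(tumor_area(g$roi, 0.1) / g$truth$model_area_mm2 - 1), 0.02)
})

test_that("normalized radius spans the ROI and boundary pixels approach 1", {
  d <- disk_contour(16, 16, 12)
  roi <- tumor_roi(d, c(32, 32))
  map <- stiffness_map(matrix(1, 32, 32), 0.1)
  rec <- radial_records(map, roi)
  expect_equal(nrow(rec), nrow(roi$pixels))
  expect_true(all(rec$r_norm <= 1 + 0.05))
  # pixels adjacent to the boundary sit near r_norm = 1
  dpx <- sqrt((roi$pixels[, 1] - 16)^2 + (roi$pixels[, 2] - 16)^2)
  boundary <- dpx > 11
  expect_true(all(rec$r_norm[boundary] >= 0.9))
  # the pixel closest to the barycenter has the smallest distance
  expect_equal(rec$distance_mm[which.min(rec$r_norm)], min(rec$distance_mm))
})

test_that("center/periphery partition is an equal-area split of a disk", {
  roi <- tumor_roi(disk_contour(16, 16, 12), c(32, 32))
  part <- partition_center_periphery(roi)
  expect_true(all(xor(part$center, part$periphery)))
  expect_equal(sort(c(part$center_idx, part$periphery_idx)),
               sort(roi$pixel_idx))
  expect_lt(abs(mean(part$center) - 0.5), 0.05)
  # the pixel nearest the barycenter is in the center mask
  d <- sqrt(rowSums(sweep(roi$pixels, 2, roi$barycenter)^2))
  expect_true(part$center[which.min(d)])
  expect_error(partition_center_periphery(
    tumor_roi(rect_contour(0, 0, 2, 2), c(8, 8))), "too small")
})
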