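test_that("maximum intensity projection dominates every slice", {
  set.seed(21)
  stack <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  proj <- max_intensity_projection(stack)
  for (k in 1:4) expect_true(all(proj >= stack[, , k]))
  expect_equal(max_intensity_projection(stack[, , 1, drop = FALSE]),
               stack[, , 1])
  big <- stack; big[, , 3] <- 2
  expect_equal(max_intensity_projection(big), big[, , 3])
})

test_that("integrated density is exactly pixel sum times pixel area", {
  img <- matrix(7, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  d <- integrated_density(img, mask, pixel_area = 1)
  expect_equal(d$integrated_density, 700)
  expect_equal(integrated_density(matrix(0, 4, 4), matrix(TRUE, 4, 4))$integrated_density, 0)
  expect_error(integrated_density(img, matrix(FALSE, 10, 10)), "empty ROI")

  set.seed(22)
  for (i in 1:100) {
    img <- matrix(runif(64, 0, 50), 8, 8)
    mask <- matrix(runif(64) < 0.4, 8, 8)
    if (!any(mask)) next
    pa <- runif(1, 0.001, 2)
    got <- integrated_density(img, mask, pixel_area = pa)
    expect_equal(got$integrated_density, bf_integrated_density(img, mask, pa),
                 tolerance = 1e-9)
    expect_equal(got$integrated_density, got$mean_gray * got$area,
                 tolerance = 1e-12)
  }
})

test_that("color deconvolution inverts the stain mixture", {
  model <- masson_stain_model()
  # pure white: no optical density, no concentration (up to the +1 offset)
  white <- array(255, dim = c(2, 2, 3))
  expect_lt(max(color_deconvolve(white, model)), 1e-8)

  # a pixel synthesized from 1.0 x collagen stain comes back as (1, 0, 0)
  conc <- array(0, dim = c(1, 1, 3)); conc[1, 1, 1] <- 1
  rgb <- stiffpdx:::stains_to_rgb(conc, model)
  back <- color_deconvolve(rgb, model)
  expect_equal(as.numeric(back), c(1, 0, 0), tolerance = 1e-9)

  # linearity: doubling OD doubles concentrations
  conc2 <- conc * 2
  back2 <- color_deconvolve(stiffpdx:::stains_to_rgb(conc2, model), model)
  expect_equal(as.numeric(back2), 2 * as.numeric(back), tolerance = 1e-8)

  expect_error(stain_model(matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 1), 3, 3,
                                  byrow = TRUE)), "singular")
})

test_that("trichrome generator round-trips through deconvolution without noise", {
  model <- masson_stain_model()
  for (s in 1:3) {
    g <- generate_trichrome_image(0.4, size = c(64, 64), seed = s)
    conc <- color_deconvolve(g$rgb, model, clamp = FALSE)
    expect_lt(max(abs(conc - g$concentrations)), 1e-6)
  }
})

test_that("trichrome mask hits the requested collagen fraction", {
  expect_equal(sum(generate_trichrome_image(0, size = c(64, 64))$mask), 0)
  expect_true(all(generate_trichrome_image(1, size = c(64, 64))$mask))
  g <- generate_trichrome_image(0.3, size = c(512, 512), seed = 7)
  expect_gte(mean(g$mask), 0.28)
  expect_lte(mean(g$mask), 0.32)
})

test_that("collagen density is zero without collagen and ordered in the fraction", {
  model <- masson_stain_model()
  d0 <- collagen_density(generate_trichrome_image(0, size = c(64, 64))$rgb,
                         model, threshold = 0.5)
  expect_equal(d0$integrated_density, 0)
  for (s in 1:5) {
    lo <- generate_trichrome_image(0.2, size = c(128, 128), seed = s)
    hi <- generate_trichrome_image(0.5, size = c(128, 128), seed = s + 100)
    thr <- batch_collagen_threshold(list(lo$rgb, hi$rgb), model)
    dlo <- collagen_density(lo$rgb, model, threshold = thr)
    dhi <- collagen_density(hi$rgb, model, threshold = thr)
    expect_lt(dlo$integrated_density, dhi$integrated_density)
  }
})

test_that("stroma percentage is the mask ratio and validates containment", {
  tissue <- matrix(TRUE, 8, 8)
  expect_equal(stroma_percentage(tissue, tissue), 100)
  expect_equal(stroma_percentage(matrix(FALSE, 8, 8), tissue), 0)
  half <- matrix(c(TRUE, FALSE), 8, 8)
  expect_equal(stroma_percentage(half, tissue), 50)
  outside <- matrix(FALSE, 8, 8); outside[1, 1] <- TRUE
  expect_error(stroma_percentage(outside, !outside), "exceeds")
})

test_that("H-score weights intensity fractions on the 0-400 scale, linearly", {
  expect_equal(hscore(c(0, 0, 0, 0, 1)), 400)
  expect_equal(hscore(c(0.5, 0, 0.5, 0, 0)), 100)
  expect_equal(hscore(c(0, 0.25, 0.25, 0.25, 0.25)), 250)
  expect_error(hscore(c(0.5, 0, 0, 0, 0)), "sum to 1")
  # linearity in the fractions
  f1 <- c(0.2, 0.2, 0.2, 0.2, 0.2); f2 <- c(0, 0, 0, 0.5, 0.5)
  a <- 0.3
  expect_equal(hscore(a * f1 + (1 - a) * f2),
               a * hscore(f1) + (1 - a) * hscore(f2))
})

test_that("ROI sampling returns disjoint, seeded, foreground-bound windows", {
  img <- matrix(1, 64, 64)
  r1 <- sample_rois(img, 5, 12, seed = 3, fg_mask = img > 0)
  r2 <- sample_rois(img, 5, 12, seed = 3, fg_mask = img > 0)
  expect_identical(r1, r2)
  expect_length(r1, 5)
  overlap <- Reduce(`+`, lapply(r1, function(m) m * 1))
  expect_lte(max(overlap), 1)
  expect_error(sample_rois(img, 100, 12, seed = 3, fg_mask = img > 0),
               "non-overlapping")
  expect_error(sample_rois(img, 1, 128, seed = 3), "fit")
})

test_that("paired center/periphery comparison matches the closed-form paired t", {
  df <- data.frame(tumor_id = rep(c("a", "b", "c"), each = 2),
                   region = rep(c("center", "periphery"), 3),
                   metric = "length_um",
                   value = c(10, 7, 12, 9, 15, 13))
  got <- compare_center_periphery(df)
  want <- bf_t_paired(c(10, 12, 15), c(7, 9, 13))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$mean_difference, mean(c(3, 3, 2)))

  # constant shift d on center values gives mean difference d, flagged t = NA
  df0 <- df; df0$value <- rep(c(5, 5), 3)
  res0 <- compare_center_periphery(df0)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$t))

  dfm <- df[-2, ]  # drop one periphery: unpaired tumor
  expect_error(compare_center_periphery(dfm), "unpaired")
})
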