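test_that("Young's modulus conversion follows E = 3 rho vs^2 in kPa", {
  expect_equal(young_modulus_from_shear_speed(1, 1000), 3)
  expect_equal(young_modulus_from_shear_speed(0, 900), 0)
  expect_equal(young_modulus_from_shear_speed(5, 1000), 75)
  expect_error(young_modulus_from_shear_speed(-1, 1000), "non-negative")
  expect_error(young_modulus_from_shear_speed(1, 0), "positive")
})

test_that("ROI summary matches a brute-force oracle on random instances", {
  # hand-checked toy: {1, 2, 3} kPa
  m <- matrix(0, 5, 5)
  m[2, 2:4] <- c(1, 2, 3)  # pixels (1,1), (2,1), (3,1)
  roi <- tumor_roi(rect_contour(0.5, 0.5, 3.5, 1.5), c(5, 5))
  s <- summarize_roi(stiffness_map(m, 0.1), roi)
  expect_equal(s[c("min", "max", "mean", "sd")],
               list(min = 1, max = 3, mean = 2, sd = 1))

  set.seed(7)
  for (i in 1:100) {
    v <- runif(sample(2:50, 1), 0, 200)
    mm <- matrix(0, 12, max(10, length(v) + 2))
    mm[2, seq_along(v) + 1] <- v
    roi <- tumor_roi(rect_contour(0.5, 0.5, length(v) + 0.5, 1.5),
                     dim(mm))
    got <- summarize_roi(stiffness_map(mm, 0.1), roi)
    want <- bf_summary(mm[roi$pixel_idx])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("representative frame minimizes gel signal with first-index ties", {
  gel <- matrix(FALSE, 4, 4); gel[1, ] <- TRUE
  mk <- function(g) {
    m <- matrix(1, 4, 4); m[1, ] <- g
    stiffness_map(m, 0.1)
  }
  expect_equal(select_representative_frame(list(mk(4)), gel), 1)
  expect_equal(select_representative_frame(list(mk(4), mk(2), mk(9)), gel), 2)
  expect_equal(select_representative_frame(list(mk(3), mk(3), mk(3)), gel), 1)
  expect_error(select_representative_frame(list(), gel), "empty")
})

test_that("noise floor is the interpolated 95th percentile of gel pixels", {
  expect_equal(estimate_noise_floor(rep(0, 40)), 0)
  expect_equal(estimate_noise_floor(1:100), 95.05)
  expect_error(estimate_noise_floor(1:10), "30 gel pixels")
  # monotone in any single pixel value
  g <- runif(50, 0, 5)
  g2 <- g; g2[7] <- g2[7] + 10
  expect_gte(estimate_noise_floor(g2), estimate_noise_floor(g))
})

test_that("mean tumor stiffness averages replicate ROI means, order-invariantly", {
  roi <- tumor_roi(rect_contour(0.5, 0.5, 3.5, 3.5), c(6, 6))
  mk <- function(c) stiffness_map(matrix(c, 6, 6), 0.1)
  acq <- acquisition_set(list(mk(10), mk(20), mk(30)), list(roi, roi, roi), 0)
  expect_equal(mean_tumor_stiffness(acq), 20)
  acq_r <- acquisition_set(list(mk(30), mk(10), mk(20)), list(roi, roi, roi), 0)
  expect_equal(mean_tumor_stiffness(acq_r), 20)
  expect_equal(mean_tumor_stiffness(
    acquisition_set(list(mk(7)), list(roi), 0)), 7)
})

test_that("caliper volume is a*b^2/2 and rejects swapped axes", {
  expect_equal(caliper_volume(4, 2), 8)
  expect_equal(caliper_volume(3, 3), 27 / 2)
  expect_equal(caliper_volume(6, 3), 27)
  expect_error(caliper_volume(2, 4), "major")
})

test_that("stiffness histogram bins percent-of-area over [0, 200]", {
  roi <- tumor_roi(rect_contour(-0.5, -0.5, 9.5, 9.5), c(10, 10))
  h <- stiffness_histogram(stiffness_map(matrix(10.4, 10, 10), 0.1), roi)
  expect_equal(h$percent[h$lower == 10], 100)
  expect_equal(sum(h$percent), 100)

  m <- matrix(c(10, 50), 10, 10)
  h2 <- stiffness_histogram(stiffness_map(m, 0.1), roi)
  expect_equal(h2$percent[h2$lower %in% c(10, 50)], c(50, 50))

  # top bin absorbs values at/above the support
  h3 <- stiffness_histogram(stiffness_map(matrix(205, 10, 10), 0.1), roi)
  expect_equal(h3$percent[h3$lower == 199], 100)
})

test_that("histogram is invariant under pixel permutation and 90-degree rotation", {
  g <- generate_stiffness_map(tiny_stiff_preset(), 5, seed = 4, map_size = 64)
  h <- stiffness_histogram(g$map, g$roi)
  # rotate the map and the contour by 90 degrees clockwise
  n <- 64
  rot_vals <- matrix(0, n, n)
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    rot_vals[x + 1, (n - 1 - y) + 1] <- g$map$values[y + 1, x + 1]
  }
  rot_contour <- cbind(x = (n - 1) - g$roi$contour[, 2], y = g$roi$contour[, 1])
  h_rot <- stiffness_histogram(stiffness_map(rot_vals, 0.1),
                               tumor_roi(rot_contour, c(n, n)))
  expect_equal(h_rot$percent, h$percent, tolerance = 1e-12)
})

test_that("center-to-edge decrease recovers a noiseless linear profile by OLS", {
  p <- tiny_stiff_preset(pixel_noise_sd = 0)
  g <- generate_stiffness_map(p, 5, seed = 6, map_size = 64)
  rec <- radial_records(g$map, g$roi)
  expect_lt(abs(center_to_edge_decrease(rec) - 80), 1)

  # constant field gives zero decrease
  flat <- rec; flat$stiffness_kpa <- 12
  expect_equal(center_to_edge_decrease(flat), 0)

  # sign flips under map reflection 200 - E
  refl <- rec; refl$stiffness_kpa <- 200 - rec$stiffness_kpa
  expect_equal(center_to_edge_decrease(refl),
               -center_to_edge_decrease(rec), tolerance = 1e-9)

  expect_error(center_to_edge_decrease(rec[1:10, ]), "30")
})

test_that("OLS slope helpers match the closed-form oracle on random series", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    day <- sort(sample(0:100, n))
    area <- runif(n, 10, 120)
    expect_equal(growth_rate(day, area), bf_ols_slope(day, area),
                 tolerance = 1e-9)
  }
  expect_equal(growth_rate(c(0, 10), c(10, 30)), 2)
  expect_equal(growth_rate(c(0, 5, 10), c(4, 4, 4)), 0)
  expect_error(growth_rate(c(0, 0, 3), c(1, 2, 3)), "strictly increasing")
})

test_that("spearman uses average ranks and matches brute-force formulas", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_true(spearman(rep(1, 5), 1:5)$degenerate)

  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties likely
    y <- x + rnorm(n)
    if (var(x) == 0) next
    expect_equal(spearman(x, y)$rho, bf_spearman_rho(x, y), tolerance = 1e-12)
    if (!anyDuplicated(x) && !anyDuplicated(y)) {
      expect_equal(spearman(x, y)$rho, bf_spearman_noties(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("soft/stiff classification cuts at 40 kPa with the boundary stiff", {
  expect_equal(classify_soft_stiff(15), "soft")   # soft removal range 8.5-22.6
  expect_equal(classify_soft_stiff(60), "stiff")  # stiff removal range 54.6-78
  expect_equal(classify_soft_stiff(40), "stiff")
  expect_error(classify_soft_stiff(-1), "non-negative")
})

test_that("adding a constant to tumor pixels shifts the mean and leaves radial rho unchanged", {
  g <- generate_stiffness_map(tiny_stiff_preset(), 5, seed = 8, map_size = 64)
  acq <- acquisition_set(list(g$map), list(g$roi), 0)
  m0 <- mean_tumor_stiffness(acq)
  rec0 <- radial_records(g$map, g$roi)

  shifted_vals <- g$map$values
  shifted_vals[g$roi$pixel_idx] <- shifted_vals[g$roi$pixel_idx] + 5
  ms <- stiffness_map(shifted_vals, g$map$pixel_spacing_mm)
  expect_equal(mean_tumor_stiffness(acquisition_set(list(ms), list(g$roi), 0)),
               m0 + 5, tolerance = 1e-12)
  rec1 <- radial_records(ms, g$roi)
  expect_equal(spearman(rec1$r_norm, rec1$stiffness_kpa)$rho,
               spearman(rec0$r_norm, rec0$stiffness_kpa)$rho,
               tolerance = 1e-12)
})

test_that("cohort correlation pools measurements and ignores their order", {
  df <- data.frame(mean_kpa = c(10, 30, 20, 50), area_mm2 = c(30, 60, 45, 100))
  r1 <- cohort_stiffness_growth_correlation(df)
  r2 <- cohort_stiffness_growth_correlation(df[c(3, 1, 4, 2), ])
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$rho, 1)
})
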