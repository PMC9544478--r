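test_that("class histograms are exact and conserve the pixel total", {
  img <- matrix(0L, 12, 10)
  img[2:4, 2:4] <- 1L; img[8:9, 8] <- 2L; img[12, 1:5] <- 3L
  cc <- count_class_pixels(img)
  expect_equal(cc$pixels[cc$class == "vital"], 9L)
  expect_equal(cc$pixels[cc$class == "necrotic"], 2L)
  expect_equal(cc$pixels[cc$class == "scale_label"], 5L)
  expect_equal(sum(cc$pixels), 120L)
  empty <- matrix(0L, 5, 5)
  cc0 <- count_class_pixels(empty)
  expect_equal(cc0$pixels[cc0$class %in% c("vital", "necrotic")], c(0L, 0L))
  bad <- img; bad[1, 1] <- 7L
  expect_error(count_class_pixels(bad), "Unknown class code")
  expect_error(count_class_pixels(matrix(integer(), 0, 0)), "non-empty")
})

test_that("generator ground truth matches the histogram (painted pixels)", {
  im <- synth_segmentation_image(2, 1, seed = 5)
  cc <- count_class_pixels(im$image)
  expect_equal(cc$pixels, unname(im$truth$pixels))
})

test_that("label calibration follows the ratio formula and rejects missing labels", {
  counts <- tibble::tibble(class = names(pixel_classes),
                           code = unname(pixel_classes),
                           pixels = c(4000L, 5000L, 0L, 1000L))
  cal <- calibrate_area(counts, nominal_label_area = 1)
  expect_equal(cal$area[cal$class == "vital"], 5)
  no_label <- counts; no_label$pixels[4] <- 0L
  expect_error(calibrate_area(no_label), "calibrator")
  # paired calibrator image supplies label pixels explicitly
  cal2 <- calibrate_area(no_label, nominal_label_area = 2, label_pixels = 500)
  expect_equal(cal2$area[cal2$class == "vital"], 20)
})

test_that("normalised areas are invariant to zoom", {
  im1 <- synth_segmentation_image(2, 1, seed = 9, zoom = 1)
  im2 <- synth_segmentation_image(2, 1, seed = 9, zoom = 2)
  a1 <- calibrate_area(count_class_pixels(im1$image))
  a2 <- calibrate_area(count_class_pixels(im2$image))
  leaf <- a1$class %in% c("vital", "necrotic")
  # identical layout rendered at 2x: calibrated areas agree up to rasterisation
  expect_equal(a2$area[leaf], a1$area[leaf], tolerance = 0.02)
  # raw pixels scale by zoom^2
  expect_equal(sum(im2$truth$pixels[c("vital", "necrotic")]) /
                 sum(im1$truth$pixels[c("vital", "necrotic")]),
               4, tolerance = 0.02)
})

test_that("vitality percent and the tolerance call follow the strict 50% rule", {
  expect_equal(vitality_percent(979, 21), 97.9)
  expect_equal(vitality_percent(100, 0), 100)
  expect_equal(vitality_percent(5, 5), 50)
  expect_warning(v <- vitality_percent(0, 0), "absent")
  expect_true(is.na(v))
  expect_error(vitality_percent(-1, 5), "non-negative")
  expect_true(classify_tolerant(c(100, 100, 100, 100, 90)))
  expect_false(classify_tolerant(c(50, 50, 50)))    # strict inequality
  expect_false(classify_tolerant(0.03))             # wild-type-like death
  expect_true(classify_tolerant(c(NA, 60, 55)))     # missing images dropped
  expect_error(classify_tolerant(NA_real_), "No replicate")
})

test_that("label images round-trip through PNG", {
  im <- synth_segmentation_image(1, 1, seed = 3, size = 120, disc_radius = 10)
  path <- withr::local_tempfile(fileext = ".png")
  write_label_image(im$image, path)
  expect_identical(read_label_image(path), im$image)
})

test_that("weight series interpolate, extrapolate and validate dry weights", {
  w <- tibble::tibble(pot = "p1", day = c(1, 3), weight_g = c(300, 280),
                      dry_weight_g = 100)
  ws <- compute_water_series(w, target_days = 2)
  expect_equal(ws$weight_g, 290)               # midpoint
  expect_equal(ws$water_content_g, 190)        # minus dry weight
  expect_equal(ws$cumulative_water_loss_g, 10) # saturated minus current
  # interpolation identity at a measured day
  ws3 <- compute_water_series(w, target_days = 3)
  expect_equal(ws3$weight_g, 280)
  # linear extrapolation beyond the last weighing
  ws4 <- compute_water_series(w, target_days = 4)
  expect_equal(ws4$weight_g, 270)
  expect_warning(compute_water_series(w, target_days = 9), "outside")
  bad <- w; bad$dry_weight_g <- 290
  expect_error(compute_water_series(bad, target_days = 2), "dry weight")
  expect_error(compute_water_series(w[1, ], target_days = 2), "fewer than 2")
})

test_that("the water model recovers a pure size effect exactly", {
  d <- tibble::tibble(line = rep(c("wt", "hc31"), each = 5),
                      vital_pixels = rep(c(1, 2, 3, 4, 5), 2),
                      water_loss = 2 + 3 * rep(c(1, 2, 3, 4, 5), 2))
  fit <- fit_water_model(d)
  expect_equal(fit$reduced_slope, 3)
  expect_equal(fit$reduced_r_squared, 1)
  expect_gte(fit$r_squared, fit$reduced_r_squared) # nested models
  expect_equal(tidy(fit)$term,
               c("line", "vital_pixels", "line:vital_pixels", "Residuals"))
  expect_equal(glance(fit)$nobs, 10L)
})

test_that("the water model requires replicated lines and full rank", {
  d <- tibble::tibble(line = c("a", "a", "b"), vital_pixels = c(1, 2, 3),
                      water_loss = c(1, 2, 3))
  expect_error(fit_water_model(d), ">= 2 observations")
  expect_error(fit_water_model(dplyr::mutate(d, line = "a")), ">= 2 lines")
})

test_that("line and interaction stay non-significant when only size matters", {
  set.seed(7)
  n_sim <- 60; alpha_hits <- 0
  sizes <- runif(60, 500, 5000)
  for (i in seq_len(n_sim)) {
    d <- tibble::tibble(
      line = rep(sprintf("L%d", 1:6), each = 10),
      vital_pixels = sizes,
      water_loss = 40 + 0.004 * sizes + rnorm(60, 0, 2))
    fit <- fit_water_model(d)
    p_line <- fit$anova$p.value[fit$anova$term == "line"]
    if (p_line < 0.05) alpha_hits <- alpha_hits + 1
  }
  expect_lte(alpha_hits / n_sim, 0.15) # ~5% nominal, small-sample slack
})

test_that("disc pixel counts grow linearly with disc number", {
  dd <- disc_assay_table(ks = 1:3, reps = 2, noise_rate = 0)
  res <- disc_linearity_check(dd)
  area <- synth_segmentation_image(1, 0, seed = 111)$truth$single_disc_area
  for (cl in c("vital", "necrotic")) {
    row <- res[res$class == cl, ]
    expect_gt(row$r_squared, 0.999)
    expect_equal(row$slope, area, tolerance = 0.02)
    expect_equal(row$intercept, 0, tolerance = area * 0.05)
  }
  expect_error(disc_linearity_check(dd[dd$n_discs == 1, ]), "single disc-count")
})
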