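test_that("well localization recovers the generator's grid and rejects bad geometry", {
  cfg <- generator_config(seed = 11, dpi = 40)
  sp <- generate_plate_image(cfg)
  rois <- locate_wells(sp$image, sp$layout)

  expect_length(rois$masks, 96L)
  got <- rois$centres[match(sp$truth$well, rois$centres$well), ]
  expect_true(all(abs(got$cx - sp$truth$cx) < 1))
  expect_true(all(abs(got$cy - sp$truth$cy) < 1))

  # ROIs are pairwise disjoint: no pixel index appears twice
  keys <- unlist(lapply(rois$masks, function(m) m[, "y"] * 1e6 + m[, "x"]))
  expect_false(anyDuplicated(keys) > 0)

  bad <- sp$layout
  bad$origin_x <- sp$image$width_px  # grid runs off the right edge
  expect_error(locate_wells(sp$image, bad), "outside image bounds")
  expect_error(locate_wells(sp$image, sp$layout, roi_fraction = 0), "positive")
})

test_that("a uniform well yields its exact channel statistics", {
  sp <- generate_plate_image(flat_config(seed = 1, rgb = c(100, 50, 25)))
  rois <- locate_wells(sp$image, sp$layout)
  f <- extract_well_features(sp$image, rois)
  w <- f[f$well == "A1", ]
  expect_equal(w$mean_r, 100)
  expect_equal(w$mean_g, 50)
  expect_equal(w$mean_b, 25)
  expect_equal(w$composite_rgb, 175)
  expect_gte(w$n_pixels, 1L)
})

test_that("noise-free extraction matches generator truth; noisy means obey the SE bound", {
  cfg0 <- generator_config(seed = 7, dpi = 40,
                           channels = data.frame(channel = c("R", "G", "B"),
                                                 slope = c(-0.06134, -0.003, -0.0015),
                                                 intercept = c(100.49757, 160, 190),
                                                 well_sd = 0),
                           pixel_sd = 0)
  sp0 <- generate_plate_image(cfg0)
  f0 <- extract_well_features(sp0$image, locate_wells(sp0$image, sp0$layout))
  m <- merge(f0, sp0$truth, by = "well")
  expect_equal(m$mean_r, m$true_r, tolerance = 1e-9)
  expect_equal(m$mean_g, m$true_g, tolerance = 1e-9)

  # with pure pixel noise sd = 2, each well mean stays within 3 SEs of truth
  cfgn <- generator_config(seed = 8, dpi = 40,
                           channels = data.frame(channel = c("R", "G", "B"),
                                                 slope = c(-0.06134, -0.003, -0.0015),
                                                 intercept = c(100.49757, 160, 190),
                                                 well_sd = 0),
                           pixel_sd = 2)
  spn <- generate_plate_image(cfgn)
  fn <- extract_well_features(spn$image, locate_wells(spn$image, spn$layout))
  mn <- merge(fn, spn$truth, by = "well")
  expect_true(all(abs(mn$mean_r - mn$true_r) < 3 * 2 / sqrt(mn$n_pixels)))

  # zero noise: rank order of mean R equals rank order of truth
  expect_equal(order(m$mean_r), order(m$true_r))
})

test_that("features are invariant to pixels outside every ROI", {
  cfg <- generator_config(seed = 9, dpi = 40)
  sp <- generate_plate_image(cfg)
  rois <- locate_wells(sp$image, sp$layout)
  f1 <- extract_well_features(sp$image, rois)

  scribbled <- sp$image
  scribbled$pixels[1:5, , ] <- 0       # margin rows far from any well
  scribbled$pixels[, 1:5, ] <- 255
  f2 <- extract_well_features(scribbled, rois)
  expect_identical(f1, f2)

  # composite is the exact sum of the three channel statistics
  expect_identical(f1$composite_rgb, f1$mean_r + f1$mean_g + f1$mean_b)
})

test_that("median statistic is available and resists a hot pixel", {
  sp <- generate_plate_image(flat_config(seed = 2, rgb = c(100, 50, 25)))
  rois <- locate_wells(sp$image, sp$layout)
  px <- rois$masks[["A1"]][1, , drop = FALSE]
  sp$image$pixels[px[, "y"], px[, "x"], 1] <- 255  # speck in one ROI pixel
  f_mean <- extract_well_features(sp$image, rois)
  f_med <- extract_well_features(sp$image, rois, stat = "median")
  expect_gt(f_mean$mean_r[f_mean$well == "A1"], 100)
  expect_equal(f_med$mean_r[f_med$well == "A1"], 100)
})

test_that("centroid refinement corrects a small grid offset", {
  cfg <- generator_config(seed = 13, dpi = 40, pixel_sd = 0.5)
  sp <- generate_plate_image(cfg)
  off <- sp$layout
  off$origin_x <- off$origin_x + 2
  off$origin_y <- off$origin_y - 2
  rois <- locate_wells(sp$image, off, refine = TRUE)
  got <- rois$centres[match(sp$truth$well, rois$centres$well), ]
  expect_lt(stats::median(abs(got$cx - sp$truth$cx)), 1)
  expect_lt(stats::median(abs(got$cy - sp$truth$cy)), 1)
})
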