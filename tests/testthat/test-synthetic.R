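test_that("generation is reproducible bit-for-bit under a fixed seed", {
  cfg <- generator_config(seed = 41, dpi = 40)
  a <- generate_plate_image(cfg)
  b <- generate_plate_image(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)

  k1 <- generate_kinetics(cfg)
  k2 <- generate_kinetics(cfg)
  expect_identical(k1$responses, k2$responses)

  d1 <- generate_dose_response(preset = "tmb", seed = 41)
  d2 <- generate_dose_response(preset = "tmb", seed = 41)
  expect_identical(d1$responses, d2$responses)

  r1 <- generate_well_responses(cfg)
  r2 <- generate_well_responses(cfg)
  expect_identical(r1, r2)
})

test_that("unrenderable concentrations are rejected with the offender named", {
  cfg <- generator_config(seed = 42, concs = c(100, 5000))
  # 100.49757 - 0.06134 * 5000 < 0: impossible channel mean
  expect_error(generate_well_responses(cfg), "5000")
  expect_error(generate_plate_image(cfg), "5000")
  expect_error(generator_config(seed = 1, concs = -5), ">= 0")
  expect_error(generator_config(), "seed")
})

test_that("kinetics start at the intercept, develop monotonically and saturate at t*", {
  cfg <- generator_config(seed = 43, times = c(0, 5, 10, 15, 20, 25))
  kin <- generate_kinetics(cfg)
  expect_equal(attr(kin, "t_star"), 15)

  # at t = 0 no colour has developed: responses equal the intercept +/- noise
  r_row <- cfg$channels[cfg$channels$channel == "R", ]
  expect_true(all(abs(kin$responses[1, ] - r_row$intercept) < 5 * r_row$well_sd))

  # after t*, the per-time calibration slope has essentially converged
  for (i in which(kin$times > cfg$t_star)) {
    f <- fit_calibration(kin$concs, kin$responses[i, ])
    expect_lt(abs(f$slope - r_row$slope) / abs(r_row$slope), 0.05)
  }
  at_tstar <- fit_calibration(kin$concs, kin$responses[kin$times == 15, ])
  expect_gt(abs(at_tstar$slope), 0.9 * abs(r_row$slope))

  expect_error(generate_kinetics(generator_config(seed = 1, times = c(5, 5, 10))),
               "strictly increasing")
  expect_error(generate_kinetics(generator_config(seed = 1, times = c(5, 10), t_star = 15)),
               "beyond the time grid")
})

test_that("reading-time selection on generated kinetics lands at or after saturation", {
  for (s in 1:8) {
    kin <- generate_kinetics(generator_config(seed = 500 + s))
    sel <- select_reading_time(kin)
    expect_gte(sel$best, 15)
  }
})

test_that("dose-response generator validates its inputs", {
  expect_error(generate_dose_response("saturating", doses = 1:5, rmax = -1, k = 1),
               "positive")
  expect_error(generate_dose_response("sigmoid", doses = 1:5, rmax = 1))
  lin <- generate_dose_response("linear", doses = seq(10, 300, 20), rmax = 0.15,
                                noise_sd = 0, seed = 2)
  expect_warning(res <- saturation_dose(lin), "not saturated")
  expect_equal(res$status, "not_saturated")
})

test_that("the full loop from pixels to ppb recovers truth within propagated noise", {
  # standards on rows A-E, unknowns with known truth on rows F-G
  cfg <- generator_config(seed = 44, dpi = 60)
  std_concs <- rep(cfg$concs[cfg$concs >= 25 & cfg$concs <= 600], each = 6)
  unk_concs <- c(30, 75, 150, 220, 333, 410, 480, 555)
  wells <- well_labels()[seq_len(length(std_concs) + length(unk_concs))]
  lay <- data.frame(well = wells,
                    role = rep(c("standard", "sample"),
                               c(length(std_concs), length(unk_concs))),
                    conc_ppb = c(std_concs, unk_concs),
                    sample_id = c(rep(NA, length(std_concs)),
                                  sprintf("u%02d", seq_along(unk_concs))))
  sp <- generate_plate_image(cfg, layout_from_config(cfg, lay))
  feats <- extract_well_features(sp$image, locate_wells(sp$image, sp$layout))

  std <- merge(feats, sp$truth, by = "well")
  std <- std[std$well %in% wells[seq_along(std_concs)], ]
  fit <- fit_calibration(std$conc_ppb, std$mean_r, linear_range = c(25, 600))
  pred <- batch_predict(fit, feats, sp$layout)

  truth <- lay$conc_ppb[match(pred$sample_id, lay$sample_id)]
  n_px <- feats$n_pixels[1]
  sd_resp <- sqrt(0.5^2 + cfg$pixel_sd^2 / n_px)
  tol <- 3 * sd_resp / abs(fit$slope)
  expect_true(all(pred$status == "OK"))
  expect_true(mean(abs(pred$conc_ppb - truth) <= tol) >= 0.95)
})
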