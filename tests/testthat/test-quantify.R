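test_that("inverting the published imager calibration reproduces the survey rows", {
  m <- imager_model()
  p <- predict_concentration(m, c(89.779, 65.795, 97.994, 75.200))
  expect_equal(p$status, rep("OK", 4))
  expect_equal(round(p$conc_ppb, 3), c(174.740, 565.741, 40.815, 412.416))

  # response equal to the intercept maps to 0 ppb, below the linear floor
  p0 <- predict_concentration(m, 100.49757)
  expect_equal(p0$status, "ND")
  expect_true(is.na(p0$conc_ppb))

  expect_error(predict_concentration(m, c(1, NA)), "finite")
})

test_that("the linear range is closed at both ends and exact at the boundary", {
  # clean binary-exact model so the boundary is not blurred by rounding
  m <- calibration_model(slope = -0.5, intercept = 100, linear_range = c(25, 600))
  y25 <- -0.5 * 25 + 100    # 87.5
  y600 <- -0.5 * 600 + 100  # -200... allow negative response scale here
  expect_error(calibration_model(slope = -0.5, intercept = 100, linear_range = c(600, 25)))
  p <- suppressWarnings(predict_concentration(m, c(y25, y600)))
  expect_equal(p$status, c("OK", "OK"))
  expect_equal(p$conc_ppb, c(25, 600))

  up <- .Machine$double.eps
  p2 <- predict_concentration(m, c(y25 * (1 + up), y600 - 1e-10))
  expect_equal(p2$status, c("ND", "ND"))
})

test_that("predictions invert the fit exactly and are monotone in response", {
  x <- c(25, 50, 100, 200, 400, 600)
  fit <- fit_calibration(x, 100.49757 - 0.06134 * x, linear_range = c(25, 600))
  for (x0 in c(25, 60, 321.5, 600)) {
    y0 <- predict(fit, x0)
    expect_equal(predict_concentration(fit, y0)$conc_ppb, x0, tolerance = 1e-9)
  }
  resp <- seq(98, 64, by = -1)
  p <- predict_concentration(fit, resp)
  expect_true(all(diff(p$conc_ppb) > 0))  # negative slope: conc rises as response falls
})

test_that("batch prediction averages replicates on the response scale and orders by sample", {
  m <- imager_model()
  s <- survey_samples()
  ok <- s[s$status == "OK", ]
  # close the loop: forward-model responses from the reported concentrations
  responses <- m$slope * ok$crdetector_ppb + m$intercept

  wells <- well_labels()[seq_len(nrow(ok))]
  layout <- plate_layout(data.frame(well = wells, role = "sample",
                                    conc_ppb = NA_real_,
                                    sample_id = sprintf("S%02d", ok$sample_id)),
                         origin_x = 50, origin_y = 50, pitch_px = 20,
                         well_radius_px = 8)
  feats <- data.frame(well = wells, mean_r = responses, mean_g = 0, mean_b = 0,
                      composite_rgb = responses, n_pixels = 10L)
  pred <- batch_predict(m, feats, layout)
  expect_equal(pred$sample_id, sort(sprintf("S%02d", ok$sample_id)))
  reported <- pred$conc_ppb[match(sprintf("S%02d", ok$sample_id), pred$sample_id)]
  expect_equal(reported, ok$crdetector_ppb, tolerance = 1e-3)

  # replicate wells with identical response behave like a single well
  lay2 <- plate_layout(data.frame(well = c("A1", "A2", "B1"),
                                  role = "sample", conc_ppb = NA_real_,
                                  sample_id = c("u", "u", "v")),
                       origin_x = 50, origin_y = 50, pitch_px = 20, well_radius_px = 8)
  f2 <- data.frame(well = c("A1", "A2", "B1"), mean_r = c(89.779, 89.779, 75.2),
                   mean_g = 0, mean_b = 0, composite_rgb = 0, n_pixels = 5L)
  p2 <- batch_predict(m, f2, lay2)
  expect_equal(round(p2$conc_ppb, 3), c(174.740, 412.416))

  # no sample wells -> empty report; unknown well label -> error
  lay0 <- plate_layout(data.frame(well = "A1", role = "blank",
                                  conc_ppb = NA_real_, sample_id = NA_character_),
                       origin_x = 50, origin_y = 50, pitch_px = 20, well_radius_px = 8)
  expect_equal(nrow(batch_predict(m, f2, lay0)), 0L)
  f_bad <- transform(f2, well = c("A1", "Z9", "B1"))
  expect_error(batch_predict(m, f_bad, lay2), "unknown well label")
  expect_error(batch_predict(m, f2[1, ], lay2), "does not cover")
})

test_that("prediction reports render N.D. and round to 3 decimals", {
  m <- imager_model()
  p <- predict_concentration(m, c(89.779, 100.49757), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(p, path)
  out <- read.csv(path, comment.char = "#", colClasses = "character")
  expect_equal(out$conc_ppb, c("174.740", "N.D."))
  expect_equal(out$status, c("OK", "ND"))
})
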