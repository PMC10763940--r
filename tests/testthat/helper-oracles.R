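# Independent closed-form oracles, kept free of the package's fitting code.

# simple linear regression by the textbook normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  sst <- sum((y - yb)^2)
  r2 <- 1 - sum(res^2) / sst
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + xb^2 / sxx)),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# product-moment correlation straight from the covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# published-constants imager calibration used throughout the tests
imager_model <- function() {
  calibration_model(slope = -0.06134, intercept = 100.49757,
                    se_slope = 0.00222, se_intercept = 0.63949,
                    channel = "R", linear_range = c(25, 600))
}

# tiny uniform plate: every channel flat at the given intercepts, no noise
flat_config <- function(seed, rgb = c(100, 50, 25), dpi = 30) {
  generator_config(seed = seed, concs = 0, replicates = 1L,
                   channels = data.frame(channel = c("R", "G", "B"),
                                         slope = 0, intercept = rgb,
                                         well_sd = 0),
                   pixel_sd = 0, dpi = dpi)
}
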