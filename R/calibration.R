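#' Fit a linear colorimetric calibration curve
#'
#' Fits the straight-line response model `Y = m * X + c` by ordinary least
#' squares, where `X` is the Cr(VI) concentration in ppb and `Y` the chosen
#' response (a channel statistic from the plate imager, or absorbance at
#' 650 nm from a spectrophotometer). Standard errors of slope and intercept
#' come from the classical closed form, the adjusted R-squared is
#' `1 - (1 - R2) * (n - 1) / (n - 2)`, and the detection and quantification
#' limits are `3.3 * sigma / |m|` and `10 * sigma / |m|` with `sigma`
#' selected by `sigma_mode` (see [detection_limits()]).
#'
#' Replicate wells enter the fit as individual pooled points (not
#' per-concentration means), so the residual degrees of freedom and standard
#' errors retain their usual meaning.
#'
#' @param conc numeric vector of concentrations in ppb (the predictor), or a
#'   data frame with columns `conc_ppb` and `response`.
#' @param response numeric vector of responses, same length as `conc`.
#' @param channel label of the response: `"R"`, `"G"`, `"B"`, `"R+G+B"` or
#'   `"absorbance650"`.
#' @param sigma_mode which uncertainty feeds the detection limits:
#'   `"slope_se"` (default), `"intercept_se"` or `"residual_sd"`.
#' @param linear_range length-2 numeric, the validated linear range in ppb;
#'   defaults to the span of `conc`. Predictions outside it are reported
#'   non-detectable.
#' @return An object of class `cr_calibration` with components `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `sigma_resid`, `r2`, `adj_r2`,
#'   `n`, `channel`, `linear_range`, `sigma_mode`, `lod_ppb`, `loq_ppb` (and
#'   unrounded `lod_raw`, `loq_raw`), plus the fitting data for methods.
#' @seealso [predict_concentration()], [detection_limits()],
#'   [calibration_model()] for building a model from known constants.
#' @examples
#' fit <- fit_calibration(c(25, 50, 100, 200, 400, 600),
#'                        100.5 - 0.0613 * c(25, 50, 100, 200, 400, 600))
#' coef(fit)
#' @export
fit_calibration <- function(conc, response, channel = "R",
                            sigma_mode = c("slope_se", "intercept_se", "residual_sd"),
                            linear_range = NULL) {
  if (is.data.frame(conc)) {
    if (!all(c("conc_ppb", "response") %in% names(conc)))
      stop("data frame input needs columns 'conc_ppb' and 'response'")
    response <- conc$response
    conc <- conc$conc_ppb
  }
  sigma_mode <- match.arg(sigma_mode)
  if (length(conc) != length(response))
    stop("'conc' and 'response' must have equal length")
  keep <- is.finite(conc) & is.finite(response)
  conc <- conc[keep]; response <- response[keep]
  n <- length(conc)
  if (n < 3L) stop("need >= 3 points to estimate standard errors (got ", n, ")")
  if (length(unique(conc)) < 2L)
    stop("all concentrations identical: slope is not estimable")

  fit <- stats::lm(response ~ conc)
  sm <- suppressWarnings(summary(fit))  # noise-free lines are legitimate input
  cf <- sm$coefficients
  r2 <- sm$r.squared
  m <- list(slope = unname(cf["conc", "Estimate"]),
            intercept = unname(cf["(Intercept)", "Estimate"]),
            se_slope = unname(cf["conc", "Std. Error"]),
            se_intercept = unname(cf["(Intercept)", "Std. Error"]),
            sigma_resid = sm$sigma,
            r2 = r2,
            adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
            n = n,
            channel = channel,
            sigma_mode = sigma_mode,
            linear_range = if (is.null(linear_range)) range(conc) else as.numeric(linear_range),
            data = data.frame(conc_ppb = conc, response = response),
            fitted = unname(stats::fitted(fit)))
  if (m$linear_range[1] >= m$linear_range[2])
    stop("linear_range must satisfy lo < hi")
  dl <- detection_limits_impl(m, sigma_mode)
  m[names(dl)] <- dl
  class(m) <- "cr_calibration"
  m
}

#' Build a calibration model from known constants
#'
#' Constructs a `cr_calibration` object directly from published or persisted
#' slope/intercept values (and optionally their standard errors), without
#' refitting. Useful for applying a previously validated calibration.
#'
#' @param slope,intercept line coefficients (response units per ppb;
#'   response at 0 ppb).
#' @param se_slope,se_intercept,sigma_resid uncertainties; `NA` if unknown
#'   (detection limits are then unavailable for the corresponding
#'   `sigma_mode`).
#' @param r2,adj_r2,n goodness-of-fit metadata, `NA` if unknown.
#' @inheritParams fit_calibration
#' @return A `cr_calibration` object.
#' @examples
#' m <- calibration_model(slope = -0.06134, intercept = 100.49757,
#'                        se_slope = 0.00222, linear_range = c(25, 600))
#' m$lod_ppb
#' @export
calibration_model <- function(slope, intercept, se_slope = NA_real_,
                              se_intercept = NA_real_, sigma_resid = NA_real_,
                              r2 = NA_real_, adj_r2 = NA_real_, n = NA_integer_,
                              channel = "R",
                              sigma_mode = c("slope_se", "intercept_se", "residual_sd"),
                              linear_range = c(25, 600)) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite numbers")
  if (linear_range[1] >= linear_range[2]) stop("linear_range must satisfy lo < hi")
  m <- list(slope = slope, intercept = intercept,
            se_slope = se_slope, se_intercept = se_intercept,
            sigma_resid = sigma_resid, r2 = r2, adj_r2 = adj_r2,
            n = n, channel = channel, sigma_mode = sigma_mode,
            linear_range = as.numeric(linear_range),
            data = NULL, fitted = NULL)
  sig <- sigma_for_mode(m, sigma_mode)
  if (is.finite(sig) && slope != 0) {
    dl <- detection_limits_impl(m, sigma_mode)
    m[names(dl)] <- dl
  } else {
    m[c("lod_ppb", "loq_ppb", "lod_raw", "loq_raw")] <- NA_real_
  }
  class(m) <- "cr_calibration"
  m
}

sigma_for_mode <- function(model, sigma_mode) {
  switch(sigma_mode,
         slope_se = model$se_slope,
         intercept_se = model$se_intercept,
         residual_sd = model$sigma_resid,
         stop("unknown sigma_mode: ", sigma_mode))
}

detection_limits_impl <- function(model, sigma_mode) {
  if (!is.finite(model$slope) || model$slope == 0)
    stop("detection limits are undefined for zero slope")
  sigma <- sigma_for_mode(model, sigma_mode)
  if (!is.finite(sigma))
    stop("sigma for mode '", sigma_mode, "' is not available in this model")
  lod <- 3.3 * sigma / abs(model$slope)
  loq <- 10 * sigma / abs(model$slope)
  list(lod_raw = lod, loq_raw = loq,
       lod_ppb = round(lod, 2), loq_ppb = round(loq, 2))
}

#' Detection and quantification limits of a calibration
#'
#' `LOD = 3.3 * sigma / |slope|`, `LOQ = 10 * sigma / |slope|`. The default
#' `sigma_mode = "slope_se"` takes sigma as the standard error of the slope;
#' ICH-style alternatives using the intercept standard error or the residual
#' standard deviation are available. Values are reported rounded to 2
#' decimals with the raw values retained.
#'
#' @param model a `cr_calibration`.
#' @param sigma_mode override of the model's sigma mode.
#' @return List with `lod_ppb`, `loq_ppb` (rounded) and `lod_raw`, `loq_raw`.
#' @examples
#' m <- calibration_model(-0.06134, 100.49757, se_slope = 0.00222)
#' detection_limits(m)
#' @export
detection_limits <- function(model, sigma_mode = model$sigma_mode) {
  stopifnot(inherits(model, "cr_calibration"))
  detection_limits_impl(model, sigma_mode)
}

#' @export
print.cr_calibration <- function(x, digits = 5, ...) {
  cat("Colorimetric calibration (channel ", x$channel, ")\n", sep = "")
  cat(sprintf("  response = %s * [Cr(VI) ppb] + %s\n",
              format(x$slope, digits = digits), format(x$intercept, digits = digits)))
  if (is.finite(x$adj_r2))
    cat(sprintf("  n = %d, R2 = %.5f, adjusted R2 = %.5f\n", x$n, x$r2, x$adj_r2))
  cat(sprintf("  linear range: %g-%g ppb", x$linear_range[1], x$linear_range[2]))
  if (is.finite(x$lod_ppb))
    cat(sprintf("; LOD %.2f ppb, LOQ %.2f ppb (sigma: %s)", x$lod_ppb, x$loq_ppb, x$sigma_mode))
  cat("\n")
  invisible(x)
}

#' @export
summary.cr_calibration <- function(object, ...) {
  print(object)
  ct <- rbind(intercept = c(object$intercept, object$se_intercept),
              slope = c(object$slope, object$se_slope))
  colnames(ct) <- c("Estimate", "Std. Error")
  cat("\nCoefficients:\n")
  print(ct)
  if (!is.null(object$data)) {
    cat(sprintf("\nResidual SD: %.5g on %d degrees of freedom\n",
                object$sigma_resid, object$n - 2L))
  }
  invisible(object)
}

#' @export
coef.cr_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted response at given concentrations
#'
#' Forward evaluation of the calibration line. For the inverse operation
#' (response to concentration) see [predict_concentration()].
#'
#' @param object a `cr_calibration`.
#' @param conc concentrations in ppb; if missing, the fitted values of the
#'   training data are returned.
#' @param ... unused.
#' @export
predict.cr_calibration <- function(object, conc, ...) {
  if (missing(conc)) {
    if (is.null(object$fitted)) stop("model has no training data; supply 'conc'")
    return(object$fitted)
  }
  object$slope * conc + object$intercept
}

#' @export
residuals.cr_calibration <- function(object, ...) {
  if (is.null(object$data)) stop("model has no training data")
  object$data$response - object$fitted
}

#' Plot a calibration curve
#'
#' Scatter of the training points with the fitted line and the validated
#' linear range shaded.
#'
#' @param x a fitted `cr_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cr_calibration <- function(x, ...) {
  if (is.null(x$data)) stop("model has no training data to plot")
  graphics::plot(x$data$conc_ppb, x$data$response,
                 xlab = "Cr(VI) (ppb)",
                 ylab = paste0("response (", x$channel, ")"), ...)
  usr <- graphics::par("usr")
  graphics::rect(x$linear_range[1], usr[3], x$linear_range[2], usr[4],
                 col = grDevices::adjustcolor("steelblue", 0.08), border = NA)
  graphics::abline(a = x$intercept, b = x$slope, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate replicate response tables from a calibration
#'
#' Draws responses `slope * conc + intercept + N(0, sigma_resid)` at the
#' model's training concentrations (or supplied ones).
#'
#' @param object a `cr_calibration` with a finite residual SD.
#' @param nsim number of replicate tables.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param conc concentrations to simulate at (defaults to training data).
#' @param ... unused.
#' @return Data frame with one simulated response column per replicate.
#' @export
simulate.cr_calibration <- function(object, nsim = 1, seed = NULL,
                                    conc = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conc)) {
    if (is.null(object$data)) stop("model has no training data; supply 'conc'")
    conc <- object$data$conc_ppb
  }
  if (!is.finite(object$sigma_resid))
    stop("model has no residual SD to simulate from")
  mu <- object$slope * conc + object$intercept
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma_resid)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(conc_ppb = conc, out)
}
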