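#' Invert a calibration to Cr(VI) concentrations
#'
#' Solves the calibration line for concentration, `X = (Y - c) / m`, and
#' applies the out-of-range rule: a raw prediction outside the validated
#' linear range (closed interval, default 25-600 ppb) is reported
#' non-detectable (`"ND"`) with no concentration. Concentrations are stored
#' at full precision; printing and CSV reports round to 3 decimals.
#'
#' @param model a `cr_calibration` with non-zero slope.
#' @param response numeric vector of responses (channel value or
#'   absorbance); must be finite.
#' @param sample_id optional identifiers, recycled against `response`.
#' @return A data frame of class `cr_prediction` with columns `sample_id`,
#'   `response`, `conc_ppb` (`NA` when non-detectable) and `status`
#'   (`"OK"` or `"ND"`).
#' @examples
#' m <- calibration_model(-0.06134, 100.49757, se_slope = 0.00222)
#' predict_concentration(m, c(89.779, 100.49757))
#' @export
predict_concentration <- function(model, response, sample_id = NULL) {
  stopifnot(inherits(model, "cr_calibration"))
  if (!is.finite(model$slope) || model$slope == 0)
    stop("calibration slope must be non-zero to invert")
  if (!all(is.finite(response)))
    stop("responses must be finite")
  if (is.null(sample_id)) sample_id <- as.character(seq_along(response))
  raw <- (response - model$intercept) / model$slope
  lo <- model$linear_range[1]; hi <- model$linear_range[2]
  ok <- raw >= lo & raw <= hi
  out <- data.frame(sample_id = as.character(sample_id),
                    response = response,
                    conc_ppb = ifelse(ok, raw, NA_real_),
                    status = ifelse(ok, "OK", "ND"),
                    stringsAsFactors = FALSE)
  attr(out, "linear_range") <- c(lo, hi)
  class(out) <- c("cr_prediction", "data.frame")
  out
}

#' @export
print.cr_prediction <- function(x, ...) {
  shown <- x
  shown$conc_ppb <- ifelse(shown$status == "ND", "N.D.",
                           formatC(shown$conc_ppb, format = "f", digits = 3))
  print.data.frame(shown, row.names = FALSE)
  rng <- attr(x, "linear_range")
  cat(sprintf("(N.D. = outside the %g-%g ppb linear range)\n", rng[1], rng[2]))
  invisible(x)
}

#' Predict concentrations for every unknown sample on a plate
#'
#' Joins a well-feature table to the plate layout, takes the response column
#' matching the model's channel, averages replicate wells of a sample on the
#' response scale (linear-calibration practice: average the measurement,
#' then invert once), and inverts the calibration. Results are ordered by
#' sample id.
#'
#' @param model a `cr_calibration`.
#' @param features a [extract_well_features()] table covering the layout's
#'   sample wells (a `response` column is used directly for
#'   `channel = "absorbance650"`).
#' @param layout a [plate_layout] naming the unknown sample wells.
#' @return A `cr_prediction` data frame, one row per sample id.
#' @export
batch_predict <- function(model, features, layout) {
  stopifnot(inherits(model, "cr_calibration"), is.data.frame(features),
            inherits(layout, "plate_layout"))
  wl <- layout$wells
  unknown <- setdiff(features$well, well_labels(layout$n_rows, layout$n_cols))
  if (length(unknown))
    stop("unknown well label(s) in feature table: ", paste(unknown, collapse = ", "))
  samples <- wl[wl$role == "sample", , drop = FALSE]
  if (nrow(samples) == 0L) {
    return(predict_concentration(model, numeric(0), character(0)))
  }
  missing_wells <- setdiff(samples$well, features$well)
  if (length(missing_wells))
    stop("feature table does not cover sample well(s): ",
         paste(missing_wells, collapse = ", "))
  col <- response_column(model$channel, features)
  idx <- match(samples$well, features$well)
  resp <- features[[col]][idx]
  agg <- tapply(resp, samples$sample_id, mean)
  ids <- sort(names(agg))
  predict_concentration(model, as.numeric(agg[ids]), ids)
}

response_column <- function(channel, features) {
  col <- switch(channel,
                "R" = "mean_r", "G" = "mean_g", "B" = "mean_b",
                "R+G+B" = "composite_rgb",
                "absorbance650" = "response",
                stop("unknown channel: ", channel))
  if (!col %in% names(features))
    stop("feature table has no '", col, "' column for channel ", channel)
  col
}

#' Write a prediction report CSV
#'
#' Concentrations are rounded to 3 decimals and non-detectable entries are
#' rendered as the literal `N.D.`.
#'
#' @param predictions a `cr_prediction` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(sample_id = predictions$sample_id,
                    response = predictions$response,
                    conc_ppb = ifelse(predictions$status == "ND", "N.D.",
                                      formatC(predictions$conc_ppb,
                                              format = "f", digits = 3)),
                    status = predictions$status)
  write_versioned_csv(out, path, "predictions")
}
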