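CSV_SCHEMA_VERSION <- "1.0"
JSON_SCHEMA_VERSION <- "1.0"

# CSV with a '#'-prefixed schema header line; readers skip comment lines.
write_versioned_csv <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chromocal %s schema_version=%s", what, CSV_SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a well-feature table
#'
#' @param features a `well_features` data frame.
#' @param path CSV path.
#' @return `path` (write) or the feature data frame (read).
#' @export
write_features <- function(features, path) {
  write_versioned_csv(features, path, "features")
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read_versioned_csv(path)
  req <- c("well", "mean_r", "mean_g", "mean_b", "composite_rgb", "n_pixels")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("feature CSV missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("well_features", "data.frame")
  df
}

#' Write / read a plate-layout table
#'
#' The CSV holds the well assignments (`well,role,conc_ppb,sample_id`);
#' geometry is supplied when reading since it belongs to the imaging setup,
#' not the sample map.
#'
#' @param layout a [plate_layout].
#' @param path CSV path.
#' @param origin_x,origin_y,pitch_px,well_radius_px grid geometry in pixels
#'   (see [plate_layout()]).
#' @return `path` (write) or a [plate_layout] (read).
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  write_versioned_csv(layout$wells, path, "layout")
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path, origin_x, origin_y, pitch_px, well_radius_px) {
  df <- read_versioned_csv(path)
  req <- c("well", "role", "conc_ppb", "sample_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("layout CSV missing column(s): ", paste(miss, collapse = ", "))
  df$conc_ppb <- as.numeric(df$conc_ppb)
  df$sample_id <- as.character(df$sample_id)
  plate_layout(df, origin_x, origin_y, pitch_px, well_radius_px)
}

#' Persist a calibration model as JSON
#'
#' Stores all coefficients, uncertainties, goodness of fit, linear range and
#' detection limits, with a schema version, creation timestamp and optional
#' seed provenance. [read_calibration()] restores a working
#' `cr_calibration` (without the training data).
#'
#' @param model a `cr_calibration`.
#' @param path JSON path.
#' @param seed optional seed recorded for provenance.
#' @return `path` (write) or a `cr_calibration` (read).
#' @export
write_calibration <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "cr_calibration"))
  payload <- list(schema_version = JSON_SCHEMA_VERSION,
                  channel = model$channel,
                  slope = model$slope, intercept = model$intercept,
                  se_slope = model$se_slope, se_intercept = model$se_intercept,
                  sigma_resid = model$sigma_resid,
                  r2 = model$r2, adj_r2 = model$adj_r2, n = model$n,
                  linear_lo = model$linear_range[1],
                  linear_hi = model$linear_range[2],
                  lod_ppb = model$lod_ppb, loq_ppb = model$loq_ppb,
                  lod_raw = model$lod_raw, loq_raw = model$loq_raw,
                  sigma_mode = model$sigma_mode,
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  seed = seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("schema_version", "channel", "slope", "intercept", "linear_lo", "linear_hi")
  miss <- setdiff(req, names(p))
  if (length(miss)) stop("calibration JSON missing field(s): ", paste(miss, collapse = ", "))
  num_or_na <- function(x) {
    if (is.null(x) || length(x) == 0 || identical(x, "NA")) NA_real_ else as.numeric(x)
  }
  calibration_model(slope = p$slope, intercept = p$intercept,
                    se_slope = num_or_na(p$se_slope),
                    se_intercept = num_or_na(p$se_intercept),
                    sigma_resid = num_or_na(p$sigma_resid),
                    r2 = num_or_na(p$r2), adj_r2 = num_or_na(p$adj_r2),
                    n = if (is.null(p$n)) NA_integer_ else as.integer(p$n),
                    channel = p$channel, sigma_mode = p$sigma_mode,
                    linear_range = c(p$linear_lo, p$linear_hi))
}

#' Read a long-format response table
#'
#' Expects columns `conc_ppb,response` (one row per well); extra columns are
#' kept.
#'
#' @param path CSV path.
#' @return Data frame with at least `conc_ppb` and `response`.
#' @export
read_response_table <- function(path) {
  df <- read_versioned_csv(path)
  if (!all(c("conc_ppb", "response") %in% names(df)))
    stop("response CSV needs columns 'conc_ppb' and 'response'")
  df
}

#' Bundled river-water survey
#'
#' A 27-sample field survey of river water analysed by both methods: the
#' reference UV-Vis spectrophotometer (absorbance at 650 nm and its
#' predicted concentration) and the plate imager (mean red-channel "UIIS
#' index" and its predicted concentration), with the per-sample error
#' fraction. Non-detectable imager results (outside the 25-600 ppb range)
#' are `NA` with `status = "ND"`.
#'
#' @return Data frame with columns `sample_id`, `absorbance`,
#'   `spectro_ppb`, `uiis_index`, `crdetector_ppb`, `status`,
#'   `error_fraction`.
#' @export
survey_samples <- function() {
  path <- system.file("extdata", "river_survey.csv", package = "chromocal")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", "N.D.", "N.A."))
  df$status <- ifelse(is.na(df$crdetector_ppb), "ND", "OK")
  df
}

#' Bundled spike-recovery series
#'
#' Recovery percentages of Cr(VI) spiked into ultrapure water at four
#' levels, as reported by the plate imager.
#'
#' @return Data frame with columns `spiked_ppb`, `recovery_pct`.
#' @export
spike_recovery_series <- function() {
  path <- system.file("extdata", "spike_recovery.csv", package = "chromocal")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
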