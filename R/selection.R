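#' Select the most informative colour channel
#'
#' Fits a linear calibration of each candidate response -- R, the composite
#' R+G+B, G and B -- against concentration and returns the channel with the
#' highest adjusted R-squared. With the blue oxidized-TMB product the red
#' channel carries the signal; the composite inherits part of it, while G
#' and B stay nearly flat. Exact ties are broken by the fixed candidate
#' order R, R+G+B, G, B.
#'
#' @param features a [extract_well_features()] table (or any data frame with
#'   `mean_r`, `mean_g`, `mean_b`, `composite_rgb`).
#' @param conc_ppb concentration of each row, in ppb; at least 3 distinct
#'   levels are required.
#' @return An object of class `channel_selection`: list with `best` (channel
#'   name) and `report` (data frame of channel, slope, r2, adj_r2).
#' @export
select_channel <- function(features, conc_ppb) {
  stopifnot(is.data.frame(features))
  if (length(conc_ppb) != nrow(features))
    stop("'conc_ppb' must match the feature rows")
  if (length(unique(conc_ppb[is.finite(conc_ppb)])) < 3L)
    stop("need >= 3 concentration levels for channel selection")
  cand <- c("R" = "mean_r", "R+G+B" = "composite_rgb",
            "G" = "mean_g", "B" = "mean_b")
  miss <- setdiff(unname(cand), names(features))
  if (length(miss)) stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  rep <- data.frame(channel = names(cand), slope = NA_real_,
                    r2 = NA_real_, adj_r2 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(cand)) {
    f <- fit_calibration(conc_ppb, features[[cand[i]]], channel = names(cand)[i])
    rep$slope[i] <- f$slope; rep$r2[i] <- f$r2; rep$adj_r2[i] <- f$adj_r2
  }
  best <- rep$channel[which.max(rep$adj_r2)]  # which.max keeps first on ties
  structure(list(best = best, report = rep), class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("Channel selection by adjusted R2 -> best:", x$best, "\n")
  print(transform(x$report, adj_r2 = round(adj_r2, 4), r2 = round(r2, 4),
                  slope = signif(slope, 4)), row.names = FALSE)
  invisible(x)
}

#' Kinetic series of channel responses
#'
#' Channel readings on a (time x concentration) grid from a colour-development
#' kinetics run.
#'
#' @param times reading times in minutes, strictly increasing.
#' @param concs Cr(VI) concentrations in ppb.
#' @param responses numeric matrix, `length(times)` rows x `length(concs)`
#'   columns.
#' @return Object of class `kinetic_series`.
#' @export
kinetic_series <- function(times, concs, responses) {
  responses <- as.matrix(responses)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (!all(dim(responses) == c(length(times), length(concs))))
    stop("'responses' must be a length(times) x length(concs) matrix")
  if (!all(is.finite(responses))) stop("responses must be finite")
  structure(list(times = as.numeric(times), concs = as.numeric(concs),
                 responses = responses), class = "kinetic_series")
}

#' Select the reading time from a kinetics run
#'
#' For each time point, fits the response against concentration. Times whose
#' absolute slope is below `slope_floor_frac` of the largest absolute slope
#' are discarded as undeveloped (the early flat phase before the colour has
#' formed). Among the remaining times the earliest one attaining the maximal
#' adjusted R-squared is returned, so the assay reads as soon as the signal
#' is fully developed.
#'
#' @param series a [kinetic_series()] with at least 2 times and 3
#'   concentrations.
#' @param slope_floor_frac fraction of the maximal per-time `|slope|` below
#'   which a time is considered undeveloped (default 0.25).
#' @return Object of class `time_selection`: `best` (minutes) and `report`
#'   (time, slope, adj_r2, eligible).
#' @export
select_reading_time <- function(series, slope_floor_frac = 0.25) {
  stopifnot(inherits(series, "kinetic_series"))
  if (length(series$times) < 2L) stop("need >= 2 time points")
  if (length(unique(series$concs)) < 3L) stop("need >= 3 concentrations")
  span <- apply(series$responses, 1, function(r) diff(range(r)))
  if (max(span) <= 1e-9 * max(1, max(abs(series$responses))))
    stop("response is flat at every time point; incubate longer before reading")
  nt <- length(series$times)
  rep <- data.frame(time = series$times, slope = NA_real_, adj_r2 = NA_real_)
  for (i in seq_len(nt)) {
    f <- fit_calibration(series$concs, series$responses[i, ])
    rep$slope[i] <- f$slope; rep$adj_r2[i] <- f$adj_r2
  }
  smax <- max(abs(rep$slope))
  if (smax == 0)
    stop("response is flat at every time point; incubate longer before reading")
  rep$eligible <- abs(rep$slope) >= slope_floor_frac * smax
  el <- rep[rep$eligible, ]
  best <- el$time[which.max(el$adj_r2)]  # earliest on exact ties
  structure(list(best = best, report = rep), class = "time_selection")
}

#' @export
print.time_selection <- function(x, ...) {
  cat("Reading-time selection -> best:", x$best, "min\n")
  print(transform(x$report, slope = signif(slope, 4), adj_r2 = round(adj_r2, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Dose-response series for reagent optimization
#'
#' @param doses reagent concentrations in mM, strictly increasing.
#' @param responses absorbance at 650 nm (AU), same length.
#' @return Object of class `dose_response_series`.
#' @export
dose_response_series <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("doses and responses must match")
  if (any(diff(doses) <= 0)) stop("'doses' must be strictly increasing")
  if (!all(is.finite(responses))) stop("responses must be finite")
  structure(list(doses = as.numeric(doses), responses = as.numeric(responses)),
            class = "dose_response_series")
}

#' Smallest saturating reagent dose
#'
#' Finds the lowest reagent concentration at which the response has reached
#' its plateau. The responses are first monotone-smoothed by isotonic
#' regression (dose-response curves of a substrate-limited reaction are
#' non-decreasing); the optimum is the smallest dose whose smoothed response
#' is within `plateau_tol` (relative) of the maximum smoothed response --
#' monotonicity guarantees every larger dose then qualifies too. If only the
#' top dose qualifies the curve is still rising and the result is flagged
#' `"not_saturated"`.
#'
#' @param series a [dose_response_series()] with at least 4 doses.
#' @param plateau_tol relative tolerance defining the plateau (default 0.05).
#' @return Object of class `saturation`: `dose` (mM), `status`
#'   (`"saturated"` or `"not_saturated"`) and a per-dose `report`.
#' @export
saturation_dose <- function(series, plateau_tol = 0.05) {
  stopifnot(inherits(series, "dose_response_series"))
  n <- length(series$doses)
  if (n < 4L) stop("need >= 4 doses to judge saturation")
  if (plateau_tol <= 0 || plateau_tol >= 1) stop("'plateau_tol' must be in (0, 1)")
  sm <- stats::isoreg(series$doses, series$responses)$yf
  rmax <- max(sm)
  ok <- sm >= (1 - plateau_tol) * rmax
  i0 <- which(ok)[1]
  status <- if (i0 == n) "not_saturated" else "saturated"
  if (status == "not_saturated")
    warning("response still rising at the top dose; not saturated")
  structure(list(dose = series$doses[i0], status = status,
                 report = data.frame(dose = series$doses,
                                     response = series$responses,
                                     smoothed = sm, within_tol = ok)),
            class = "saturation")
}

#' @export
print.saturation <- function(x, ...) {
  cat(sprintf("Saturation analysis -> %s at %g mM\n", x$status, x$dose))
  invisible(x)
}
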