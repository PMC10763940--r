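#' Configuration for the synthetic plate generator
#'
#' Describes the simulated assay: a linear response-vs-concentration truth
#' per colour channel, two noise scales (between-well and per-pixel), the
#' concentration series, plate geometry, and the kinetic colour-development
#' curve. Defaults emulate the TMB-H2O2 Cr(VI) assay read on a flatbed
#' plate scanner: the red channel carries the calibration signal (slope
#' -0.06134 R-units/ppb, intercept 100.49757 at 0 ppb), the green and blue
#' channels are nearly flat with more noise, and colour development
#' saturates by 15 minutes.
#'
#' @param seed integer random seed (mandatory; every generator output is
#'   reproducible bit-for-bit under a fixed seed).
#' @param concs Cr(VI) standard concentrations in ppb.
#' @param replicates replicate wells per concentration for tabular response
#'   generation.
#' @param channels data frame with columns `channel`, `slope`, `intercept`,
#'   `well_sd` -- the per-channel truth and between-well noise SD
#'   (intensity units).
#' @param pixel_sd per-pixel Gaussian noise SD added on top of the well
#'   value (intensity units).
#' @param dpi rendering resolution of synthetic plate images.
#' @param background_rgb background intensity of the rendered plate.
#' @param times kinetic sampling times in minutes.
#' @param t_star colour-development saturation time in minutes: the
#'   development curve reaches 95% of its final level at `t_star`.
#' @param kinetic_hill Hill exponent of the development curve (larger =
#'   sharper onset; the early phase is visibly flat).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             concs = c(1, 25, 50, 75, 100, 200, 400, 600, 800, 1000),
                             replicates = 50L,
                             channels = data.frame(
                               channel = c("R", "G", "B"),
                               slope = c(-0.06134, -0.0030, -0.0015),
                               intercept = c(100.49757, 160, 190),
                               well_sd = c(0.5, 1.2, 1.8)),
                             pixel_sd = 2.0,
                             dpi = 150,
                             background_rgb = c(235, 235, 235),
                             times = seq(5, 25, by = 5),
                             t_star = 15,
                             kinetic_hill = 12) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a numeric 'seed' is mandatory")
  stopifnot(is.data.frame(channels),
            all(c("channel", "slope", "intercept", "well_sd") %in% names(channels)),
            all(c("R", "G", "B") %in% channels$channel))
  if (any(concs < 0)) stop("concentrations must be >= 0 ppb")
  structure(list(seed = as.integer(seed), concs = concs,
                 replicates = as.integer(replicates), channels = channels,
                 pixel_sd = pixel_sd, dpi = dpi,
                 background_rgb = background_rgb,
                 times = times, t_star = t_star, kinetic_hill = kinetic_hill,
                 # Costar-style 96-well geometry, millimetres
                 pitch_mm = 9, well_diameter_mm = 6.85,
                 a1_offset_mm = c(x = 14.38, y = 11.24),
                 plate_mm = c(w = 127.76, h = 85.47)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed %d, %d concentrations x %d replicates, %g dpi\n",
              x$seed, length(x$concs), x$replicates, x$dpi))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

channel_truth <- function(config, channel, conc) {
  row <- config$channels[config$channels$channel == channel, ]
  row$slope * conc + row$intercept
}

check_renderable <- function(config, concs) {
  for (ch in c("R", "G", "B")) {
    mu <- channel_truth(config, ch, concs)
    bad <- mu < 0 | mu > 255
    if (any(bad))
      stop("channel ", ch, " mean outside [0, 255] at concentration(s): ",
           paste(unique(concs[bad]), collapse = ", "), " ppb")
  }
  invisible(TRUE)
}

#' Generate a table of well responses with known truth
#'
#' Tabular (non-image) generation: each replicate well receives its
#' channel-truth mean plus between-well Gaussian noise. This is the fast
#' path for calibration studies where pixel-level rendering is irrelevant.
#'
#' @param config a [generator_config()].
#' @param concs,replicates override the config's concentration series or
#'   replicate count.
#' @return Data frame with `conc_ppb`, `mean_r`, `mean_g`, `mean_b`,
#'   `composite_rgb` (feature-table layout, usable by [select_channel()]).
#' @export
generate_well_responses <- function(config, concs = config$concs,
                                    replicates = config$replicates) {
  stopifnot(inherits(config, "generator_config"))
  check_renderable(config, concs)
  set.seed(config$seed)
  conc <- rep(concs, each = replicates)
  n <- length(conc)
  sd_of <- function(ch) config$channels$well_sd[config$channels$channel == ch]
  out <- data.frame(conc_ppb = conc,
                    mean_r = channel_truth(config, "R", conc) + stats::rnorm(n, 0, sd_of("R")),
                    mean_g = channel_truth(config, "G", conc) + stats::rnorm(n, 0, sd_of("G")),
                    mean_b = channel_truth(config, "B", conc) + stats::rnorm(n, 0, sd_of("B")))
  out$composite_rgb <- out$mean_r + out$mean_g + out$mean_b
  out
}

#' Default plate layout for a generated image
#'
#' Assigns the config's concentration series to wells row-major as
#' calibration standards, `replicates_per_plate` wells per concentration
#' (defaults to as many as fit on 96 wells).
#'
#' @param config a [generator_config()].
#' @param replicates_per_plate wells per concentration on the plate.
#' @return A [plate_layout] in the config's pixel geometry.
#' @export
default_plate_layout <- function(config,
                                 replicates_per_plate = 96L %/% length(config$concs)) {
  n_wells <- length(config$concs) * replicates_per_plate
  if (n_wells > 96L)
    stop("layout needs ", n_wells, " wells; a plate has 96")
  labels <- well_labels()[seq_len(n_wells)]
  wells <- data.frame(well = labels,
                      role = "standard",
                      conc_ppb = rep(config$concs, each = replicates_per_plate),
                      sample_id = NA_character_,
                      stringsAsFactors = FALSE)
  layout_from_config(config, wells)
}

#' Build a plate layout in a generator config's pixel geometry
#'
#' Converts the config's millimetre plate geometry to pixels at its dpi and
#' attaches the given well-assignment table.
#'
#' @param config a [generator_config()].
#' @param wells well-assignment data frame (see [plate_layout()]).
#' @return A [plate_layout].
#' @export
layout_from_config <- function(config, wells) {
  px_mm <- config$dpi / 25.4
  plate_layout(wells,
               origin_x = config$a1_offset_mm["x"] * px_mm,
               origin_y = config$a1_offset_mm["y"] * px_mm,
               pitch_px = config$pitch_mm * px_mm,
               well_radius_px = config$well_diameter_mm / 2 * px_mm)
}

#' Render a synthetic plate image with ground truth
#'
#' Draws each assigned well as a disk whose channel value is the linear
#' truth at the well's concentration plus between-well noise; per-pixel
#' Gaussian noise is added on top and intensities are clipped to
#' `[0, 255]`. The truth table records the exact pre-noise channel means and
#' the realized (post-well-noise, pre-pixel-noise) values, plus the true
#' well-centre coordinates.
#'
#' @param config a [generator_config()].
#' @param layout optional [plate_layout]; defaults to
#'   [default_plate_layout()]. Sample wells must carry a `conc_ppb` truth
#'   value to be rendered.
#' @return Object of class `synthetic_plate`: list with `image`
#'   ([plate_image]), `layout`, `truth` (data frame) and `config`.
#' @export
generate_plate_image <- function(config, layout = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(layout)) layout <- default_plate_layout(config)
  stopifnot(inherits(layout, "plate_layout"))
  wl <- layout$wells
  if (nrow(wl) > 96L) stop("at most 96 assigned wells")
  if (anyNA(wl$conc_ppb))
    stop("every assigned well needs a truth concentration to render")
  check_renderable(config, wl$conc_ppb)
  set.seed(config$seed)

  px_mm <- config$dpi / 25.4
  width <- as.integer(round(unname(config$plate_mm["w"]) * px_mm))
  height <- as.integer(round(unname(config$plate_mm["h"]) * px_mm))
  pix <- array(rep(config$background_rgb, each = width * height),
               c(height, width, 3))

  rc <- well_row_col(wl$well)
  cx <- unname(layout$origin_x + (rc[, "col"] - 1) * layout$pitch_px)
  cy <- unname(layout$origin_y + (rc[, "row"] - 1) * layout$pitch_px)
  r <- layout$well_radius_px

  truth <- data.frame(well = wl$well, conc_ppb = wl$conc_ppb,
                      cx = cx, cy = cy, stringsAsFactors = FALSE)
  for (ch in c("R", "G", "B"))
    truth[[paste0("true_", tolower(ch))]] <- channel_truth(config, ch, wl$conc_ppb)
  sds <- config$channels$well_sd[match(c("R", "G", "B"), config$channels$channel)]
  for (k in 1:3) {
    nm <- paste0("well_", c("r", "g", "b")[k])
    truth[[nm]] <- truth[[paste0("true_", c("r", "g", "b")[k])]] +
      stats::rnorm(nrow(wl), 0, sds[k])
  }

  plane_len <- as.numeric(height * width)
  for (i in seq_len(nrow(wl))) {
    px <- disk_pixels(cx[i], cy[i], r, height, width)
    npx <- nrow(px)
    lin <- (px[, "x"] - 1) * height + px[, "y"]
    for (k in 1:3) {
      v <- truth[[paste0("well_", c("r", "g", "b")[k])]][i]
      vals <- v + if (config$pixel_sd > 0) stats::rnorm(npx, 0, config$pixel_sd) else 0
      pix[lin + (k - 1) * plane_len] <- vals
    }
  }
  pix[pix < 0] <- 0
  pix[pix > 255] <- 255
  structure(list(image = plate_image(pix, dpi = config$dpi),
                 layout = layout, truth = truth, config = config),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %d wells, seed %d\n", nrow(x$truth), x$config$seed))
  print(x$image)
  invisible(x)
}

# colour-development fraction: Hill curve through 0 reaching 95% at t_star
development_fraction <- function(t, t_star, hill) {
  t50 <- t_star / 19^(1 / hill)   # f(t_star) = 0.95
  t^hill / (t50^hill + t^hill)
}

#' Generate a kinetic colour-development series
#'
#' Simulates the red-channel reading over time:
#' `response(t, X) = intercept + slope * X * f(t) + noise`, where `f` rises
#' monotonically from 0 to 1 and reaches 0.95 at the saturation time
#' `t_star`. Early times are visibly flat (undeveloped colour), so per-time
#' calibration slopes grow with `t`.
#'
#' @param config a [generator_config()]; uses its `times`, `t_star`,
#'   `kinetic_hill`, red-channel truth and well noise.
#' @return A [kinetic_series()] with attribute `t_star`.
#' @export
generate_kinetics <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  times <- config$times
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (config$t_star > max(times))
    stop("saturation time t_star lies beyond the time grid")
  set.seed(config$seed + 1L)
  row <- config$channels[config$channels$channel == "R", ]
  f <- development_fraction(times, config$t_star, config$kinetic_hill)
  mu <- outer(f, config$concs, function(fi, x) row$intercept + row$slope * x * fi)
  resp <- mu + stats::rnorm(length(mu), 0, row$well_sd)
  ks <- kinetic_series(times, config$concs, resp)
  attr(ks, "t_star") <- config$t_star
  ks
}

#' Generate a reagent dose-response series
#'
#' Saturating curves follow a Hill form
#' `r(d) = rmax * d^h / (k^h + d^h) + noise`; linear curves rise
#' proportionally to dose and never plateau. Two presets reproduce the
#' optimization series of the assay's reagents: `"tmb"` (0.1-1.5 mM,
#' absorbance envelope 0.0047-0.0685 AU, plateau from 0.9 mM) and `"h2o2"`
#' (10-300 mM, envelope 0.0243-0.1523 AU, plateau from 50 mM).
#'
#' @param kind `"saturating"` or `"linear"`.
#' @param preset optional `"tmb"` or `"h2o2"`; fills doses and curve
#'   parameters.
#' @param doses reagent concentrations in mM (strictly increasing).
#' @param rmax asymptotic (saturating) or top-dose (linear) response, AU.
#' @param k half-saturation dose in mM (saturating kind).
#' @param hill Hill exponent (saturating kind).
#' @param noise_sd absorbance noise SD in AU.
#' @param seed random seed.
#' @return A [dose_response_series()].
#' @export
generate_dose_response <- function(kind = c("saturating", "linear"),
                                   preset = NULL,
                                   doses = NULL, rmax = NULL, k = NULL,
                                   hill = 2, noise_sd = 1e-4, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tmb", "h2o2"))
    if (preset == "tmb") {
      doses <- seq(0.1, 1.5, by = 0.1); k <- 0.25; hill <- 2
      rmax <- 0.0685 / (1.5^2 / (0.25^2 + 1.5^2)); noise_sd <- 1e-4
    } else {
      doses <- c(10, 20, 30, 40, 50, 100, 150, 200, 250, 300); k <- 10; hill <- 2
      rmax <- 0.1523 / (300^2 / (10^2 + 300^2)); noise_sd <- 2e-4
    }
  }
  if (is.null(doses) || is.null(rmax))
    stop("supply 'doses' and 'rmax' (or a preset)")
  if (rmax <= 0 || (kind == "saturating" && (is.null(k) || k <= 0)))
    stop("curve parameters must be positive")
  set.seed(seed)
  mu <- if (kind == "saturating") rmax * doses^hill / (k^hill + doses^hill)
        else rmax * doses / max(doses)
  dose_response_series(doses, mu + stats::rnorm(length(doses), 0, noise_sd))
}
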