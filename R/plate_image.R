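#' In-memory plate image
#'
#' Wraps an RGB raster of a scanned 96-well plate. Channel values are kept as
#' numeric intensities on the 0--255 scale (8-bit sRGB as delivered by a
#' flatbed scanner); they are quantized to 8 bits only when written to disk,
#' so synthetic images can carry exact fractional well means. Pixel
#' coordinates follow image convention: origin at the top-left corner, x
#' increasing rightwards (columns), y increasing downwards (rows).
#'
#' @param pixels numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]` (channels ordered R, G, B).
#' @param dpi scan resolution in dots per inch (metadata only).
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, dpi = 600) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a height x width x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0)
    stop("'dpi' must be a positive number")
  structure(list(pixels = pixels,
                 width_px = dim(pixels)[2],
                 height_px = dim(pixels)[1],
                 dpi = dpi),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, %g dpi\n", x$width_px, x$height_px, x$dpi))
  invisible(x)
}

#' Read a plate image from PNG or TIFF
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param dpi resolution metadata to attach (files do not reliably carry it).
#' @return A [plate_image].
#' @export
read_plate_image <- function(path, dpi = 600) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  plate_image(img * 255, dpi = dpi)
}

#' Write a plate image to PNG or TIFF (8-bit)
#'
#' Channel values are divided by 255 and quantized to 8 bits per channel, so
#' a read-back reproduces intensities to within 0.5 units.
#'
#' @param image a [plate_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- image$pixels / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  invisible(path)
}

row_letters <- LETTERS[1:8]

#' Well labels of a 96-well plate in row-major order
#'
#' @param n_rows,n_cols plate dimensions (8 x 12 for a standard plate).
#' @return Character vector `A1, A2, ..., H12`.
#' @export
well_labels <- function(n_rows = 8L, n_cols = 12L) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

#' Plate layout: well assignments plus grid geometry
#'
#' Describes which wells hold blanks, calibration standards (with known
#' Cr(VI) concentration in ppb) or unknown samples, and where the well grid
#' sits in the image. The geometry is a deterministic template: the scanner
#' holds the plate in a fixed fixture, so well centres are taken from the
#' grid rather than detected.
#'
#' @param wells data frame with columns `well` (labels like "A1"), `role`
#'   (`"blank"`, `"standard"` or `"sample"`), `conc_ppb` (known concentration,
#'   required `>= 0` for standards, `NA` allowed otherwise) and `sample_id`
#'   (identifier for samples, `NA` otherwise).
#' @param origin_x,origin_y pixel coordinates of the centre of well A1.
#' @param pitch_px centre-to-centre well spacing in pixels (9 mm on a
#'   standard plate).
#' @param well_radius_px well radius in pixels.
#' @param n_rows,n_cols grid dimensions; 8 x 12 for a 96-well plate.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, origin_x, origin_y, pitch_px, well_radius_px,
                         n_rows = 8L, n_cols = 12L) {
  stopifnot(is.data.frame(wells))
  req <- c("well", "role", "conc_ppb", "sample_id")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  wells$well <- as.character(wells$well)
  wells$role <- as.character(wells$role)
  valid <- well_labels(n_rows, n_cols)
  bad <- setdiff(wells$well, valid)
  if (length(bad)) stop("invalid well label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(wells$well)) stop("duplicate well label(s) in layout")
  if (!all(wells$role %in% c("blank", "standard", "sample")))
    stop("role must be one of 'blank', 'standard', 'sample'")
  std <- wells$role == "standard"
  if (any(std & (is.na(wells$conc_ppb) | wells$conc_ppb < 0)))
    stop("standard wells need a concentration >= 0 ppb")
  if (pitch_px <= 0 || well_radius_px <= 0)
    stop("pitch_px and well_radius_px must be positive")
  structure(list(wells = wells, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 origin_x = origin_x, origin_y = origin_y,
                 pitch_px = pitch_px, well_radius_px = well_radius_px),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d grid, %d assigned wells (%d standards, %d samples, %d blanks)\n",
              x$n_rows, x$n_cols, nrow(x$wells),
              sum(x$wells$role == "standard"), sum(x$wells$role == "sample"),
              sum(x$wells$role == "blank")))
  cat(sprintf("  A1 centre (%.1f, %.1f) px, pitch %.1f px, well radius %.1f px\n",
              x$origin_x, x$origin_y, x$pitch_px, x$well_radius_px))
  invisible(x)
}

# grid position (row, col) of a well label like "B7"
well_row_col <- function(well) {
  row <- match(substr(well, 1, 1), LETTERS)
  col <- as.integer(substring(well, 2))
  cbind(row = row, col = col)
}

#' Locate well regions of interest on a plate image
#'
#' Places a disk-shaped ROI at every grid position of the layout. The ROI
#' radius is `roi_fraction` of the well radius: a central disk avoids the
#' meniscus shadow and edge shading at the well wall. Optionally the centre
#' of each well is refined within +/- 3 px by minimizing the luminance
#' variance inside the ROI (a well-centred disk sees uniform liquid; an
#' off-centre one mixes in background).
#'
#' @param image a [plate_image].
#' @param layout a [plate_layout] whose geometry must fit inside the image.
#' @param roi_fraction fraction of the well radius used for the ROI disk
#'   (default 0.6); must be in (0, 1].
#' @param refine logical; apply the +/- 3 px centroid refinement (default
#'   `FALSE` -- the template grid is exact for fixtured scanners).
#' @return An object of class `well_rois`: a list with a data frame of well
#'   centres and a list of per-well pixel index matrices (columns `y`, `x`).
#' @export
locate_wells <- function(image, layout, roi_fraction = 0.6, refine = FALSE) {
  stopifnot(inherits(image, "plate_image"), inherits(layout, "plate_layout"))
  if (!is.numeric(roi_fraction) || length(roi_fraction) != 1L || roi_fraction <= 0)
    stop("'roi_fraction' must be positive (got a degenerate ROI)")
  if (roi_fraction > 1) stop("'roi_fraction' cannot exceed 1")
  r_roi <- roi_fraction * layout$well_radius_px
  if (2 * r_roi > layout$pitch_px)
    stop("ROI disks of radius ", round(r_roi, 2), " px overlap at pitch ",
         layout$pitch_px, " px")
  labels <- well_labels(layout$n_rows, layout$n_cols)
  rc <- well_row_col(labels)
  cx <- layout$origin_x + (rc[, "col"] - 1) * layout$pitch_px
  cy <- layout$origin_y + (rc[, "row"] - 1) * layout$pitch_px
  pad <- if (refine) 3 else 0
  out <- cx - layout$well_radius_px - pad < 0.5 |
         cx + layout$well_radius_px + pad > image$width_px + 0.5 |
         cy - layout$well_radius_px - pad < 0.5 |
         cy + layout$well_radius_px + pad > image$height_px + 0.5
  if (any(out))
    stop("well(s) outside image bounds: ", paste(labels[out], collapse = ", "))

  lum <- NULL
  if (refine) lum <- (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3

  masks <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    if (refine) {
      # search at the full well radius: a shifted disk then samples background
      # across the well wall, which a roi_fraction-sized interior disk cannot see
      sh <- refine_centre(lum, cx[i], cy[i], layout$well_radius_px)
      cx[i] <- cx[i] + sh[1]
      cy[i] <- cy[i] + sh[2]
    }
    masks[[i]] <- disk_pixels(cx[i], cy[i], r_roi,
                              image$height_px, image$width_px)
    if (nrow(masks[[i]]) == 0L)
      stop("empty ROI for well ", labels[i])
  }
  structure(list(centres = data.frame(well = labels,
                                      row = rc[, "row"], col = rc[, "col"],
                                      cx = cx, cy = cy,
                                      r_roi = r_roi,
                                      stringsAsFactors = FALSE),
                 masks = stats::setNames(masks, labels),
                 roi_fraction = roi_fraction),
            class = "well_rois")
}

#' @export
print.well_rois <- function(x, ...) {
  npx <- vapply(x$masks, nrow, integer(1))
  cat(sprintf("<well_rois> %d ROIs, radius %.1f px, %d-%d px each\n",
              length(x$masks), x$centres$r_roi[1], min(npx), max(npx)))
  invisible(x)
}

# integer pixel coordinates inside a disk, clipped to the image
disk_pixels <- function(cx, cy, r, height, width) {
  xs <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

# pick the integer offset in [-3,3]^2 minimizing luminance variance in the ROI
refine_centre <- function(lum, cx, cy, r) {
  offs <- expand.grid(dx = -3:3, dy = -3:3)
  offs <- offs[order(offs$dx^2 + offs$dy^2, offs$dy, offs$dx), ]
  best <- c(0, 0); best_v <- Inf
  for (k in seq_len(nrow(offs))) {
    px <- disk_pixels(cx + offs$dx[k], cy + offs$dy[k], r,
                      nrow(lum), ncol(lum))
    v <- stats::var(lum[px])
    if (is.finite(v) && v < best_v - 1e-12) {
      best_v <- v
      best <- c(offs$dx[k], offs$dy[k])
    }
  }
  best
}

#' Reduce each well ROI to colour-channel statistics
#'
#' Computes, per well, the mean (or median) R, G and B intensity over the ROI
#' pixels and their sum (`composite_rgb`). The mean red value is the plate
#' imager's response variable ("UIIS index") used for calibration.
#'
#' @param image the [plate_image] the ROIs were located on.
#' @param rois a [well_rois] object from [locate_wells()].
#' @param stat `"mean"` (default, matching standard R-value usage) or
#'   `"median"` for robustness to specks.
#' @return A data frame of class `well_features` with columns `well`,
#'   `mean_r`, `mean_g`, `mean_b`, `composite_rgb`, `n_pixels`.
#' @export
extract_well_features <- function(image, rois, stat = c("mean", "median")) {
  stopifnot(inherits(image, "plate_image"), inherits(rois, "well_rois"))
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  ch <- function(k, px) f(image$pixels[, , k][px])
  n <- length(rois$masks)
  res <- data.frame(well = names(rois$masks),
                    mean_r = numeric(n), mean_g = numeric(n),
                    mean_b = numeric(n), composite_rgb = numeric(n),
                    n_pixels = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    px <- rois$masks[[i]]
    if (nrow(px) == 0L) stop("empty ROI for well ", res$well[i])
    res$mean_r[i] <- ch(1L, px)
    res$mean_g[i] <- ch(2L, px)
    res$mean_b[i] <- ch(3L, px)
    res$n_pixels[i] <- nrow(px)
  }
  res$composite_rgb <- res$mean_r + res$mean_g + res$mean_b
  class(res) <- c("well_features", "data.frame")
  res
}
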