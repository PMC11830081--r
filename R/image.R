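#' Pixel scale of the imaging setup
#'
#' The brightfield frames are 1536 x 1152 px covering 4.33 x 3.24 mm,
#' i.e. 354.7 px/mm (2.819 um/px); radial bins of 2 px are 5.64 um wide
#' and the 600-bin profile spans 1200 px = 3.38 mm.
#' @export
PX_PER_MM <- 1536 / 4.33

# rescale integer-typed or out-of-range images to [0, 1]
rescale_image <- function(im) {
  if (!all(is.finite(im))) stop("image must be finite")
  if (is.integer(im) || max(im) > 1) {
    dmax <- if (max(im) > 255) 65535 else 255
    im <- im / dmax
  }
  im
}

#' Estimate the spheroid center of mass in a grayscale image
#'
#' Pipeline: subtract the median intensity (background), Gaussian-smooth
#' with sigma = 4 px, binarize where the absolute deviation from the
#' median exceeds 0.08 (the object is darker than background in
#' brightfield, so the magnitude of the deviation is thresholded), find
#' connected components, drop objects smaller than 4000 px^2, and keep the
#' most rounded remaining object (minimum ellipse-fit eccentricity, ties
#' broken by larger area). The center is the mean of that object's row and
#' column indices.
#'
#' @param image Numeric matrix (rows x cols), at least 64 x 64; integer
#'   images are rescaled by their type maximum.
#' @param min_area Minimum object area in px^2 (default 4000).
#' @param threshold Binarization threshold on the smoothed absolute
#'   deviation (default 0.08).
#' @return Object of class `center_estimate`: `row`, `col` (fractional
#'   pixel coordinates), `n_objects_considered`, `selected_object_area`,
#'   `selected_object_eccentricity`.
#' @export
estimate_center <- function(image, min_area = 4000, threshold = 0.08) {
  stopifnot(is.matrix(image), nrow(image) >= 64, ncol(image) >= 64)
  im <- rescale_image(image)
  dev <- abs(im - stats::median(im))
  # EBImage uses (x, y) = (col, row) ordering
  sm <- EBImage::gblur(EBImage::Image(t(dev)), sigma = 4)
  bw <- sm > threshold
  lab <- EBImage::bwlabel(bw)
  n_all <- max(lab)
  if (n_all == 0) stop("no spheroid found: binarized image is empty")
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shp[, "s.area"]
  ecc <- mom[, "m.eccentricity"]
  keep <- which(area >= min_area)
  if (length(keep) == 0) stop("no spheroid found: all objects below min_area")
  # most rounded object; ties on eccentricity broken by larger area
  sel <- keep[order(ecc[keep], -area[keep])][1]
  labm <- t(EBImage::imageData(lab)) # back to rows x cols
  idx <- which(labm == sel, arr.ind = TRUE)
  structure(list(row = mean(idx[, 1]), col = mean(idx[, 2]),
                 n_objects_considered = length(keep),
                 selected_object_area = unname(area[sel]),
                 selected_object_eccentricity = unname(ecc[sel])),
            class = "center_estimate")
}

#' @export
print.center_estimate <- function(x, ...) {
  cat(sprintf("<center_estimate> (row, col) = (%.2f, %.2f); area %d px^2, eccentricity %.3f (%d candidates)\n",
              x$row, x$col, x$selected_object_area,
              x$selected_object_eccentricity, x$n_objects_considered))
  invisible(x)
}

#' Radial cell-density profile of a spheroid image
#'
#' Inverts the intensity (1 - image), bins every pixel by its distance to
#' the center into 600 annuli of 2 px, and averages per bin. The spheroid
#' boundary bin i* is the first bin beyond bin 100 where the first
#' difference of the 201-bin moving average (window truncated at the
#' array edges) changes from negative to positive; the profile is held
#' constant from i* outward and the boundary value is subtracted so the
#' surrounding region has density 0.
#'
#' @param image Numeric matrix (rows x cols).
#' @param center A [estimate_center()] result, or a length-2 numeric
#'   `(row, col)`.
#' @param n_bins Number of annuli (default 600).
#' @param bin_px Annulus width in pixels (default 2).
#' @param px_per_mm Pixel scale (default [PX_PER_MM]).
#' @param ma_halfwidth Moving-average half-window in bins (default 100).
#' @return Object of class `radial_profile`: `bin_centers_px`,
#'   `bin_centers_mm`, `y` (mean inverted intensity per bin), `y_avg`
#'   (moving average), `boundary_bin`, `y_subtracted`, `px_per_mm`.
#' @export
radial_density_profile <- function(image, center, n_bins = 600, bin_px = 2,
                                   px_per_mm = PX_PER_MM,
                                   ma_halfwidth = 100) {
  stopifnot(is.matrix(image))
  if (inherits(center, "center_estimate")) center <- c(center$row, center$col)
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image)) {
    stop("center must lie inside the image")
  }
  inv <- 1 - rescale_image(image)
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  bin <- floor(d / bin_px) + 1L
  mask <- bin <= n_bins
  cnt <- tabulate(bin[mask], nbins = n_bins)
  tot <- numeric(n_bins)
  sums <- rowsum(inv[mask], bin[mask])
  tot[as.integer(rownames(sums))] <- sums
  y <- ifelse(cnt > 0, tot / cnt, NA_real_)
  # truncated moving average, NA-aware
  y_avg <- vapply(seq_len(n_bins), function(i) {
    w <- y[max(1, i - ma_halfwidth):min(n_bins, i + ma_halfwidth)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  d1 <- diff(y_avg)
  last_data <- max(which(is.finite(y))) # bins past the image corners are empty
  istar <- NA_integer_
  for (i in (ma_halfwidth + 1):min(n_bins - 1, last_data - 1)) {
    if (!is.na(d1[i - 1]) && !is.na(d1[i]) && d1[i - 1] < 0 && d1[i] > 0) {
      istar <- i
      break
    }
  }
  if (is.na(istar)) {
    istar <- last_data
    warning("no derivative sign change found; boundary set to the last bin")
  }
  y_flat <- y
  y_flat[seq(istar, n_bins)] <- y[istar]
  y_sub <- y_flat - y[istar]
  y_sub[is.na(y_sub)] <- 0
  bin_centers_px <- (seq_len(n_bins) - 0.5) * bin_px
  structure(list(bin_centers_px = bin_centers_px,
                 bin_centers_mm = bin_centers_px / px_per_mm,
                 y = y, y_avg = y_avg, boundary_bin = istar,
                 y_subtracted = y_sub, px_per_mm = px_per_mm),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins (%.3g mm span); boundary bin %d (%.3g mm)\n",
              length(x$y), max(x$bin_centers_mm), x$boundary_bin,
              x$bin_centers_mm[x$boundary_bin]))
  invisible(x)
}

#' Full image-to-profile conversion
#'
#' Convenience wrapper: [estimate_center()] then
#' [radial_density_profile()].
#'
#' @inheritParams radial_density_profile
#' @return A `radial_profile` with the `center_estimate` attached as
#'   attribute `center`.
#' @export
image_to_profile <- function(image, px_per_mm = PX_PER_MM) {
  ctr <- estimate_center(image)
  prof <- radial_density_profile(image, ctr, px_per_mm = px_per_mm)
  attr(prof, "center") <- ctr
  prof
}
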