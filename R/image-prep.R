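#' Estimate the cell's major axis from a binary mask
#'
#' Principal-axis estimate from the second central moments of the mask: the
#' returned angle is that of the eigenvector with the larger eigenvalue, in
#' degrees counterclockwise from the image row direction, wrapped to
#' (-90, 90].
#'
#' @param mask logical or 0/1 matrix.
#' @return angle in degrees.
#' @export
estimate_major_axis <- function(mask) {
  if (!is.matrix(mask)) stopf("'mask' must be a matrix")
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("empty mask: no major axis")
  x <- idx[, 2]; y <- idx[, 1]          # x along columns, y along rows
  mxx <- mean((x - mean(x))^2)
  myy <- mean((y - mean(y))^2)
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  gap <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  if (gap <= 1e-9 * (mxx + myy + 1e-12))
    stopf("isotropic mask: principal axes are degenerate")
  wrap_angle(0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
}

## Otsu threshold over a plain numeric vector (between-class variance
## maximization on a 256-bin histogram); EBImage's otsu() operates on whole
## [0,1] images, whereas here the histogram must be restricted to the ROI.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0)
    stopf("cannot compute an Otsu threshold on a constant region")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Preprocess a micrograph into a binary TAT mask
#'
#' The raw-image chain: rolling-ball style background subtraction
#' (grayscale opening with a disc of `background_radius`, subtracted from
#' the image), Gaussian smoothing, thresholding (Otsu computed within the
#' ROI, or a fixed predefined threshold), then restriction to the ROI minus
#' nuclei minus a border strip of width `exclude_margin` (the surface
#' sarcolemma).  All parameters are physical (nm/um) and are converted by
#' `pixel_size`, so the same settings apply to STED (16.23 nm) and confocal
#' (114 nm) data.
#'
#' With `smooth_sigma = 0` and a fixed threshold of 0.5 the chain is
#' idempotent on an already-binary image whose structures are thinner than
#' the rolling-ball diameter.
#'
#' @param image numeric matrix of counts.
#' @param roi a [cell_roi()] congruent with `image`.
#' @param params a [preprocess_params()].
#' @param pixel_size pixel size in nm.
#' @return logical matrix (the binary TAT mask), with attributes
#'   `threshold` (counts) and `analysis_mask` (ROI minus nuclei and margin,
#'   the region over which network area metrics are defined).
#' @export
preprocess <- function(image, roi, params = preprocess_params(),
                       pixel_size = 16.23) {
  stopifnot(inherits(roi, "cell_roi"), inherits(params, "preprocess_params"))
  if (!is.matrix(image) || !all(dim(image) == dim(roi$mask)))
    stopf("image and ROI mask must be congruent matrices")
  check_scalar(pixel_size, "pixel_size", 0, strict_lower = TRUE)

  work <- image
  ## background: subtract a grayscale opening (disc radius in px)
  r_px <- params$background_radius / pixel_size
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * floor(r_px) + 1L, shape = "disc")
    bg <- EBImage::opening(EBImage::as.Image(work), brush)
    work <- pmax(work - as.matrix(EBImage::imageData(bg)), 0)
  }
  sig_px <- params$smooth_sigma / pixel_size
  if (sig_px > 0) {
    work <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::as.Image(work), sigma = sig_px)))
  }

  analysis <- roi$mask
  for (n in roi$nucleus_masks) analysis <- analysis & !n
  m_px <- params$exclude_margin * 1000 / pixel_size
  if (m_px >= 1) {
    brush <- EBImage::makeBrush(2L * floor(m_px) + 1L, shape = "disc")
    core <- EBImage::erode(EBImage::as.Image(roi$mask * 1), brush)
    analysis <- analysis & (as.matrix(EBImage::imageData(core)) > 0)
  }

  thr <- if (params$threshold_mode == "fixed") {
    if (params$fixed_threshold < min(image) ||
        params$fixed_threshold > max(image))
      stopf("fixed threshold %g outside the image dynamic range [%g, %g]",
            params$fixed_threshold, min(image), max(image))
    params$fixed_threshold
  } else {
    vals <- work[analysis]
    if (length(vals) == 0L) stopf("empty analysis region")
    otsu_threshold(vals)
  }

  out <- (work > thr) & analysis
  attr(out, "threshold") <- thr
  attr(out, "analysis_mask") <- analysis
  out
}
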