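#' Extract a cross-tubule intensity profile
#'
#' Samples a rotated rectangular ROI (default 50 x 30 px, the STED tubule
#' sizing window): the profile axis is perpendicular to the tubule, and
#' intensities are averaged over the 30-px dimension running along the
#' tubule.  Sampling uses bilinear interpolation at sub-pixel positions.
#'
#' @param image numeric matrix of counts.
#' @param roi_center `c(row, col)` center of the ROI, 1-based pixels
#'   (fractional allowed).
#' @param roi_axis_angle tubule orientation in degrees (counterclockwise
#'   from the row direction); the profile runs perpendicular to it.
#' @param length_px,width_px profile length (across the tubule) and
#'   averaging width (along it), in pixels.
#' @param pixel_size pixel size in nm.
#' @return an object of class `intensity_profile`: data.frame-like list with
#'   `positions_nm` (0-based pixel index x pixel size) and `intensities`.
#' @export
extract_profile <- function(image, roi_center, roi_axis_angle,
                            length_px = 50, width_px = 30,
                            pixel_size = 16.23) {
  if (!is.matrix(image)) stopf("'image' must be a matrix")
  check_scalar(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  a <- roi_axis_angle * pi / 180
  u_along <- c(sin(a), cos(a))   # (drow, dcol) along the tubule
  u_perp <- c(cos(a), -sin(a))   # across it
  i_off <- seq_len(length_px) - (length_px + 1) / 2
  j_off <- seq_len(width_px) - (width_px + 1) / 2
  rows <- roi_center[1] + outer(i_off * u_perp[1], j_off * u_along[1], "+")
  cols <- roi_center[2] + outer(i_off * u_perp[2], j_off * u_along[2], "+")
  if (min(rows) < 1 || max(rows) > nrow(image) ||
      min(cols) < 1 || max(cols) > ncol(image))
    stopf("profile ROI extends outside the image")
  vals <- bilinear_sample(image, rows, cols)
  structure(list(
    positions_nm = (seq_len(length_px) - 1) * pixel_size,
    intensities = rowMeans(vals),
    pixel_size = pixel_size
  ), class = "intensity_profile")
}

## bilinear interpolation at (possibly fractional) row/col matrices
bilinear_sample <- function(image, rows, cols) {
  r0 <- pmin(pmax(floor(rows), 1), nrow(image) - 1)
  c0 <- pmin(pmax(floor(cols), 1), ncol(image) - 1)
  fr <- as.vector(rows - r0); fc <- as.vector(cols - c0)
  r0 <- as.vector(r0); c0 <- as.vector(c0)
  v <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
    fr * (1 - fc) * image[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * image[cbind(r0, c0 + 1)] +
    fr * fc * image[cbind(r0 + 1, c0 + 1)]
  matrix(v, nrow(rows), ncol(rows))
}

#' Fit a one- or two-peak Gaussian to an intensity profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `C + sum_j A_j exp(-(x - m_j)^2 / (2 s_j^2))` with data-driven
#' initialization: peaks are picked as the highest local maxima of a
#' sigma = 1 px smoothed copy (ties broken leftmost).  For a single peak the
#' FWHM is `2 sqrt(2 log 2) * sigma`; for two peaks it is the width of the
#' fitted envelope between its outermost half-maximum crossings (see
#' [tubule_width()]).  Fits that do not converge, or whose sigma collapses
#' below a quarter pixel, are flagged as failed rather than returned
#' silently.
#'
#' @param profile an `intensity_profile` (or list with `positions_nm` and
#'   `intensities`).
#' @param n_peaks 1 or 2.
#' @return an object of class `gaussian_fit`: `ok`, `n_peaks`, `baseline`,
#'   `peaks` (data.frame `amplitude`, `center_nm`, `sigma_nm`), `fwhm_nm`,
#'   `peak_separation_nm` (2-peak), `residual_rms`.
#' @export
fit_gaussian <- function(profile, n_peaks = 1) {
  x <- profile$positions_nm
  y <- profile$intensities
  if (!n_peaks %in% c(1, 2)) stopf("n_peaks must be 1 or 2")
  if (length(x) < 5 * n_peaks)
    stopf("profile too short: need >= %d samples", 5 * n_peaks)
  px <- if (length(x) > 1) x[2] - x[1] else 1
  failed <- function(msg) structure(
    list(ok = FALSE, n_peaks = n_peaks, message = msg,
         baseline = NA_real_, peaks = NULL, fwhm_nm = NA_real_,
         peak_separation_nm = NA_real_, residual_rms = NA_real_),
    class = "gaussian_fit")

  ## initialization from the smoothed profile
  k <- stats::dnorm(-3:3)
  ys <- as.numeric(stats::filter(c(rep(y[1], 3), y, rep(y[length(y)], 3)),
                                 k / sum(k), sides = 2))[4:(length(y) + 3)]
  base0 <- min(ys)
  locmax <- which(diff(sign(diff(c(-Inf, ys, -Inf)))) < 0)
  ## keep only prominent maxima (>= 20% of the full excursion above the
  ## floor); the rest are baseline ripple or edge artifacts
  locmax <- locmax[ys[locmax] - base0 >= 0.2 * (max(ys) - base0)]
  if (!length(locmax)) return(failed("no local maximum in profile"))
  ord <- locmax[order(-ys[locmax], locmax)]  # highest first, ties leftmost
  pk <- ord[seq_len(min(n_peaks, length(ord)))]
  plateau <- length(pk) < n_peaks
  if (plateau) {
    ## a single broad/flat-topped maximum: seed the two peaks at the edges
    ## of the 60%-of-max plateau instead of on top of each other
    lvl <- base0 + 0.6 * (ys[pk[1]] - base0)
    above <- which(ys >= lvl)
    pk <- c(above[1], above[length(above)])
    if (diff(pk) < 2) pk <- c(max(pk[1] - 1, 1), min(pk[2] + 1, length(ys)))
  }
  pk <- sort(pk)
  sig0 <- if (plateau) max((x[pk[2]] - x[pk[1]]) / 4, px)
          else max(init_sigma(x, ys, pk[1], base0), px)
  amp0 <- if (plateau) rep(0.8 * (max(ys) - base0), 2)
          else pmax(ys[pk] - base0, 1e-6)

  df <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (n_peaks == 1) {
      minpack.lm::nlsLM(
        y ~ C + A1 * exp(-(x - m1)^2 / (2 * s1^2)), data = df,
        start = list(C = base0, A1 = amp0[1],
                     m1 = x[pk[1]], s1 = sig0),
        lower = c(-Inf, 0, min(x), px / 100),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ C + A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
          A2 * exp(-(x - m2)^2 / (2 * s2^2)), data = df,
        start = list(C = base0,
                     A1 = amp0[1], m1 = x[pk[1]], s1 = sig0,
                     A2 = amp0[2], m2 = x[pk[2]], s2 = sig0),
        lower = c(-Inf, 0, min(x), px / 100, 0, min(x), px / 100),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  sig <- abs(cf[grep("^s", names(cf))])
  if (any(sig < px / 4))
    return(failed("fitted sigma below pixel_size/4: unresolved peak"))
  peaks <- data.frame(
    amplitude = unname(cf[grep("^A", names(cf))]),
    center_nm = unname(cf[grep("^m", names(cf))]),
    sigma_nm = unname(sig))
  peaks <- peaks[order(peaks$center_nm), , drop = FALSE]
  out <- structure(list(
    ok = TRUE, n_peaks = n_peaks, message = "converged",
    baseline = unname(cf[["C"]]), peaks = peaks,
    fwhm_nm = NA_real_,
    peak_separation_nm = if (n_peaks == 2)
      diff(peaks$center_nm) else NA_real_,
    residual_rms = sqrt(mean(stats::resid(fit)^2))
  ), class = "gaussian_fit")
  out$fwhm_nm <- if (n_peaks == 1) FWHM_PER_SIGMA * peaks$sigma_nm[1]
                 else envelope_fwhm(out)
  out
}

## crude sigma init: half-width at half max of the smoothed peak
init_sigma <- function(x, ys, pk, base) {
  half <- base + (ys[pk] - base) / 2
  r <- pk; while (r < length(ys) && ys[r] > half) r <- r + 1
  l <- pk; while (l > 1 && ys[l] > half) l <- l - 1
  (x[r] - x[l]) / 2 / 1.1774  # HWHM -> sigma
}

## evaluate the fitted model on arbitrary positions
predict_gaussian <- function(fit, x) {
  y <- rep(fit$baseline, length(x))
  for (i in seq_len(nrow(fit$peaks)))
    y <- y + fit$peaks$amplitude[i] *
      exp(-(x - fit$peaks$center_nm[i])^2 / (2 * fit$peaks$sigma_nm[i]^2))
  y
}

## outer half-maximum width of the fitted (possibly two-peak) model:
## the distance between the outermost crossings of
## baseline + (max - baseline)/2, found by root bracketing on a fine grid
envelope_fwhm <- function(fit) {
  lo <- min(fit$peaks$center_nm) - 8 * max(fit$peaks$sigma_nm)
  hi <- max(fit$peaks$center_nm) + 8 * max(fit$peaks$sigma_nm)
  xg <- seq(lo, hi, length.out = 4096)
  yg <- predict_gaussian(fit, xg)
  ymax <- max(yg)
  half <- fit$baseline + (ymax - fit$baseline) / 2
  above <- yg > half
  if (!any(above) || all(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  f <- function(x) predict_gaussian(fit, x) - half
  left <- if (i1 > 1)
    stats::uniroot(f, c(xg[i1 - 1], xg[i1]), tol = 1e-9)$root else xg[i1]
  right <- if (i2 < length(xg))
    stats::uniroot(f, c(xg[i2], xg[i2 + 1]), tol = 1e-9)$root else xg[i2]
  right - left
}

#' Tubule width (FWHM) from a Gaussian profile fit
#'
#' For a single-peak fit the width is the Gaussian FWHM
#' `2 sqrt(2 log 2) * sigma`.  For a two-peak fit (the two membrane walls of
#' a resolved tubule) it is the distance between the outermost half-maximum
#' crossings of the fitted two-peak-plus-baseline model, the dashed-line
#' reading of a wall-to-wall width; the peak-to-peak separation is also
#' available on the fit object.
#'
#' @param fit a converged `gaussian_fit`.
#' @return width in nm.
#' @export
tubule_width <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!isTRUE(fit$ok)) stopf("cannot take a width from a failed fit: %s",
                             fit$message)
  w <- fit$fwhm_nm
  if (!is.finite(w))
    stopf("fitted model never reaches half maximum (pathological baseline)")
  w
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("Gaussian fit FAILED: %s\n", x$message))
    return(invisible(x))
  }
  cat(sprintf("%d-peak Gaussian fit (residual RMS %.3g)\n", x$n_peaks,
              x$residual_rms))
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("  peak %d: A = %.3g, center = %.1f nm, sigma = %.1f nm\n",
                i, x$peaks$amplitude[i], x$peaks$center_nm[i],
                x$peaks$sigma_nm[i]))
  cat(sprintf("  baseline %.3g; FWHM %.1f nm", x$baseline, x$fwhm_nm))
  if (x$n_peaks == 2)
    cat(sprintf(" (peak separation %.1f nm)", x$peak_separation_nm))
  cat("\n")
  invisible(x)
}

#' @export
plot.gaussian_fit <- function(x, profile = NULL, ...) {
  if (!isTRUE(x$ok)) stopf("nothing to plot: fit failed")
  lo <- min(x$peaks$center_nm) - 6 * max(x$peaks$sigma_nm)
  hi <- max(x$peaks$center_nm) + 6 * max(x$peaks$sigma_nm)
  xg <- seq(lo, hi, length.out = 512)
  if (!is.null(profile)) {
    plot(profile$positions_nm, profile$intensities, pch = 16, cex = 0.6,
         xlab = "position (nm)", ylab = "intensity (counts)", ...)
    graphics::lines(xg, predict_gaussian(x, xg), col = "red", lwd = 2)
  } else {
    plot(xg, predict_gaussian(x, xg), type = "l", col = "red", lwd = 2,
         xlab = "position (nm)", ylab = "intensity (counts)", ...)
  }
  invisible(x)
}
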