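#' Render synthetic tubule geometry through a Gaussian-PSF microscope
#'
#' Each segment is a ribbon of its physical width; a finite rectangle
#' convolved with an isotropic Gaussian PSF factorizes exactly in the
#' ribbon's own frame into a product of error-function differences, which is
#' evaluated per pixel (no discretization of the convolution itself).  The
#' summed field is scaled so its maximum equals `tubule_peak_signal` above
#' `background_level`, then Poisson shot noise, Gaussian read noise and
#' quantization to `bit_depth` are applied in that order.
#'
#' @param segs a `tat_segments` object from [generate_network_geometry()].
#' @param imaging an [imaging_spec()].
#' @param fov optional field of view `c(width_um, height_um)`; must contain
#'   the cell.  Default: cell bounding box plus a margin.
#' @param pad margin (um) around the cell bounding box when `fov` is NULL.
#' @return an object of class `tat_image`: list with `image` (matrix of
#'   counts, rows = image rows), `truth_mask` (logical, pre-PSF ribbon
#'   footprint), `pixel_size` (nm), `origin` (um, position of the (1,1)
#'   pixel's corner), `imaging`, and the geometry `truth` carried over.
#' @export
render_image <- function(segs, imaging, fov = NULL, pad = 0.5) {
  stopifnot(inherits(segs, "tat_segments"), inherits(imaging, "imaging_spec"))
  pp <- imaging$pixel_size / 1000              # um per pixel
  sigma <- imaging$psf_fwhm / 1000 / FWHM_PER_SIGMA
  poly <- segs$cell_polygon
  bbox_w <- diff(range(poly[, 1])); bbox_h <- diff(range(poly[, 2]))
  if (is.null(fov)) {
    fov <- c(bbox_w, bbox_h) + 2 * pad
    origin <- c(min(poly[, 1]), min(poly[, 2])) - pad
  } else {
    if (fov[1] < bbox_w || fov[2] < bbox_h)
      stopf("field of view (%.1f x %.1f um) smaller than the cell (%.1f x %.1f um)",
            fov[1], fov[2], bbox_w, bbox_h)
    origin <- c(mean(range(poly[, 1])), mean(range(poly[, 2]))) - fov / 2
  }
  nc <- ceiling(fov[1] / pp); nr <- ceiling(fov[2] / pp)
  xs <- origin[1] + (seq_len(nc) - 0.5) * pp
  ys <- origin[2] + (seq_len(nr) - 0.5) * pp

  field <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  seg <- segs$segments
  for (i in seq_len(nrow(seg))) {
    p0 <- c(seg$x0[i], seg$y0[i]); p1 <- c(seg$x1[i], seg$y1[i])
    L <- seg$length_um[i]
    if (L <= 0) next
    d <- (p1 - p0) / L
    w2 <- seg$width_nm[i] / 2000                # half width, um
    r <- w2 + 4 * sigma + pp
    ci <- which(xs >= min(p0[1], p1[1]) - r & xs <= max(p0[1], p1[1]) + r)
    ri <- which(ys >= min(p0[2], p1[2]) - r & ys <= max(p0[2], p1[2]) + r)
    if (!length(ci) || !length(ri)) next
    gx <- outer(rep(1, length(ri)), xs[ci]) - p0[1]
    gy <- outer(ys[ri], rep(1, length(ci))) - p0[2]
    u <- gx * d[1] + gy * d[2]
    v <- -gx * d[2] + gy * d[1]
    if (sigma > 0) {
      f <- (stats::pnorm(u / sigma) - stats::pnorm((u - L) / sigma)) *
        (stats::pnorm((v + w2) / sigma) - stats::pnorm((v - w2) / sigma))
    } else {
      f <- (u >= 0 & u <= L & abs(v) <= w2) * 1
    }
    field[ri, ci] <- field[ri, ci] + f
    mask[ri, ci] <- mask[ri, ci] | (u >= 0 & u <= L & abs(v) <= w2)
  }

  ## scale so the ridge of a representative (median-width) long tubule
  ## reaches tubule_peak_signal; overlaps may exceed it, as in real data,
  ## up to the quantization ceiling
  f_ref <- if (nrow(seg) == 0) 1 else {
    w2_ref <- stats::median(seg$width_nm) / 2000
    if (sigma > 0) 2 * stats::pnorm(w2_ref / sigma) - 1 else 1
  }
  img <- imaging$background_level +
    imaging$tubule_peak_signal * field / f_ref

  img <- with_seed(imaging$seed, {
    out <- img
    if (imaging$shot_noise)
      out <- matrix(stats::rpois(length(out), lambda = out),
                    nrow(out), ncol(out))
    if (imaging$read_noise_sd > 0)
      out <- out + stats::rnorm(length(out), 0, imaging$read_noise_sd)
    out
  })
  img <- round(img)
  img[img < 0] <- 0
  maxval <- 2^imaging$bit_depth - 1
  img[img > maxval] <- maxval

  structure(list(image = img, truth_mask = mask,
                 pixel_size = imaging$pixel_size, origin = origin,
                 imaging = imaging, truth = segs$truth,
                 cell_polygon = segs$cell_polygon),
            class = "tat_image")
}

#' @export
print.tat_image <- function(x, ...) {
  cat(sprintf("Synthetic micrograph: %d x %d px at %.2f nm/px (%.1f x %.1f um)\n",
              nrow(x$image), ncol(x$image), x$pixel_size,
              ncol(x$image) * x$pixel_size / 1000,
              nrow(x$image) * x$pixel_size / 1000))
  cat(sprintf("  counts: background %.0f, range [%.0f, %.0f]\n",
              x$imaging$background_level, min(x$image), max(x$image)))
  invisible(x)
}

#' Pixel mask of the cell interior for a rendered image
#'
#' Rasterizes the cell polygon of a rendered synthetic image into a logical
#' matrix congruent with the image, for use as [cell_roi()] mask.
#'
#' @param img a `tat_image`.
#' @return logical matrix.
#' @export
cell_mask_from_image <- function(img) {
  stopifnot(inherits(img, "tat_image"))
  pp <- img$pixel_size / 1000
  nr <- nrow(img$image); nc <- ncol(img$image)
  xs <- img$origin[1] + (seq_len(nc) - 0.5) * pp
  ys <- img$origin[2] + (seq_len(nr) - 0.5) * pp
  poly <- img$cell_polygon
  ## point-in-convex-polygon: same side of every edge
  inside <- matrix(TRUE, nr, nc)
  n <- nrow(poly)
  gx <- outer(rep(1, nr), xs)
  gy <- outer(ys, rep(1, nc))
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    inside <- inside & (ex * (gy - poly[i, 2]) - ey * (gx - poly[i, 1]) >= 0)
  }
  inside
}
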