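test_that("empty geometry renders a constant background", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 5, cell_width = 3), seed = 1)
  segs$segments <- segs$segments[0, ]
  im <- render_image(segs, imaging_spec(pixel_size = 114, psf_fwhm = 250,
                                        background_level = 37,
                                        shot_noise = FALSE,
                                        read_noise_sd = 0))
  expect_true(all(im$image == 37))
  expect_false(any(im$truth_mask))
})

test_that("noiseless cross-profile matches the numerical convolution oracle", {
  r <- render_single_tubule(250, psf_fwhm = 60, pixel = 16.23)
  prof <- r$profile
  y <- prof$intensities - min(prof$intensities)
  ## oracle profile on a dense grid, sampled at the same positions
  sig <- 60 / (2 * sqrt(2 * log(2)))
  xg <- seq(-1000, 1000, by = 1)
  ribbon <- as.numeric(abs(xg) <= 125)
  k <- stats::dnorm(seq(-5 * sig, 5 * sig, by = 1), sd = sig)
  og <- as.numeric(stats::filter(ribbon, k / sum(k), sides = 2))
  ## compare shapes after peak normalization, centering on the half-max
  ## midpoint (the plateau top is flat, so the arg-max is not a center)
  ## and allowing a sub-pixel alignment shift
  above <- range(prof$positions_nm[y > max(y) / 2])
  ctr <- mean(above)
  best <- Inf
  for (shift in seq(-20, 20, by = 0.5)) {
    oy <- stats::approx(xg, og, xout = prof$positions_nm - ctr + shift,
                        rule = 2)$y
    best <- min(best, max(abs(y / max(y) - oy / max(oy, na.rm = TRUE)),
                          na.rm = TRUE))
  }
  expect_lt(best, 0.02)
})

test_that("shot noise has Poisson variance on a uniform background", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 20, cell_width = 10), seed = 1)
  segs$segments <- segs$segments[0, ]
  im <- render_image(segs, imaging_spec(pixel_size = 114, psf_fwhm = 0,
                                        background_level = 100,
                                        shot_noise = TRUE,
                                        read_noise_sd = 0, seed = 9))
  v <- as.numeric(im$image)
  n <- length(v)
  expect_gt(n, 1e4)
  ## variance/mean ratio ~ 1 within a generous CI (quantization adds a bit)
  expect_lt(abs(stats::var(v) / mean(v) - 1), 3 * sqrt(2 / n) + 0.02)
})

test_that("rendering is deterministic and FOV errors are explicit", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 6, cell_width = 4), seed = 2)
  ispec <- imaging_spec(pixel_size = 114, psf_fwhm = 250, seed = 21)
  a <- render_image(segs, ispec)
  b <- render_image(segs, ispec)
  expect_identical(a$image, b$image)
  c <- render_image(segs, imaging_spec(pixel_size = 114, psf_fwhm = 250,
                                       seed = 22))
  expect_false(identical(a$image, c$image))
  expect_error(render_image(segs, ispec, fov = c(2, 2)), "field of view")
})

test_that("the truth mask covers the ribbon footprint", {
  r <- render_single_tubule(300, psf_fwhm = 60, pixel = 16.23)
  im <- r$image
  ## mask pixels must be bright in the noiseless image (above background)
  expect_true(all(im$image[im$truth_mask] >
                  im$imaging$background_level + 1))
})
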