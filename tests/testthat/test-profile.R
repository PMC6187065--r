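test_that("profile extraction averages across the tubule axis", {
  img <- matrix(42, 80, 80)
  prof <- extract_profile(img, c(40, 40), 0)
  expect_length(prof$positions_nm, 50)
  expect_equal(diff(prof$positions_nm)[1], 16.23)
  expect_true(all(abs(prof$intensities - 42) < 1e-9))
  expect_error(extract_profile(img, c(3, 3), 0), "outside")
})

test_that("averaging over 30 pixels reduces noise by about sqrt(30)", {
  sds <- vapply(1:50, function(s) {
    img <- tatnet:::with_seed(s, matrix(stats::rnorm(150 * 150, 100, 10),
                                        150, 150))
    prof <- extract_profile(img, c(75.5, 75.5), 0)
    stats::sd(prof$intensities)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 10 / sqrt(30)) / (10 / sqrt(30)), 0.2)
})

test_that("FWHM identity holds to 1e-6 and reproduces the 90 nm scale", {
  x <- seq(0, 49) * 16.23
  y <- 5 + 40 * exp(-(x - 400)^2 / (2 * 38.2^2))
  f <- fit_gaussian(list(positions_nm = x, intensities = y), 1)
  expect_true(f$ok)
  expect_equal(f$fwhm_nm / f$peaks$sigma_nm, 2 * sqrt(2 * log(2)),
               tolerance = 1e-6)
  expect_equal(f$fwhm_nm, 2 * sqrt(2 * log(2)) * 38.2, tolerance = 1e-4)
  expect_lt(abs(f$fwhm_nm - 90), 0.1)
})

test_that("two coincident peaks reduce to the single-peak width", {
  x <- seq(0, 49) * 16.23
  y <- 5 + 20 * exp(-(x - 400)^2 / (2 * 50^2)) +
    20 * exp(-(x - 400)^2 / (2 * 50^2))
  f2 <- fit_gaussian(list(positions_nm = x, intensities = y), 2)
  f1 <- fit_gaussian(list(positions_nm = x, intensities = y), 1)
  expect_true(f2$ok && f1$ok)
  expect_lt(abs(tubule_width(f2) - tubule_width(f1)) / tubule_width(f1),
            0.01)
})

test_that("sigma is recovered within 5% bias at SNR 10", {
  est <- vapply(1:30, function(s) {
    x <- seq(0, 49) * 16.23
    y0 <- 10 + 50 * exp(-(x - 400)^2 / (2 * 60^2))
    y <- tatnet:::with_seed(s, y0 + stats::rnorm(length(x), 0, 5))
    f <- fit_gaussian(list(positions_nm = x, intensities = y), 1)
    if (f$ok) f$peaks$sigma_nm else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 60) / 60, 0.05)
})

test_that("width is invariant to affine intensity transforms", {
  r <- render_single_tubule(250)
  p <- r$profile
  w0 <- tubule_width(fit_gaussian(p, 2))
  p2 <- p; p2$intensities <- 3.7 * p$intensities + 55
  w1 <- tubule_width(fit_gaussian(p2, 2))
  expect_equal(w0, w1, tolerance = 1e-6)
})

test_that("estimated width respects the resolution floor", {
  ## even a very thin tubule cannot appear narrower than the PSF
  r <- render_single_tubule(150, psf_fwhm = 60)
  w <- tubule_width(fit_gaussian(r$profile, 2))
  expect_gte(w, 60)
})

test_that("unresolvable fits are flagged, not silently returned", {
  x <- seq(0, 49) * 16.23
  y <- tatnet:::with_seed(1, stats::rnorm(50, 100, 1))  # featureless
  f <- fit_gaussian(list(positions_nm = x, intensities = y), 2)
  if (f$ok) succeed() else expect_error(tubule_width(f), "failed")
  ## sub-quarter-pixel spike collapses sigma and must be rejected
  y2 <- rep(10, 50); y2[25] <- 200
  f2 <- fit_gaussian(list(positions_nm = x, intensities = y2), 1)
  expect_false(f2$ok && f2$peaks$sigma_nm[1] < 16.23 / 4)
})

test_that("symmetric two-peak widths are symmetric about the midpoint", {
  x <- seq(0, 49) * 16.23
  y <- 5 + 30 * exp(-(x - 300)^2 / (2 * 45^2)) +
    30 * exp(-(x - 500)^2 / (2 * 45^2))
  f <- fit_gaussian(list(positions_nm = x, intensities = y), 2)
  expect_true(f$ok)
  expect_equal(mean(f$peaks$center_nm), 400, tolerance = 1)
  expect_equal(f$peak_separation_nm, 200, tolerance = 2)
  w <- tubule_width(f)
  ## envelope width symmetric: crossings equidistant from 400
  xg <- seq(100, 700, by = 0.5)
  yg <- tatnet:::predict_gaussian(f, xg)
  half <- f$baseline + (max(yg) - f$baseline) / 2
  above <- range(xg[yg > half])
  expect_equal(400 - above[1], above[2] - 400, tolerance = 1)
  expect_equal(w, diff(above), tolerance = 2)
})
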