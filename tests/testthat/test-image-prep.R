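test_that("major-axis estimate matches symmetry and closed form", {
  ## axis-aligned rectangle
  m <- matrix(FALSE, 60, 220); m[10:49, 11:210] <- TRUE
  expect_equal(estimate_major_axis(m), 0, tolerance = 1e-9)
  ## rotated rectangle
  for (a in c(30, -50, 75))
    expect_equal(estimate_major_axis(mask_rot_rect(a)), a, tolerance = 0.5)
  ## ellipse with known covariance: angle = 0.5 atan2(2 mxy, mxx - myy)
  n <- 201; ctr <- 101
  xs <- outer(rep(1, n), seq_len(n)) - ctr
  ys <- outer(seq_len(n), rep(1, n)) - ctr
  a <- 20 * pi / 180
  u <- xs * cos(a) + ys * sin(a); v <- -xs * sin(a) + ys * cos(a)
  ell <- (u / 80)^2 + (v / 25)^2 <= 1
  expect_equal(estimate_major_axis(ell), 20, tolerance = 0.5)
})

test_that("degenerate masks raise explicit errors", {
  expect_error(estimate_major_axis(matrix(FALSE, 10, 10)), "empty")
  sq <- matrix(FALSE, 41, 41); sq[11:31, 11:31] <- TRUE
  expect_error(estimate_major_axis(sq), "isotropic")
})

test_that("fixed-threshold binarization recovers a noiseless two-level image", {
  img <- matrix(10, 40, 40)
  bright <- matrix(FALSE, 40, 40); bright[15:25, 5:35] <- TRUE
  img[bright] <- 100
  roi <- cell_roi(matrix(TRUE, 40, 40))
  p <- preprocess_params(smooth_sigma = 0, background_radius = 1e6,
                         threshold_mode = "fixed", fixed_threshold = 50,
                         exclude_margin = 0)
  ## huge rolling-ball radius disables the opening (brush > image)
  p$background_radius <- 0.5  # sub-pixel: skips background subtraction
  mask <- preprocess(img, roi, p, pixel_size = 100)
  expect_identical(unname(mask[, ] > 0), bright)
})

test_that("otsu on a constant region errors; fixed threshold is range-checked", {
  img <- matrix(5, 30, 30)
  roi <- cell_roi(matrix(TRUE, 30, 30))
  p <- preprocess_params(smooth_sigma = 0, background_radius = 0.5,
                         exclude_margin = 0)
  expect_error(preprocess(img, roi, p, pixel_size = 100), "constant|Otsu")
  pf <- preprocess_params(smooth_sigma = 0, background_radius = 0.5,
                          threshold_mode = "fixed", fixed_threshold = 999,
                          exclude_margin = 0)
  expect_error(preprocess(img, roi, pf, pixel_size = 100), "dynamic range")
})

test_that("binarization is idempotent on binary input at threshold 0.5", {
  bin <- matrix(0, 30, 30)
  bin[15, 5:25] <- 1; bin[5:25, 10] <- 1
  roi <- cell_roi(matrix(TRUE, 30, 30))
  p <- preprocess_params(smooth_sigma = 0, background_radius = 300,
                         threshold_mode = "fixed", fixed_threshold = 0.5,
                         exclude_margin = 0)
  mask <- preprocess(bin, roi, p, pixel_size = 100)
  expect_identical(unname(mask[, ] > 0), bin > 0.5)
})

test_that("raising the fixed threshold never adds mask pixels", {
  img <- tatnet:::with_seed(4, matrix(stats::runif(900, 0, 100), 30, 30))
  roi <- cell_roi(matrix(TRUE, 30, 30))
  masks <- lapply(c(20, 40, 60), function(th)
    preprocess(img, roi,
               preprocess_params(smooth_sigma = 0, background_radius = 0.5,
                                 threshold_mode = "fixed",
                                 fixed_threshold = th, exclude_margin = 0),
               pixel_size = 100))
  expect_true(all(masks[[2]][masks[[3]]]))
  expect_true(all(masks[[1]][masks[[2]]]))
})

test_that("mask respects ROI, nuclei and the border exclusion strip", {
  img <- matrix(0, 60, 60)
  cellm <- matrix(FALSE, 60, 60); cellm[10:50, 10:50] <- TRUE
  img[cellm] <- 100
  nuc <- matrix(FALSE, 60, 60); nuc[25:35, 25:35] <- TRUE
  roi <- cell_roi(cellm, list(nuc))
  p <- preprocess_params(smooth_sigma = 0, background_radius = 0.5,
                         threshold_mode = "fixed", fixed_threshold = 50,
                         exclude_margin = 0.5)
  mask <- preprocess(img, roi, p, pixel_size = 100)  # 0.5 um = 5 px margin
  expect_true(all(cellm[mask]))
  expect_false(any(mask & nuc))
  ## border strip removed: pixels at the ROI edge are excluded
  expect_false(any(mask[10, ]))
  expect_false(any(mask[, 10]))
  expect_true(any(mask[20, 20]))
})

test_that("physical parameters give matching masks at STED and confocal scales", {
  ## same two-level physical pattern sampled at 114 nm and 28.5 nm
  make <- function(px_nm) {
    n <- round(4000 / px_nm)
    img <- matrix(10, n, n)
    ## band defined in physical coordinates (1.6-2.4 um)
    ctr_um <- (seq_len(n) - 0.5) * px_nm / 1000
    img[ctr_um >= 1.6 & ctr_um <= 2.4, ] <- 100
    roi <- cell_roi(matrix(TRUE, n, n))
    p <- preprocess_params(smooth_sigma = 0, background_radius = 10,
                           threshold_mode = "fixed", fixed_threshold = 50,
                           exclude_margin = 0)
    mask <- preprocess(img, roi, p, pixel_size = px_nm)
    sum(mask) * (px_nm / 1000)^2  # masked area in um2
  }
  a1 <- make(114); a2 <- make(28.5)
  expect_lt(abs(a1 - a2) / a2, 0.05)
})
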