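test_that("single-orientation skeletons concentrate in the right bin", {
  ## horizontal ribbon, reference 0: all mass in the bin containing 0
  h <- orientation_histogram(skeletonize(mask_ribbon(0), 100),
                             reference_angle = 0)
  peak <- h$bins[which.max(h$bins$length_um), ]
  expect_true(peak$bin_lo <= 0 && peak$bin_hi >= 0)
  expect_gt(peak$length_um / sum(h$bins$length_um), 0.9)
  ## 45-degree ribbon: mass within one bin of 45
  h45 <- orientation_histogram(skeletonize(mask_ribbon(45), 100),
                               reference_angle = 0)
  mid <- h45$bins$bin_mid[which.max(h45$bins$length_um)]
  expect_lt(abs(mid - 45), 7.5)
})

test_that("bin masses sum to the total skeleton length", {
  g <- build_graph(skeletonize(mask_grid(), 100))
  h <- orientation_histogram(g, reference_angle = 0)
  expect_equal(sum(h$bins$length_um), g$total_length_um, tolerance = 1e-9)
  expect_error(orientation_histogram(skeletonize(matrix(FALSE, 5, 5), 100)),
               "empty")
})

test_that("a 70:30 mixture of orientations recovers its mass ratio", {
  ## two disjoint ribbons: horizontal 70 px, vertical 30 px
  M <- matrix(FALSE, 100, 100)
  M[20, 11:80] <- TRUE   # 70 px at 0 deg
  M[41:70, 60] <- TRUE   # 30 px at 90 deg
  h <- orientation_histogram(skeletonize(M, 100), reference_angle = 0)
  cs <- classify_components(h, roi_area = 100)
  fr <- cs$components$relative_fraction
  expect_equal(fr[1], 0.7, tolerance = 0.03)
  expect_equal(fr[3], 0.3, tolerance = 0.03)
})

test_that("pure components classify to single fractions", {
  h0 <- orientation_histogram(skeletonize(mask_ribbon(0), 100), 0)
  c0 <- classify_components(h0, 50)
  expect_equal(c0$components$relative_fraction,
               c(1, 0, 0), tolerance = 1e-9)
  h90 <- orientation_histogram(skeletonize(mask_ribbon(90), 100), 0)
  c90 <- classify_components(h90, 50)
  expect_equal(c90$components$relative_fraction[3], 1, tolerance = 1e-9)
})

test_that("classified plus unclassified mass is conserved", {
  g <- build_graph(skeletonize(mask_ribbon(22), 100))
  h <- orientation_histogram(g, reference_angle = 0)
  ## strict 5-degree windows leave a 22-degree ribbon unclassified
  cs <- classify_components(h, 50, window = 5)
  expect_gt(cs$unclassified_fraction, 0.5)
  tot <- sum(cs$components$length_um) +
    cs$unclassified_fraction * cs$total_length_um
  expect_equal(tot, cs$total_length_um, tolerance = 1e-9)
  ## exhaustive window classifies everything
  cs2 <- classify_components(h, 50, window = 22.5)
  expect_equal(cs2$unclassified_fraction, 0, tolerance = 1e-9)
})

test_that("rotating image and reference together leaves the summary fixed", {
  M <- mask_ribbon(30)
  h1 <- orientation_histogram(skeletonize(M, 100), reference_angle = 10)
  c1 <- classify_components(h1, 50)
  ## rotate the mask by +90 deg (transpose + flip) and the reference too
  M90 <- t(M)[, rev(seq_len(nrow(M)))]
  # mapping takes orientation theta -> theta + 90
  h2 <- orientation_histogram(skeletonize(M90, 100),
                              reference_angle = tatnet:::wrap_angle(100))
  c2 <- classify_components(h2, 50)
  expect_equal(c1$components$relative_fraction,
               c2$components$relative_fraction, tolerance = 0.06)
})

test_that("absolute densities never exceed the overall density", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 10, cell_width = 6), seed = 4)
  im <- render_image(segs, imaging_spec(pixel_size = 32.46, psf_fwhm = 60,
                                        seed = 5))
  roi <- cell_roi(cell_mask_from_image(im))
  na <- analyze_network(im$image, roi, 32.46)
  expect_true(all(na$components$components$absolute_density <=
                  na$metrics$density + 1e-9))
  expect_equal(sum(na$components$components$relative_fraction), 1,
               tolerance = 1e-9)
})
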