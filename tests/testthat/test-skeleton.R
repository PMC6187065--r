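test_that("a one-pixel line is a fixed point of thinning", {
  M <- mask_line(20)
  sk <- skeletonize(M, 16.23)
  expect_identical(sk$pixels, M)
})

test_that("a wide bar thins to a single centerline of matching length", {
  M <- matrix(FALSE, 15, 60)
  M[6:10, 5:55] <- TRUE  # 5 px wide, 51 px long
  sk <- skeletonize(M, 16.23)
  g <- build_graph(sk, prune_spurs_px = 0)
  expect_equal(g$n_junctions, 0)
  expect_equal(nrow(g$branches), 1)
  ## centerline length within ~width of the bar length (tip erosion)
  expect_lt(abs(g$branches$length_px - 50), 6)
  ## and within 1 px once tip erosion is compensated
  g2 <- build_graph(sk, prune_spurs_px = 0, tip_extension = TRUE)
  expect_lt(abs(g2$branches$length_px - 50), 2)
})

test_that("no thinned mask contains a fully occupied 2x2 block", {
  for (s in 1:8) {
    P <- skeletonize(random_blob_mask(s), 100)$pixels
    blocks <- P[-nrow(P), -ncol(P)] & P[-1, -ncol(P)] &
      P[-nrow(P), -1] & P[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("empty mask yields an empty skeleton, not an error", {
  sk <- skeletonize(matrix(FALSE, 10, 10), 100)
  expect_false(any(sk$pixels))
  g <- build_graph(sk)
  expect_equal(g$total_length_um, 0)
  expect_equal(nrow(g$branches), 0)
})

test_that("straight 100-px line gives one branch of 99 steps", {
  M <- matrix(FALSE, 9, 104)
  M[5, 3:102] <- TRUE
  g <- build_graph(skeletonize(M, 16.23), prune_spurs_px = 0)
  expect_equal(g$n_junctions, 0)
  expect_equal(g$n_endpoints, 2)
  expect_equal(nrow(g$branches), 1)
  expect_equal(g$branches$length_um, 99 * 16.23 / 1000, tolerance = 1e-9)
})

test_that("plus-sign skeleton has one junction and four branches", {
  g <- build_graph(skeletonize(mask_plus(), 16.23), prune_spurs_px = 0)
  expect_equal(g$n_junctions, 1)
  expect_equal(nrow(g$branches), 4)
  expect_equal(g$n_endpoints, 4)
})

test_that("an isolated pixel is a degenerate node with no branches", {
  M <- matrix(FALSE, 7, 7); M[4, 4] <- TRUE
  g <- build_graph(skeletonize(M, 16.23))
  expect_equal(nrow(g$branches), 0)
  expect_equal(g$total_length_um, 0)
  expect_identical(g$nodes$type, "isolated")
})

test_that("graph decomposition equals the brute-force oracle on fixtures", {
  fixtures <- list(mask_line(), mask_L(), mask_plus(), mask_grid())
  for (M in fixtures) {
    sk <- skeletonize(M, 16.23)
    for (prune in c(0, 2)) {
      g <- build_graph(sk, prune_spurs_px = prune)
      o <- oracle_graph(sk$pixels, 16.23, prune_px = prune)
      expect_identical(g$n_junctions, o$n_junctions)
      expect_identical(nrow(g$branches), o$n_branches)
      expect_equal(g$total_length_um, o$total_length_um, tolerance = 1e-9)
      expect_identical(g$n_endpoints, o$n_endpoints)
    }
  }
})

test_that("graph decomposition equals the oracle on random thinned blobs", {
  for (s in 1:15) {
    sk <- skeletonize(random_blob_mask(s), 100)
    g <- build_graph(sk, prune_spurs_px = 2)
    o <- oracle_graph(sk$pixels, 100, prune_px = 2)
    expect_identical(g$n_junctions, o$n_junctions)
    expect_identical(nrow(g$branches), o$n_branches)
    expect_equal(g$total_length_um, o$total_length_um, tolerance = 1e-9)
  }
})

test_that("network metrics scale correctly with ROI area", {
  M <- matrix(FALSE, 9, 104); M[5, 3:102] <- TRUE
  g <- build_graph(skeletonize(M, 16.23), prune_spurs_px = 0)
  m1 <- network_metrics(g, 100)
  m2 <- network_metrics(g, 200)
  expect_equal(m1$density, 99 * 16.23 / 1000 / 100, tolerance = 1e-9)
  expect_equal(m1$junction_density, 0)
  expect_equal(m2$density, m1$density / 2, tolerance = 1e-12)
  expect_error(network_metrics(g, 0), "roi_area")
})
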