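test_that("degenerate pure-axial mixture yields exactly parallel segments", {
  for (axis in c(0, 30)) {
    spec <- network_spec(cell_length = 12, cell_width = 6,
                         axis_angle = axis, frac_at = 1, frac_ot = 0,
                         frac_tt = 0, angle_jitter_sd = 0,
                         junction_rate = 0)
    segs <- generate_network_geometry(spec, seed = 11)
    s <- segs$segments
    ang <- atan2(s$y1 - s$y0, s$x1 - s$x0) * 180 / pi
    dev <- abs(tatnet:::wrap_angle(ang - axis))
    expect_lt(max(dev), 1e-6)
  }
})

test_that("truth totals equal independent recomputation from the geometry", {
  for (seed in c(1, 7, 19)) {
    segs <- generate_network_geometry(
      network_spec(cell_length = 15, cell_width = 8), seed = seed)
    s <- segs$segments
    len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
    expect_equal(segs$truth$total_length, sum(len), tolerance = 1e-12)
    for (k in c("AT", "OT", "TT"))
      expect_equal(segs$truth$length_by_component[[k]],
                   sum(len[s$component == k]), tolerance = 1e-12)
    expect_equal(segs$truth$density,
                 sum(len) / segs$cell_area, tolerance = 1e-12)
    ## junction truth equals the enumerated crossing/T points
    expect_equal(segs$truth$junction_count, nrow(junction_points(segs)))
  }
})

test_that("realized length fractions track the spec over 20 seeds", {
  target <- c(0.60, 0.25, 0.15)
  fr <- vapply(1:20, function(s) {
    segs <- generate_network_geometry(
      network_spec(cell_length = 15, cell_width = 8, frac_at = target[1],
                   frac_ot = target[2], frac_tt = target[3]), seed = s)
    segs$truth$length_fractions
  }, numeric(3))
  expect_lt(max(abs(rowMeans(fr) - target)), 0.03)
})

test_that("geometry generation is deterministic in the seed", {
  spec <- network_spec(cell_length = 10, cell_width = 6)
  a <- generate_network_geometry(spec, seed = 5)
  b <- generate_network_geometry(spec, seed = 5)
  c <- generate_network_geometry(spec, seed = 6)
  expect_identical(a$segments, b$segments)
  expect_false(identical(a$segments, c$segments))
})

test_that("infeasible density raises an explicit error", {
  expect_error(generate_network_geometry(
    network_spec(cell_length = 500, cell_width = 500,
                 target_density = 50, segment_length_mean = 0.05),
    seed = 1), "infeasible")
})

test_that("segments stay inside the cell polygon", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 12, cell_width = 6, axis_angle = 25),
    seed = 3)
  poly <- segs$cell_polygon
  ctr <- colMeans(poly)
  inside <- function(x, y) {
    ok <- TRUE
    for (i in 1:4) {
      j <- i %% 4 + 1
      ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
      side <- ex * (y - poly[i, 2]) - ey * (x - poly[i, 1])
      ref <- ex * (ctr[2] - poly[i, 2]) - ey * (ctr[1] - poly[i, 1])
      ok <- ok && (sign(side) == sign(ref) || abs(side) < 1e-6)
    }
    ok
  }
  s <- segs$segments
  for (i in seq_len(nrow(s))) {
    expect_true(inside(s$x0[i], s$y0[i]))
    expect_true(inside(s$x1[i], s$y1[i]))
  }
})

test_that("region-restricted truth is conserved against the full mask", {
  segs <- generate_network_geometry(
    network_spec(cell_length = 10, cell_width = 6), seed = 2)
  ## a mask covering everything reproduces the full truth
  full <- matrix(TRUE, 400, 500)
  tr <- segment_truth_in_mask(segs, full, c(0, 0), 32.46)
  expect_equal(tr$length_um, segs$truth$total_length, tolerance = 1e-6)
  expect_equal(tr$junction_count, segs$truth$junction_count)
})
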