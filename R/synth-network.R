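## Synthetic TAT network geometry.
##
## Coordinates are in micrometers: x runs along image columns, y along image
## rows, angles counterclockwise from the row (x) direction in (-90, 90].
## The cell is a rotated rectangle; segments are straight tubules placed
## uniformly inside it with component-specific orientations, clipped at the
## cell border (tubules ending at the sarcolemma).

CANONICAL_ANGLES <- c(AT = 0, OT = 45, TT = 90)

#' Generate ground-truthed synthetic TAT network geometry
#'
#' Draws straight tubule segments inside a rotated rectangular cell until the
#' target network density is reached.  Each segment gets a component label
#' (AT/OT/TT) drawn with the spec's fractions, an orientation at the
#' component's canonical angle relative to the cell axis (0/45/90 deg, with
#' oblique tubules at either +45 or -45) plus Gaussian jitter, and a physical
#' width.  T-junctions are additionally seeded at `junction_rate` per um2 by
#' growing branch segments from points on existing tubules.  The returned
#' truth block records realized per-component lengths, density, and the
#' expected junction count (seeded T-junctions plus chance crossings).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed; output is deterministic given `spec` and `seed`.
#' @return an object of class `tat_segments`: list with `segments`
#'   (data.frame `x0, y0, x1, y1, component, width_nm, length_um`),
#'   `cell_polygon` (4x2 matrix, um), `cell_area` (um2), and `truth`.
#' @export
generate_network_geometry <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  hl <- spec$cell_length / 2
  hw <- spec$cell_width / 2
  area <- spec$cell_length * spec$cell_width
  a <- spec$axis_angle * pi / 180
  u <- c(cos(a), sin(a))   # along the major axis
  v <- c(-sin(a), cos(a))  # across

  target_total <- spec$target_density * area
  exp_t_len <- spec$junction_rate * area * spec$segment_length_mean / 2
  target_main <- max(target_total - exp_t_len, 0.25 * target_total)
  if (target_total / spec$segment_length_mean > 2e5)
    stopf("infeasible density: ~%.0f segments required for this cell",
          target_total / spec$segment_length_mean)

  ## clip a line through local point m with local direction d to the
  ## rectangle; returns reach (t>0 and t<0 limits)
  reach <- function(m, d) {
    lim <- function(h, mi, di) {
      if (abs(di) < 1e-12) return(c(Inf, Inf))
      ts <- sort(c((h - mi) / di, (-h - mi) / di))
      c(-ts[1], ts[2]) # (backward reach, forward reach), both >= 0
    }
    lu <- lim(hl, m[1], d[1]); lv <- lim(hw, m[2], d[2])
    c(min(lu[1], lv[1]), min(lu[2], lv[2]))
  }

  fracs <- c(AT = spec$frac_at, OT = spec$frac_ot, TT = spec$frac_tt)
  widths <- c(AT = spec$tubule_width_at,
              OT = (spec$tubule_width_at + spec$tubule_width_tt) / 2,
              TT = spec$tubule_width_tt)

  ## volume exclusion: tubules are distinct membrane structures, so a
  ## candidate running near-parallel to an existing segment closer than one
  ## tubule width would fuse with it in any rendered image; such candidates
  ## are redrawn
  par_tol <- 25
  too_close <- function(seg, p0, p1, th_local, width_um, skip = 0L) {
    for (ii in seq_along(seg)) {
      if (ii == skip) next
      s <- seg[[ii]]
      if (abs(wrap_angle(th_local - s$th)) > par_tol) next
      gap <- (width_um + s$w) / 2
      if (seg_seg_dist(p0, p1, s$p0, s$p1) < gap) return(TRUE)
    }
    FALSE
  }

  res <- with_seed(seed, {
    ## quota (deficit-greedy) component assignment: the next segment takes
    ## the component whose realized length share trails its target most,
    ## keeping realized fractions tight to the spec at any network size
    len_by <- c(AT = 0, OT = 0, TT = 0)
    draw_comp <- function() {
      tot <- sum(len_by)
      share <- if (tot > 0) len_by / tot else fracs * 0
      names(fracs)[which.max(fracs - share)]
    }
    draw_angle_local <- function(comp) {
      base <- CANONICAL_ANGLES[[comp]]
      if (comp == "OT") base <- base * sample(c(-1, 1), 1L)
      base + stats::rnorm(1L, 0, spec$angle_jitter_sd)
    }
    seg <- list()
    total <- 0
    i <- 0L
    while (total < target_main) {
      i <- i + 1L
      if (i > 5e5) stopf("infeasible density: segment budget exhausted")
      comp <- draw_comp()
      th_local <- draw_angle_local(comp)
      len <- max(0.05, stats::rnorm(1L, spec$segment_length_mean,
                                    spec$segment_length_sd))
      m <- c(stats::runif(1L, -hl, hl), stats::runif(1L, -hw, hw))
      d <- c(cos(th_local * pi / 180), sin(th_local * pi / 180))
      rc <- reach(m, d)
      t_b <- min(len / 2, rc[1]); t_f <- min(len / 2, rc[2])
      if (t_b + t_f < 0.05) next
      p0 <- m - t_b * d; p1 <- m + t_f * d
      w_um <- widths[[comp]] / 1000
      if (i < 2e5 && too_close(seg, p0, p1, th_local, w_um)) next
      seg[[length(seg) + 1L]] <- list(p0 = p0, p1 = p1, comp = comp,
                                      th = th_local, w = w_um,
                                      seeded = FALSE)
      total <- total + t_b + t_f
      len_by[comp] <- len_by[comp] + t_b + t_f
    }
    n_main <- length(seg)
    n_t <- stats::rpois(1L, spec$junction_rate * area)
    n_t <- min(n_t, n_main) # need a parent per T-junction
    t_parents <- if (n_t > 0) sample.int(n_main, n_t, replace = TRUE)
                 else integer(0)
    ## a seeded junction is only a junction if it is resolvable: the
    ## attachment point must sit clear of the parent's ends and the child
    ## branch must be long enough to survive as a distinct tubule
    end_clear <- 0.4   # um from the parent's ends
    min_branch <- 0.6  # um child length
    for (j in seq_len(n_t)) {
      pid <- t_parents[j]
      par <- seg[[pid]]
      par_len <- sqrt(sum((par$p1 - par$p0)^2))
      if (par_len < 2 * end_clear + 0.1) next
      for (try in 1:20) {
        tt <- stats::runif(1L, end_clear / par_len, 1 - end_clear / par_len)
        m <- par$p0 + tt * (par$p1 - par$p0)
        comp <- draw_comp()
        th_local <- draw_angle_local(comp)
        ## a branch leaving its parent at a shallow angle is not an
        ## optically resolvable junction; require a clear angle
        if (abs(wrap_angle(th_local - par$th)) < 40) next
        d <- c(cos(th_local * pi / 180), sin(th_local * pi / 180))
        if (stats::runif(1L) < 0.5) d <- -d
        len <- max(min_branch, stats::rnorm(1L, spec$segment_length_mean / 2,
                                            spec$segment_length_sd / 2))
        t_f <- min(len, reach(m, d)[2])
        if (t_f < min_branch) next
        w_um <- widths[[comp]] / 1000
        p1 <- m + t_f * d
        if (too_close(seg, m, p1, th_local, w_um, skip = pid)) next
        seg[[length(seg) + 1L]] <- list(p0 = m, p1 = p1, comp = comp,
                                        th = th_local, w = w_um,
                                        seeded = TRUE)
        len_by[comp] <- len_by[comp] + t_f
        break
      }
    }
    seg
  })

  ## local -> global coordinates (cell centered so its bounding box starts
  ## at a 1 um margin)
  to_global <- function(p) p[1] * u + p[2] * v
  pts0 <- t(vapply(res, function(s) to_global(s$p0), numeric(2)))
  pts1 <- t(vapply(res, function(s) to_global(s$p1), numeric(2)))
  corners_local <- rbind(c(-hl, -hw), c(hl, -hw), c(hl, hw), c(-hl, hw))
  poly <- t(apply(corners_local, 1L, to_global))
  margin <- 1
  off <- c(margin - min(poly[, 1]), margin - min(poly[, 2]))
  poly <- sweep(poly, 2L, off, "+")
  pts0 <- sweep(pts0, 2L, off, "+")
  pts1 <- sweep(pts1, 2L, off, "+")
  colnames(poly) <- c("x", "y")

  comp <- vapply(res, function(s) s$comp, character(1))
  segments <- data.frame(
    x0 = pts0[, 1], y0 = pts0[, 2], x1 = pts1[, 1], y1 = pts1[, 2],
    component = comp,
    width_nm = unname(widths[comp]),
    seeded_junction = vapply(res, function(s) s$seeded, logical(1)),
    stringsAsFactors = FALSE
  )
  segments$length_um <- sqrt((segments$x1 - segments$x0)^2 +
                             (segments$y1 - segments$y0)^2)

  n_cross <- count_crossings(segments)
  n_seeded <- sum(segments$seeded_junction)
  len_by_comp <- vapply(c("AT", "OT", "TT"), function(k)
    sum(segments$length_um[segments$component == k]), numeric(1))
  truth <- list(
    total_length = sum(segments$length_um),
    length_by_component = len_by_comp,
    length_fractions = len_by_comp / sum(segments$length_um),
    density = sum(segments$length_um) / area,
    junction_count = n_seeded + n_cross,
    junction_density = (n_seeded + n_cross) / area,
    n_segments = nrow(segments)
  )
  structure(list(segments = segments, cell_polygon = poly,
                 cell_area = area, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "tat_segments")
}

## minimum distance between two 2D segments
seg_seg_dist <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) > 1e-12) {
    r <- q0 - p0
    t1 <- (r[1] * d2[2] - r[2] * d2[1]) / den
    t2 <- (r[1] * d1[2] - r[2] * d1[1]) / den
    if (t1 >= 0 && t1 <= 1 && t2 >= 0 && t2 <= 1) return(0)
  }
  min(pt_seg_dist(p0, q0, q1), pt_seg_dist(p1, q0, q1),
      pt_seg_dist(q0, p0, p1), pt_seg_dist(q1, p0, p1))
}

pt_seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
  sqrt(sum((p - (a + t * ab))^2))
}

## number of strict interior-interior crossings between segment pairs
## (T-junction contact points are endpoint contacts and are excluded; they
## are counted separately as seeded junctions)
count_crossings <- function(segments) {
  n <- nrow(segments)
  if (n < 2L) return(0L)
  eps <- 1e-9
  p0x <- segments$x0; p0y <- segments$y0
  dx <- segments$x1 - segments$x0; dy <- segments$y1 - segments$y0
  n_cross <- 0L
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    den <- dx[i] * dy[j] - dy[i] * dx[j]
    rx <- p0x[j] - p0x[i]; ry <- p0y[j] - p0y[i]
    t_i <- (rx * dy[j] - ry * dx[j]) / den
    t_j <- (rx * dy[i] - ry * dx[i]) / den
    hit <- abs(den) > eps &
      t_i > eps & t_i < 1 - eps & t_j > eps & t_j < 1 - eps
    n_cross <- n_cross + sum(hit, na.rm = TRUE)
  }
  n_cross
}

#' Ground-truth junction coordinates of a segment set
#'
#' Seeded T-junction attachment points plus strict interior crossings of
#' segment pairs, in micrometer coordinates.
#'
#' @param segs a `tat_segments`.
#' @return data.frame with `x`, `y` (um).
#' @export
junction_points <- function(segs) {
  stopifnot(inherits(segs, "tat_segments"))
  s <- segs$segments
  pts <- NULL
  if (any(s$seeded_junction))
    pts <- cbind(x = s$x0[s$seeded_junction], y = s$y0[s$seeded_junction])
  n <- nrow(s)
  eps <- 1e-9
  dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      den <- dx[i] * dy[j] - dy[i] * dx[j]
      if (abs(den) <= eps) next
      rx <- s$x0[j] - s$x0[i]; ry <- s$y0[j] - s$y0[i]
      t_i <- (rx * dy[j] - ry * dx[j]) / den
      t_j <- (rx * dy[i] - ry * dx[i]) / den
      if (t_i > eps && t_i < 1 - eps && t_j > eps && t_j < 1 - eps)
        pts <- rbind(pts, cbind(x = s$x0[i] + t_i * dx[i],
                                y = s$y0[i] + t_i * dy[i]))
    }
  }
  as.data.frame(if (is.null(pts)) cbind(x = numeric(0), y = numeric(0))
                else pts)
}

#' Ground truth restricted to an analysis region
#'
#' Evaluates the generator's truth (length, per-component length, junction
#' count, densities) within a pixel mask, e.g. the margin-eroded analysis
#' region the network pipeline actually measures.  Segment length inside
#' the region is integrated by dense sampling along each segment.
#'
#' @param segs a `tat_segments`.
#' @param mask logical matrix defining the region.
#' @param origin um coordinates of the (1,1) pixel corner (as in
#'   `tat_image$origin`).
#' @param pixel_size pixel size in nm.
#' @return list with `length_um`, `length_by_component`,
#'   `length_fractions`, `density`, `junction_count`, `junction_density`,
#'   `area_um2`.
#' @export
segment_truth_in_mask <- function(segs, mask, origin, pixel_size) {
  stopifnot(inherits(segs, "tat_segments"))
  pp <- pixel_size / 1000
  inside <- function(xs, ys) {
    cols <- round((xs - origin[1]) / pp + 0.5)
    rows <- round((ys - origin[2]) / pp + 0.5)
    ok <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
    res <- logical(length(xs))
    res[ok] <- mask[cbind(rows[ok], cols[ok])]
    res
  }
  s <- segs$segments
  len <- c(AT = 0, OT = 0, TT = 0)
  for (i in seq_len(nrow(s))) {
    n <- max(2L, ceiling(s$length_um[i] / 0.02))
    tv <- seq(0, 1, length.out = n)
    frac <- mean(inside(s$x0[i] + tv * (s$x1[i] - s$x0[i]),
                        s$y0[i] + tv * (s$y1[i] - s$y0[i])))
    len[s$component[i]] <- len[s$component[i]] + s$length_um[i] * frac
  }
  jp <- junction_points(segs)
  nj <- if (nrow(jp)) sum(inside(jp$x, jp$y)) else 0L
  area <- sum(mask) * pp^2
  list(length_um = sum(len), length_by_component = len,
       length_fractions = len / sum(len),
       density = sum(len) / area,
       junction_count = nj, junction_density = nj / area,
       area_um2 = area)
}

#' @export
print.tat_segments <- function(x, ...) {
  cat("Synthetic TAT network geometry\n")
  cat(sprintf("  cell: %.1f x %.1f um (axis %.1f deg), area %.1f um2\n",
              x$spec$cell_length, x$spec$cell_width, x$spec$axis_angle,
              x$cell_area))
  cat(sprintf("  segments: %d (total %.1f um, density %.3f um/um2)\n",
              x$truth$n_segments, x$truth$total_length, x$truth$density))
  fr <- x$truth$length_fractions
  cat(sprintf("  length fractions: AT %.2f / OT %.2f / TT %.2f\n",
              fr[["AT"]], fr[["OT"]], fr[["TT"]]))
  cat(sprintf("  expected junctions: %d (%.3f per um2)\n",
              x$truth$junction_count, x$truth$junction_density))
  invisible(x)
}

#' @export
plot.tat_segments <- function(x, ...) {
  cols <- c(AT = "#D55E00", OT = "#0072B2", TT = "#009E73")
  plot(NA, xlim = range(x$cell_polygon[, 1]),
       ylim = rev(range(x$cell_polygon[, 2])), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = "Synthetic TAT geometry", ...)
  graphics::polygon(x$cell_polygon, border = "grey40")
  s <- x$segments
  graphics::segments(s$x0, s$y0, s$x1, s$y1, col = cols[s$component])
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
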