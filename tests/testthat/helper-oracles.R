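## Independent oracles and fixtures for the test suite.
##
## oracle_graph() re-derives the skeleton-graph quantities by exhaustive
## pixel-neighbourhood enumeration with plain loops and flood fill — no
## igraph, no vectorized adjacency — so that it shares no code path with
## build_graph().

oracle_graph <- function(M, pixel_size = 16.23, prune_px = 0) {
  repeat {
    res <- oracle_graph_once(M, pixel_size)
    if (prune_px <= 0) return(res)
    ## remove spur branches (< prune_px steps, touching an endpoint)
    spurs <- Filter(function(b) b$has_endpoint && b$len_px < prune_px,
                    res$branch_list)
    if (!length(spurs)) return(res)
    for (b in spurs) for (p in b$pixels) M[p[1], p[2]] <- FALSE
    prune_px <- -1  # single pruning pass, then recompute
  }
}

oracle_graph_once <- function(M, pixel_size) {
  nr <- nrow(M); nc <- ncol(M)
  has <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && M[r, c]
  pts <- which(M, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L)
    return(list(n_junctions = 0L, n_branches = 0L, total_length_um = 0,
                n_endpoints = 0L, branch_list = list()))
  id_of <- matrix(0L, nr, nc)
  for (i in seq_len(n)) id_of[pts[i, 1], pts[i, 2]] <- i

  ## adjacency under the redundant-diagonal rule
  adj <- vector("list", n)
  len_of <- function(i, j) {
    if (pts[i, 1] != pts[j, 1] && pts[i, 2] != pts[j, 2]) sqrt(2) else 1
  }
  for (i in seq_len(n)) {
    r <- pts[i, 1]; c <- pts[i, 2]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r2 <- r + dr; c2 <- c + dc
      if (!has(r2, c2)) next
      if (dr != 0L && dc != 0L && (has(r, c2) || has(r2, c))) next
      nb <- c(nb, id_of[r2, c2])
    }
    adj[[i]] <- nb
  }
  deg <- lengths(adj)
  is_junc <- deg >= 3L

  flood <- function(members_mask) {
    lab <- integer(n); cur <- 0L
    for (s in which(members_mask)) {
      if (lab[s] > 0L) next
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (lab[v] > 0L) next
        lab[v] <- cur
        for (w in adj[[v]]) if (members_mask[w] && lab[w] == 0L)
          stack <- c(stack, w)
      }
    }
    lab
  }
  jlab <- flood(is_junc)
  clab <- flood(!is_junc)

  branch_ids <- sort(unique(clab[clab > 0L]))
  branch_list <- list()
  total_px <- 0
  n_branches <- 0L
  for (b in branch_ids) {
    members <- which(clab == b)
    len <- 0; nsteps <- 0L; has_end <- FALSE
    for (i in members) {
      if (deg[i] == 1L) has_end <- TRUE
      for (j in adj[[i]]) {
        if (is_junc[j]) {           # connecting step, counted once here
          len <- len + len_of(i, j); nsteps <- nsteps + 1L
        } else if (j > i) {          # internal step
          len <- len + len_of(i, j); nsteps <- nsteps + 1L
        }
      }
    }
    if (nsteps == 0L) next  # isolated pixel: degenerate node, not a branch
    n_branches <- n_branches + 1L
    total_px <- total_px + len
    branch_list[[length(branch_list) + 1L]] <- list(
      len_px = len, has_endpoint = has_end,
      pixels = lapply(members, function(i) pts[i, ]))
  }
  list(n_junctions = length(unique(jlab[jlab > 0L])),
       n_branches = n_branches,
       total_length_um = total_px * pixel_size / 1000,
       n_endpoints = sum(deg == 1L),
       branch_list = branch_list)
}

## dense-grid numerical convolution oracle for tubule width: envelope
## half-maximum width of ribbon (x) Gaussian on a 1 nm grid
oracle_ribbon_width <- function(w_nm, psf_fwhm) {
  dx <- 1
  x <- seq(-2000, 2000, by = dx)
  ribbon <- as.numeric(abs(x) <= w_nm / 2)
  sig <- psf_fwhm / (2 * sqrt(2 * log(2)))
  kx <- seq(-5 * sig, 5 * sig, by = dx)
  k <- stats::dnorm(kx, sd = sig); k <- k / sum(k)
  prof <- as.numeric(stats::filter(ribbon, k, sides = 2))
  half <- max(prof, na.rm = TRUE) / 2
  above <- which(prof > half)
  i1 <- above[1]; i2 <- above[length(above)]
  xl <- stats::approx(prof[(i1 - 1):i1], x[(i1 - 1):i1], xout = half)$y
  xr <- stats::approx(prof[i2:(i2 + 1)], x[i2:(i2 + 1)], xout = half)$y
  xr - xl
}

## ---- mask fixtures ----

mask_line <- function(n = 20, nr = 9) {
  M <- matrix(FALSE, nr, n + 4)
  M[ceiling(nr / 2), 3:(n + 2)] <- TRUE
  M
}

mask_L <- function() {
  M <- matrix(FALSE, 20, 20)
  M[10, 3:15] <- TRUE
  M[3:10, 15] <- TRUE
  M
}

mask_plus <- function() {
  M <- matrix(FALSE, 21, 21)
  M[11, 3:19] <- TRUE
  M[3:19, 11] <- TRUE
  M
}

mask_grid <- function() {
  M <- matrix(FALSE, 25, 25)
  for (r in c(6, 12, 18)) M[r, 3:23] <- TRUE
  for (c in c(6, 12, 18)) M[3:23, c] <- TRUE
  M
}

## random blob sampler: thresholded smoothed noise, <= 32 x 32
random_blob_mask <- function(seed, nr = 24, nc = 24) {
  tatnet:::with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    zs <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::as.Image(z), sigma = 2)))
    zs > stats::quantile(zs, 0.75)
  })
}

## rotated rectangle mask built analytically (for axis-angle tests)
mask_rot_rect <- function(angle_deg, len = 120, wid = 30, pad = 20) {
  n <- len + 2 * pad
  a <- angle_deg * pi / 180
  ctr <- (n + 1) / 2
  xs <- outer(rep(1, n), seq_len(n)) - ctr   # x = col
  ys <- outer(seq_len(n), rep(1, n)) - ctr   # y = row
  u <- xs * cos(a) + ys * sin(a)
  v <- -xs * sin(a) + ys * cos(a)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

## straight-ribbon mask at an angle (orientation tests)
mask_ribbon <- function(angle_deg, n = 80, len = 60, w = 3) {
  a <- angle_deg * pi / 180
  ctr <- (n + 1) / 2
  xs <- outer(rep(1, n), seq_len(n)) - ctr
  ys <- outer(seq_len(n), rep(1, n)) - ctr
  u <- xs * cos(a) + ys * sin(a)
  v <- -xs * sin(a) + ys * cos(a)
  abs(u) <= len / 2 & abs(v) <= w / 2
}

## small rendered single-tubule image + profile, shared by width tests
render_single_tubule <- function(w_nm, psf_fwhm = 60, pixel = 16.23,
                                 seed = 3, noise = FALSE) {
  spec <- network_spec(cell_length = 4, cell_width = 2.5,
                       target_density = 0.1, frac_at = 1, frac_ot = 0,
                       frac_tt = 0, angle_jitter_sd = 0,
                       segment_length_mean = 3, tubule_width_at = w_nm)
  segs <- generate_network_geometry(spec, seed = seed)
  im <- render_image(segs, imaging_spec(pixel_size = pixel,
                                        psf_fwhm = psf_fwhm,
                                        shot_noise = noise,
                                        read_noise_sd = if (noise) 2 else 0,
                                        seed = seed + 7))
  s <- segs$segments[1, ]
  ctr_px <- (c((s$y0 + s$y1) / 2, (s$x0 + s$x1) / 2) - rev(im$origin)) /
    (pixel / 1000) + 0.5
  ang <- atan2(s$y1 - s$y0, s$x1 - s$x0) * 180 / pi
  list(image = im, profile = extract_profile(im$image, ctr_px, ang,
                                             pixel_size = pixel))
}
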