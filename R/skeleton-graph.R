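## Skeleton -> branch/junction graph decomposition.
##
## Definitions (order-independent):
##   * a junction pixel has >= 3 skeleton neighbours (8-connectivity);
##   * a node is an 8-connected cluster of junction pixels, an endpoint
##     (1 neighbour), or an isolated pixel (degenerate node);
##   * non-junction pixels have degree <= 2, so their connected components
##     are simple paths or cycles: each such component, together with its
##     steps into adjacent junction clusters, is one branch;
##   * branch length = sum of its pixel steps (1 or sqrt(2) px) x pixel
##     size; steps internal to a junction cluster carry no length;
##   * total skeleton length = sum of branch lengths.

## all 8-adjacency steps between skeleton pixels, scanning E/S/SE/NE so each
## unordered pair appears once; returns linear indices and step length (px).
## A diagonal step whose two pixels share an occupied orthogonal neighbour
## is redundant (the path runs through that neighbour): keeping it would
## turn every staircase corner of a thinned line into a spurious 3-junction
## and double-count its length, so such steps are dropped.
skeleton_steps <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  idx <- which(M)
  out_from <- integer(0); out_to <- integer(0); out_len <- numeric(0)
  dirs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
               c(-1L, 1L, sqrt(2)))
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  at <- function(rr, c2) {
    ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
    out <- logical(length(rr))
    out[ok] <- M[(c2[ok] - 1L) * nr + rr[ok]]
    out
  }
  for (d in dirs) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- M[j]
    from <- idx[ok][hit]; to <- j[hit]
    if (d[1] != 0L && d[2] != 0L) {
      rf <- (from - 1L) %% nr + 1L; cf <- (from - 1L) %/% nr + 1L
      rt <- (to - 1L) %% nr + 1L; ct <- (to - 1L) %/% nr + 1L
      redundant <- at(rf, ct) | at(rt, cf)
      from <- from[!redundant]; to <- to[!redundant]
    }
    out_from <- c(out_from, from)
    out_to <- c(out_to, to)
    out_len <- c(out_len, rep(d[3], length(from)))
  }
  data.frame(from = out_from, to = out_to, len_px = out_len)
}

## full decomposition used by build_graph and orientation weighting
skeleton_decompose <- function(M, pixel_size, radius = NULL,
                               tip_extension = FALSE) {
  nr <- nrow(M); nc <- ncol(M)
  idx <- which(M)
  n <- length(idx)
  empty <- list(nodes = data.frame(), branches = data.frame(),
                n_junctions = 0L, n_endpoints = 0L, total_length_um = 0,
                pixel_weights_um = numeric(0), pixel_index = integer(0))
  if (n == 0L) return(empty)

  steps <- skeleton_steps(M)
  vid <- integer(nr * nc)
  vid[idx] <- seq_len(n)
  deg <- tabulate(c(vid[steps$from], vid[steps$to]), n)
  is_junc <- deg >= 3L

  f <- vid[steps$from]; t <- vid[steps$to]
  kind <- ifelse(is_junc[f] & is_junc[t], "intra",
                 ifelse(!is_junc[f] & !is_junc[t], "internal", "connect"))

  ## junction clusters
  junc_ids <- which(is_junc)
  clus <- integer(n)
  if (length(junc_ids)) {
    je <- steps[kind == "intra", , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(vid[je$from], junc_ids),
                 to = match(vid[je$to], junc_ids)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(junc_ids)))
    clus[junc_ids] <- igraph::components(g)$membership
  }
  n_clusters <- if (length(junc_ids)) as.integer(max(clus[junc_ids])) else 0L

  ## non-junction components (paths / cycles / singletons)
  nonj_ids <- which(!is_junc)
  comp <- integer(n)
  if (length(nonj_ids)) {
    ie <- steps[kind == "internal", , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(vid[ie$from], nonj_ids),
                 to = match(vid[ie$to], nonj_ids)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(nonj_ids)))
    comp[nonj_ids] <- igraph::components(g)$membership
  }
  n_comps <- if (length(nonj_ids)) as.integer(max(comp[nonj_ids])) else 0L

  px_um <- pixel_size / 1000
  ## per-branch accounting
  int_len <- num_by(steps$len_px[kind == "internal"],
                    comp[f[kind == "internal"]], n_comps)
  con <- steps[kind == "connect", , drop = FALSE]
  if (nrow(con)) {
    con_comp <- ifelse(is_junc[vid[con$from]], comp[vid[con$to]],
                       comp[vid[con$from]])
    con_clus <- ifelse(is_junc[vid[con$from]], clus[vid[con$from]],
                       clus[vid[con$to]])
  } else {
    con_comp <- integer(0); con_clus <- integer(0)
  }
  con_len <- num_by(con$len_px, con_comp, n_comps)
  n_con <- tabulate(con_comp, n_comps)
  comp_size <- tabulate(comp[nonj_ids], n_comps)
  int_deg <- tabulate(c(comp[f[kind == "internal"]],
                        comp[t[kind == "internal"]]), n_comps)

  ## endpoints: global degree 1 (always non-junction)
  is_end <- deg == 1L
  n_end_by_comp <- tabulate(comp[which(is_end)], n_comps)

  ## optional tip-erosion compensation: thinning retracts every free end
  ## by roughly the local half-width of the mask, so each endpoint adds
  ## back (distance-to-background - 1/2) px of length
  ext_len <- numeric(n_comps)
  if (tip_extension && !is.null(radius)) {
    is_end_px <- which(deg == 1L)
    if (length(is_end_px)) {
      ext <- pmax(radius[idx[is_end_px]] - 0.5, 0)
      ext_len <- num_by(ext, comp[is_end_px], n_comps)
    }
  }

  ## branch = non-junction component with at least one step
  br_len_px <- int_len + con_len + ext_len
  is_branch <- comp_size > 0L & (int_deg > 0L | n_con > 0L)

  branch_rows <- which(is_branch)
  node_a <- node_b <- character(length(branch_rows))
  for (bi in seq_along(branch_rows)) {
    b <- branch_rows[bi]
    ends <- character(0)
    if (n_con[b] > 0) {
      cl <- con_clus[con_comp == b]
      ends <- paste0("J", cl)
    }
    if (n_end_by_comp[b] > 0) {
      eps <- which(is_end & comp == b)
      ends <- c(ends, paste0("E", eps))
    }
    ends <- c(ends, rep(NA_character_, max(0, 2 - length(ends))))
    node_a[bi] <- ends[1]; node_b[bi] <- ends[2]
  }
  branches <- data.frame(
    id = branch_rows,  # = non-junction component label, stable across passes
    node_a = node_a, node_b = node_b,
    length_px = br_len_px[branch_rows],
    length_um = br_len_px[branch_rows] * px_um,
    n_pixels = comp_size[branch_rows],
    is_loop = (n_con[branch_rows] == 0L & n_end_by_comp[branch_rows] == 0L),
    has_endpoint = n_end_by_comp[branch_rows] > 0L,
    stringsAsFactors = FALSE
  )

  ## node table
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  nodes <- data.frame(id = character(0), type = character(0),
                      row = numeric(0), col = numeric(0))
  if (n_clusters > 0) {
    jr <- num_by(rows[junc_ids], clus[junc_ids], n_clusters) /
      tabulate(clus[junc_ids], n_clusters)
    jc <- num_by(cols[junc_ids], clus[junc_ids], n_clusters) /
      tabulate(clus[junc_ids], n_clusters)
    nodes <- rbind(nodes, data.frame(
      id = paste0("J", seq_len(n_clusters)), type = "junction",
      row = jr, col = jc))
  }
  ep <- which(is_end)
  if (length(ep))
    nodes <- rbind(nodes, data.frame(
      id = paste0("E", ep), type = "endpoint",
      row = rows[ep], col = cols[ep]))
  iso <- which(deg == 0L)
  if (length(iso))
    nodes <- rbind(nodes, data.frame(
      id = paste0("I", iso), type = "isolated",
      row = rows[iso], col = cols[iso]))

  ## per-pixel length weights for orientation analysis: each counted step
  ## contributes half its length to both of its pixels
  w <- numeric(n)
  counted <- kind != "intra"
  half <- steps$len_px[counted] / 2
  w <- w + num_by(half, f[counted], n) + num_by(half, t[counted], n)

  list(nodes = nodes, branches = branches,
       n_junctions = n_clusters, n_endpoints = length(ep),
       total_length_um = sum(branches$length_um),
       pixel_weights_um = w * px_um, pixel_index = idx,
       is_junction_pixel = is_junc)
}

## sum of x grouped by integer labels g in 1..n (0 labels dropped)
num_by <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- tapply(x, g, sum)
    out[as.integer(names(s))] <- s
  }
  out
}

#' Build the branch/junction graph of a skeleton
#'
#' Decomposes a one-pixel skeleton into junction nodes (8-connected clusters
#' of pixels with >= 3 neighbours), endpoints, and branches (maximal chains
#' of non-junction pixels, including their steps into adjacent junctions);
#' branch length counts each pixel step once (1 or sqrt(2) pixels).  Spur
#' branches shorter than `prune_spurs_px` that end in an endpoint (thinning
#' artifacts) are removed and the graph rebuilt once.
#'
#' Branch lengths count pixel steps (Analyze-Skeleton convention).  With
#' `tip_extension = TRUE` each free end additionally recovers the length the
#' thinning retracted there — the local mask half-width from the distance
#' transform — which removes the systematic tip-erosion bias when measuring
#' physical network length from wide ribbons; leave it off when comparing
#' against step-counting tools.
#'
#' @param skel a `tat_skeleton` from [skeletonize()].
#' @param prune_spurs_px prune endpoint-terminated branches shorter than
#'   this many pixels (default 2; 0 disables pruning).
#' @param tip_extension logical (default FALSE): compensate tip erosion at
#'   endpoints using the mask distance transform recorded by
#'   [skeletonize()].
#' @param junction_merge_um merge junction nodes whose centroids lie within
#'   this physical radius (um) when counting junctions (default 0 = only
#'   8-connected merging).  A four-way crossing of wide tubules often thins
#'   into two nearby 3-junctions; at high resolution these are one
#'   biological branch point.
#' @return an object of class `tat_graph`: `nodes` and `branches` data
#'   frames, `n_junctions`, `n_endpoints`, `total_length_um`, `pixel_size`,
#'   and the (possibly pruned) skeleton matrix as `pixels`.
#' @export
build_graph <- function(skel, prune_spurs_px = 2, tip_extension = FALSE,
                        junction_merge_um = 0) {
  stopifnot(inherits(skel, "tat_skeleton"))
  M <- skel$pixels
  dec <- skeleton_decompose(M, skel$pixel_size)
  if (prune_spurs_px > 0 && nrow(dec$branches) > 0) {
    ## spur decision on raw step length, before any tip extension
    spur <- dec$branches$has_endpoint &
      dec$branches$length_px < prune_spurs_px
    if (any(spur)) {
      ## remove the non-junction pixels of spur branches; branches are
      ## indexed by non-junction component, recovered by the labelled pass
      M2 <- M
      lab <- branch_membership(M, skel$pixel_size)
      for (b in dec$branches$id[spur]) {
        M2[dec$pixel_index[lab == b]] <- FALSE
      }
      M <- M2
      dec <- skeleton_decompose(M, skel$pixel_size)
    }
  }
  if (tip_extension)
    dec <- skeleton_decompose(M, skel$pixel_size, radius = skel$radius_px,
                              tip_extension = TRUE)
  n_junc <- dec$n_junctions
  if (junction_merge_um > 0 && n_junc > 1) {
    jn <- dec$nodes[dec$nodes$type == "junction", , drop = FALSE]
    r_px <- junction_merge_um * 1000 / skel$pixel_size
    d <- as.matrix(stats::dist(jn[, c("row", "col")]))
    g <- igraph::graph_from_adjacency_matrix(d <= r_px, mode = "undirected")
    n_junc <- as.integer(igraph::components(g)$no)
  }
  structure(list(nodes = dec$nodes, branches = dec$branches,
                 n_junctions = n_junc,
                 n_endpoints = dec$n_endpoints,
                 total_length_um = dec$total_length_um,
                 pixel_size = skel$pixel_size, pixels = M,
                 pixel_weights_um = dec$pixel_weights_um,
                 pixel_index = dec$pixel_index),
            class = "tat_graph")
}

## map each skeleton pixel to its branch id (0 for junction/isolated pixels)
branch_membership <- function(M, pixel_size) {
  idx <- which(M)
  n <- length(idx)
  if (n == 0L) return(integer(0))
  steps <- skeleton_steps(M)
  vid <- integer(nrow(M) * ncol(M)); vid[idx] <- seq_len(n)
  deg <- tabulate(c(vid[steps$from], vid[steps$to]), n)
  is_junc <- deg >= 3L
  nonj_ids <- which(!is_junc)
  comp <- integer(n)
  if (length(nonj_ids)) {
    f <- vid[steps$from]; t <- vid[steps$to]
    intn <- !is_junc[f] & !is_junc[t]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(f[intn], nonj_ids),
                 to = match(t[intn], nonj_ids)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(nonj_ids)))
    comp[nonj_ids] <- igraph::components(g)$membership
  }
  comp
}

#' @export
print.tat_graph <- function(x, ...) {
  cat("TAT skeleton graph\n")
  cat(sprintf("  %d junctions, %d endpoints, %d branches\n",
              x$n_junctions, x$n_endpoints, nrow(x$branches)))
  cat(sprintf("  total length %.2f um; mean branch %.2f um\n",
              x$total_length_um,
              if (nrow(x$branches)) mean(x$branches$length_um) else NA))
  invisible(x)
}

#' Network metrics from a skeleton graph
#'
#' @param graph a `tat_graph`.
#' @param roi_area analysis-region area in um2 (> 0).
#' @return an object of class `network_metrics`: `density` (um/um2),
#'   `junction_density` (1/um2), `mean_branch_length` (um), `n_branches`,
#'   `n_junctions`, `total_length`, `roi_area`.
#' @export
network_metrics <- function(graph, roi_area) {
  stopifnot(inherits(graph, "tat_graph"))
  check_scalar(roi_area, "roi_area", 0, strict_lower = TRUE)
  nb <- nrow(graph$branches)
  structure(list(
    density = graph$total_length_um / roi_area,
    junction_density = graph$n_junctions / roi_area,
    mean_branch_length = if (nb > 0) mean(graph$branches$length_um)
                         else NA_real_,
    n_branches = nb,
    n_junctions = graph$n_junctions,
    total_length = graph$total_length_um,
    roi_area = roi_area
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("TAT network metrics\n")
  cat(sprintf("  density           %.4f um/um2\n", x$density))
  cat(sprintf("  junction density  %.4f /um2\n", x$junction_density))
  cat(sprintf("  mean branch       %.3f um (%d branches)\n",
              x$mean_branch_length, x$n_branches))
  cat(sprintf("  total length      %.2f um in %.1f um2\n",
              x$total_length, x$roi_area))
  invisible(x)
}
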