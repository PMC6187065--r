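## Topology-preserving thinning (Zhang-Suen) with a cleanup pass that
## removes redundant pixels completing 2x2 blocks, so the result satisfies
## the one-pixel-thin invariant used by the graph decomposition.

## neighbour image: value of the neighbour at offset `off` for every pixel
nb <- function(P, off) shift_mat(P, -off[1], -off[2])

## number of 0->1 transitions around the 8-neighbourhood (crossing number)
transitions8 <- function(nbs) {
  A <- matrix(0L, nrow(nbs[[1]]), ncol(nbs[[1]]))
  for (i in 1:8) {
    j <- i %% 8L + 1L
    A <- A + (nbs[[i]] == 0L & nbs[[j]] == 1L)
  }
  A
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide, 8-connected skeleton, followed
#' by a cleanup pass deleting simple pixels that still complete a fully
#' occupied 2x2 block (staircase residue of the thinning).  Connectivity of
#' each component is preserved.  An empty mask yields an empty skeleton.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size pixel size in nm.
#' @return an object of class `tat_skeleton`: list with `pixels` (logical
#'   matrix) and `pixel_size` (nm).
#' @export
skeletonize <- function(mask, pixel_size = 16.23) {
  if (!is.matrix(mask)) stopf("'mask' must be a matrix")
  check_scalar(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  P <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nbs <- lapply(NB8, function(o) nb(P, o))
      B <- Reduce(`+`, nbs)
      A <- transitions8(nbs)
      p2 <- nbs[[1]]; p4 <- nbs[[3]]; p6 <- nbs[[5]]; p8 <- nbs[[7]]
      if (sub == 1L) {
        cond <- P == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- P == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        P[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P <- clean_2x2(P)
  ## local half-width of the original mask (Euclidean distance to
  ## background), used by the optional tip-erosion correction in
  ## build_graph()
  radius <- as.matrix(EBImage::imageData(
    EBImage::distmap(EBImage::as.Image(matrix(as.numeric(mask > 0),
                                              nrow(mask), ncol(mask))))))
  structure(list(pixels = P > 0, pixel_size = pixel_size,
                 radius_px = radius),
            class = "tat_skeleton")
}

## delete pixels that are 8-simple (crossing number 1, not endpoints) while
## they complete a fully occupied 2x2 block; sequential raster order for
## determinism
clean_2x2 <- function(P) {
  nr <- nrow(P); nc <- ncol(P)
  repeat {
    blocks <- P[-nr, -nc, drop = FALSE] & P[-1, -nc, drop = FALSE] &
      P[-nr, -1, drop = FALSE] & P[-1, -1, drop = FALSE]
    if (!any(blocks)) break
    idx <- which(blocks, arr.ind = TRUE)
    removed <- FALSE
    for (b in seq_len(nrow(idx))) {
      for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- idx[b, 1] + off[1]; cc <- idx[b, 2] + off[2]
        if (P[r, cc] == 0L) next
        vals <- vapply(NB8, function(o) {
          rr <- r + o[1]; c2 <- cc + o[2]
          if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) 0L else P[rr, c2]
        }, integer(1))
        B <- sum(vals)
        A <- sum(vals == 0L & vals[c(2:8, 1)] == 1L)
        if (A == 1L && B >= 2L) {
          P[r, cc] <- 0L
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break  # no simple pixel in any block; give up safely
  }
  P
}

#' @export
print.tat_skeleton <- function(x, ...) {
  cat(sprintf("TAT skeleton: %d pixels on a %d x %d grid (%.2f nm/px)\n",
              sum(x$pixels), nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}
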