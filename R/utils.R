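#' @keywords internal
"_PACKAGE"

## conversion constant: FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Evaluate code with a local, restored RNG state
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that a seed given in a spec never leaks into (or depends
#' on) the caller's global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## wrap an angle in degrees into (-90, 90]
wrap_angle <- function(theta) {
  theta <- (theta + 90) %% 180 - 90
  theta[theta <= -90] <- theta[theta <= -90] + 180
  theta
}

## fold an orientation onto [0, 90] (axial symmetry: theta ~ theta + 180, and
## the unsigned deviation from the reference axis is what classifies a tubule)
fold_angle <- function(theta) abs(wrap_angle(theta))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

## shift a matrix by (dr, dc) with zero padding; used by the thinning and
## neighbour-counting code
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rsrc <- seq_len(nr) - dr
  csrc <- seq_len(nc) - dc
  rok <- rsrc >= 1L & rsrc <= nr
  cok <- csrc >= 1L & csrc <= nc
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

## the 8-neighbourhood offsets in the clockwise order P2..P9 used by
## Zhang-Suen thinning (P2 = north)
NB8 <- list(
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)

## linear interpolation of the x where y crosses `level` between two samples
cross_interp <- function(x0, x1, y0, y1, level) {
  if (y1 == y0) return(x0)
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}

## Gaussian blur that zero-pads first, so the filter window may exceed the
## image (EBImage::filter2 refuses kernels larger than the image)
gblur_padded <- function(m, sigma) {
  pad <- as.integer(ceiling(3 * sigma)) + 1L
  big <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  out <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::as.Image(big), sigma = sigma)))
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}
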