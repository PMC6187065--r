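#' Write an image (counts) to a single-channel TIFF
#'
#' @param image numeric matrix of counts, or a `tat_image`.
#' @param path output file.
#' @param bit_depth 8 or 16 (default: from the `tat_image`, else 16).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, bit_depth = NULL) {
  if (inherits(image, "tat_image")) {
    if (is.null(bit_depth)) bit_depth <- image$imaging$bit_depth
    image <- image$image
  }
  if (is.null(bit_depth)) bit_depth <- 16L
  maxval <- 2^bit_depth - 1
  m <- pmin(pmax(image, 0), maxval) / maxval
  tiff::writeTIFF(m, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a single-channel TIFF as a counts matrix
#'
#' @param path TIFF file.
#' @return numeric matrix of counts (integer sample values).
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write a trace to a two-column CSV
#'
#' @param trace data.frame whose first column is time (`time_s` or
#'   `time_ms`) and second the value.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, 1:2], path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column trace CSV
#'
#' @param path CSV with a time column (`time_s`/`time_ms`/`time`) and a
#'   value column.
#' @return data.frame as stored.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stopf("trace CSV needs two columns")
  df
}

#' Write a truth/metadata block as a JSON sidecar
#' @param truth a list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON sidecar
#' @param path JSON file.
#' @return a list.
#' @export
read_truth_json <- function(path) jsonlite::read_json(path,
                                                      simplifyVector = TRUE)
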