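#' Optical action-potential metrics from a voltage-dye trace
#'
#' Computes the three stimulus-aligned metrics of a fluorescence AP
#' recording: amplitude (post-stimulus maximum minus the pre-stimulus
#' baseline), onset (time from stimulus end to the first crossing of
#' baseline + `threshold`, linearly interpolated between samples), and
#' maximum upstroke slope (maximum first derivative of a Savitzky-Golay
#' smoothed copy within the upstroke window).  The recording-site label
#' (surface sarcolemma, TT or AT) is carried through but never enters the
#' computation.
#'
#' @param time time in ms (uniformly sampled).
#' @param dff baseline-normalized fluorescence (dF/F).
#' @param stim_end end of the stimulus, ms; the baseline is the mean dF/F
#'   before this point.
#' @param threshold onset threshold above baseline, dF/F (default 0.04,
#'   i.e. 4% dF/F).
#' @param smooth_window Savitzky-Golay window (odd number of samples) for
#'   the derivative; default 5.
#' @param site_label optional `"SS"`, `"TT"` or `"AT"`.
#' @return an object of class `ap_metrics`: `amplitude` (dF/F), `onset`
#'   (ms, NA with `onset_found = FALSE` when no crossing exists),
#'   `max_slope` (dF/F per ms), `peak_dff` (amplitude without baseline
#'   subtraction), `baseline`, `site_label`.
#' @export
ap_metrics <- function(time, dff, stim_end, threshold = 0.04,
                       smooth_window = 5, site_label = NA_character_) {
  if (length(time) != length(dff) || length(time) < 5L)
    stopf("need >= 5 aligned samples")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stopf("time must be uniformly sampled and increasing")
  if (stim_end <= min(time) || stim_end >= max(time))
    stopf("stim_end must lie within the trace")
  dt <- mean(dt)
  pre <- dff[time < stim_end]
  if (!length(pre)) stopf("no pre-stimulus baseline window")
  baseline <- mean(pre)
  post <- which(time >= stim_end)
  peak_abs <- max(dff[post])
  amplitude <- max(peak_abs - baseline, 0)

  ## onset: first interpolated crossing of baseline + threshold after the
  ## stimulus
  lvl <- baseline + threshold
  onset <- NA_real_
  found <- FALSE
  above <- dff[post] >= lvl
  if (any(above)) {
    i <- post[which(above)[1]]
    onset_t <- if (i == post[1] || dff[i - 1] >= lvl) time[i] else
      cross_interp(time[i - 1], time[i], dff[i - 1], dff[i], lvl)
    onset <- onset_t - stim_end
    found <- TRUE
  }

  ## maximum slope in the upstroke window (from stimulus end, or the onset
  ## crossing when found, to the post-stimulus peak)
  n <- length(dff)
  sw <- as.integer(smooth_window)
  if (sw %% 2L == 0L) sw <- sw + 1L
  ## window < 3 disables smoothing (derivative of the raw trace)
  sm <- if (sw >= 3L && n > sw) signal::sgolayfilt(dff, p = 2, n = sw)
        else dff
  deriv <- c(NA, diff(sm) / dt)
  ip <- post[which.max(dff[post])]
  w0 <- post[1]
  win <- seq(max(w0, 2L), max(ip, w0 + 1L))
  max_slope <- max(deriv[win], na.rm = TRUE)

  structure(list(
    amplitude = amplitude, onset = onset, onset_found = found,
    max_slope = max_slope, peak_dff = peak_abs, baseline = baseline,
    threshold = threshold, site_label = site_label
  ), class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat("Optical AP metrics")
  if (!is.na(x$site_label)) cat(sprintf(" [%s]", x$site_label))
  cat("\n")
  cat(sprintf("  amplitude %.4g dF/F (peak %.4g, baseline %.4g)\n",
              x$amplitude, x$peak_dff, x$baseline))
  if (x$onset_found) {
    cat(sprintf("  onset %.3g ms after stimulus end (threshold %g dF/F)\n",
                x$onset, x$threshold))
  } else {
    cat(sprintf("  no threshold crossing (threshold %g dF/F)\n",
                x$threshold))
  }
  cat(sprintf("  max slope %.4g dF/F per ms\n", x$max_slope))
  invisible(x)
}
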